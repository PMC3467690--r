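# Shared miniature objects, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# Memoized miniature trained record (5 neurons, 200 afferents, 10 s).
get_fixture <- function(seed = 1L) {
  key <- paste0("fix", seed)
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- make_fixture(seed)
  fixture_env[[key]]
}

# Hand-built chain_test object: `spike_list` is a list of data.frames
# (neuron, time relative to onset), one per presentation.
fake_test <- function(spike_list, n_exc = 5, pattern_duration = 50,
                      gap = 150) {
  onsets <- 100 + (seq_along(spike_list) - 1) * (pattern_duration + gap)
  spikes <- do.call(rbind, lapply(seq_along(spike_list), function(i) {
    df <- spike_list[[i]]
    if (is.null(df) || !nrow(df)) return(NULL)
    data.frame(neuron = df$neuron, time = df$time + onsets[i])
  }))
  if (is.null(spikes)) spikes <- data.frame(neuron = integer(0), time = numeric(0))
  structure(list(spikes = spikes[order(spikes$time), ], onsets = onsets,
                 pattern_duration = pattern_duration,
                 n_presentations = length(spike_list), n_exc = n_exc,
                 lateral_enabled = TRUE, speed_factor = 1, reverse = FALSE),
            class = "chain_test")
}

# Random spike trains for STDP property tests.
random_train <- function(n, t_max = 200) sort(stats::runif(n, 0, t_max))
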