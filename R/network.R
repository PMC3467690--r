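# Network-level protocols: training, testing (including severed-lateral,
# reversed-pattern and speed-scaled probes), multi-pattern training and
# chain concatenation.
#
# The network is N excitatory LIF neurons, all-to-all laterally connected
# with plastic synapses (zero diagonal), plus one inhibitory neuron wired to
# and from every excitatory neuron with static weights. Any excitatory spike
# drives the inhibitory neuron, whose spike transiently hyperpolarizes the
# whole excitatory population: a winner-takes-all mechanism that enforces
# sparse, one-at-a-time responses during learning.

#' Network configuration
#'
#' @param n_exc Number of excitatory neurons (default 20).
#' @param train_duration Training duration in ms (default 200000). Pattern
#'   learning emerges first; the sequence criterion (lateral dependence and
#'   fixed firing order) is typically met late in training, once the
#'   depression-dominated drift has pruned unselective drive.
#' @param stimulus A [stimulus_config()]; its `dt` and `seed` are overridden
#'   by the network-level `dt` and `seed`.
#' @param neuron A [neuron_params()].
#' @param kinetics A [synapse_kinetics()].
#' @param stdp_mode `"nearest_neighbor"` or `"all_to_all"`.
#' @param nn_depression Depression pairing in nearest-neighbor mode:
#'   `"nearest_post"` (default; fully symmetric nearest-neighbor pairing,
#'   which preserves the exact 1.05 depression/potentiation balance of the
#'   pairing window for uncorrelated trains) or `"all_post"` (each
#'   presynaptic spike is depressed by the full postsynaptic trace; this
#'   makes uncorrelated input so strongly net-depressing that network
#'   activity collapses before any pattern can be learnt, so it is provided
#'   for comparison only).
#' @param tau_p,tau_d STDP window time constants in ms (default 20).
#' @param wl_max Bound on the summed incoming lateral weight per neuron
#'   (default 50).
#' @param wp_max Feed-forward per-synapse weight bound; `NULL` (default)
#'   computes it with [compute_wmax_ff()].
#' @param a_const Strength constant of the feed-forward bound. The default
#'   12.8 is calibrated behaviorally for this implementation (see
#'   [compute_wmax_ff()]): it places the initial mean membrane drive
#'   moderately above threshold, so neurons fire noise-driven from the
#'   start, the winner-takes-all competition can assign pattern segments,
#'   and the trained network ends up with segment-selective neurons.
#' @param w_ei,w_ie Static excitatory-to-inhibitory / inhibitory-to-
#'   excitatory weights; `NULL` derives them with [derive_wta_weights()].
#' @param shared_noise If `TRUE`, all excitatory neurons see the identical
#'   noise realization (diagnostic mode). Default `FALSE`: each neuron gets
#'   independent carrier/background realizations and only the frozen pattern
#'   is shared, which provides the symmetry-breaking noise the competitive
#'   learning needs.
#' @param snapshot_every Weight-snapshot interval in ms (default 5000;
#'   `0` disables snapshots).
#' @param dt Integration step in ms (default 0.1).
#' @param seed Master integer seed; independent sub-streams for pattern,
#'   schedule, noise, initial weights and tests are derived from it.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_exc = 20, train_duration = 200000,
                           stimulus = stimulus_config(),
                           neuron = neuron_params(),
                           kinetics = synapse_kinetics(),
                           stdp_mode = c("nearest_neighbor", "all_to_all"),
                           nn_depression = c("nearest_post", "all_post"),
                           tau_p = 20, tau_d = 20,
                           wl_max = 50, wp_max = NULL, a_const = 12.8,
                           w_ei = NULL, w_ie = NULL,
                           shared_noise = FALSE,
                           snapshot_every = 5000,
                           dt = 0.1, seed = 1L) {
  stdp_mode <- match.arg(stdp_mode)
  nn_depression <- match.arg(nn_depression)
  if (n_exc < 2) stop("`n_exc` must be at least 2")
  stop_if_not_scalar_pos(train_duration, "train_duration", strict = FALSE)
  stop_if_not_scalar_pos(wl_max, "wl_max")
  stimulus$dt <- dt
  stimulus$total_duration <- train_duration
  neuron$dt <- dt
  structure(list(
    n_exc = as.integer(n_exc), train_duration = train_duration,
    stimulus = stimulus, neuron = neuron, kinetics = kinetics,
    stdp_mode = stdp_mode, nn_depression = nn_depression,
    tau_p = tau_p, tau_d = tau_d,
    wl_max = wl_max, wp_max = wp_max, a_const = a_const,
    w_ei = w_ei, w_ie = w_ie,
    shared_noise = isTRUE(shared_noise),
    snapshot_every = snapshot_every,
    dt = dt, seed = as.integer(seed)
  ), class = "network_config")
}

#' Derive the static winner-takes-all loop weights
#'
#' The loop weights are not learned; they are calibrated behaviorally from a
#' deterministic simulation of the loop itself. The excitatory-to-inhibitory
#' weight `w_ei` is set so one excitatory spike drives the inhibitory
#' membrane across threshold within `response_ms` (on the early rising edge
#' of the PSP, so competition acts before further winners emerge). Because a
#' PSP strong enough for such a fast response keeps the inhibitory membrane
#' near threshold for a while, the inhibitory neuron answers each excitatory
#' spike with a brief burst rather than a single spike; the
#' inhibitory-to-excitatory weight `w_ie` is therefore sized against the
#' *compound* response: the simulated inhibitory burst is replayed onto an
#' excitatory neuron and `w_ie` scaled so the compound hyperpolarization
#' peaks at `ie_peak_factor` times threshold, which suppresses the
#' excitatory population for a few milliseconds and then releases it.
#'
#' @param params A [neuron_params()].
#' @param kinetics A [synapse_kinetics()].
#' @param response_ms Time after an excitatory spike at which the inhibitory
#'   membrane must reach threshold (ms).
#' @param ie_peak_factor Compound peak hyperpolarization in units of
#'   threshold.
#' @return List with `w_ei`, `w_ie`, the simulated `burst` (inhibitory spike
#'   times after one excitatory spike, ms) and `suppression_ms` (time the
#'   compound hyperpolarization stays above half the threshold).
#' @export
derive_wta_weights <- function(params = neuron_params(),
                               kinetics = synapse_kinetics(),
                               response_ms = 1.5, ie_peak_factor = 2) {
  v1 <- psp_closed_form(response_ms, 1, params, kinetics)
  w_ei <- params$theta / v1
  # deterministic loop response: one excitatory spike -> inhibitory burst
  horizon <- 6 * params$tau_m
  inh <- simulate_neuron(0, w_ei, duration = horizon, params = params,
                         kinetics = kinetics)
  burst <- inh$spikes + params$dt  # one-step synaptic delay
  resp <- simulate_neuron(burst, 1, duration = 3 * horizon, params = params,
                          kinetics = kinetics, threshold_active = FALSE)
  depth1 <- max(resp$v)
  w_ie <- ie_peak_factor * params$theta / depth1
  above <- resp$time[resp$v * w_ie > 0.5 * params$theta]
  list(w_ei = w_ei, w_ie = w_ie, burst = burst,
       suppression_ms = if (length(above)) diff(range(above)) else 0)
}

# Resolve derived quantities of a network_config into a flat parameter list.
resolve_config <- function(cfg) {
  st <- cfg$stimulus
  mean_rate <- st$carrier_rate + st$background_rate
  wp_max <- if (is.null(cfg$wp_max)) {
    compute_wmax_ff(cfg$neuron$theta, cfg$neuron$tau_m, mean_rate, cfg$dt,
                    cfg$a_const, st$n_pattern_afferents)
  } else cfg$wp_max
  ff <- compute_learning_rates(wp_max, cfg$tau_p, cfg$tau_d)
  lat <- compute_learning_rates(cfg$wl_max, cfg$tau_p, cfg$tau_d)
  wta <- derive_wta_weights(cfg$neuron, cfg$kinetics)
  list(
    wp_max = wp_max,
    a_p_ff = ff$a_p, a_d_ff = ff$a_d,
    a_p_lat = lat$a_p, a_d_lat = lat$a_d,
    w_ei = if (is.null(cfg$w_ei)) wta$w_ei else cfg$w_ei,
    w_ie = if (is.null(cfg$w_ie)) wta$w_ie else cfg$w_ie,
    p_carrier = rate_to_p(st$carrier_rate, cfg$dt),
    p_background = rate_to_p(st$background_rate, cfg$dt)
  )
}

# Pattern list -> flattened 0-based (aff, bin) arrays sorted by bin.
flatten_patterns <- function(patterns, dt) {
  pat_aff <- integer(0); pat_bin <- integer(0)
  pat_start <- 0L; pat_dur <- integer(0)
  for (p in patterns) {
    rel <- as.integer(round(p$spikes$time / dt))
    ord <- order(rel, p$spikes$afferent)
    pat_aff <- c(pat_aff, p$spikes$afferent[ord] - 1L)
    pat_bin <- c(pat_bin, rel[ord])
    pat_start <- c(pat_start, length(pat_aff))
    pat_dur <- c(pat_dur, as.integer(round(p$duration / dt)))
  }
  list(aff = pat_aff, bin = pat_bin, start = pat_start, dur = pat_dur)
}

# Low-level wrapper around the compiled simulator.
run_sim <- function(cfg, res, patterns, schedule, w, duration,
                    plastic = TRUE, lateral_scale = 1, theta = NULL,
                    noise_seed, snapshot_every = 0, snapshot_ff = TRUE,
                    v_record_neuron = -1L) {
  dt <- cfg$dt
  fp <- flatten_patterns(patterns, dt)
  n_steps <- as.integer(round(duration / dt))
  onset_bins <- as.integer(round(schedule$onset / dt))
  snap_bins <- if (snapshot_every > 0) as.integer(round(snapshot_every / dt)) else 0L
  raw <- .sim_network_cpp(
    n_exc = cfg$n_exc, n_aff = cfg$stimulus$n_afferents,
    n_pat_aff = cfg$stimulus$n_pattern_afferents,
    n_steps = n_steps, dt = dt,
    tau_m = cfg$neuron$tau_m,
    theta = if (is.null(theta)) cfg$neuron$theta else theta,
    theta_inh = cfg$neuron$theta,
    tau_r = cfg$kinetics$tau_r, tau_f = cfg$kinetics$tau_f,
    pat_aff = fp$aff, pat_bin = fp$bin, pat_start = fp$start,
    pat_dur = fp$dur,
    sched_onset = onset_bins, sched_pat = schedule$pattern - 1L,
    p_carrier = res$p_carrier, p_background = res$p_background,
    shared_noise = cfg$shared_noise,
    w_ff_in = w$w_ff, w_lat_in = w$w_lat,
    wp_max = res$wp_max, wl_max = cfg$wl_max,
    a_p_ff = res$a_p_ff, a_d_ff = res$a_d_ff,
    a_p_lat = res$a_p_lat, a_d_lat = res$a_d_lat,
    tau_p = cfg$tau_p, tau_d = cfg$tau_d,
    stdp_mode = if (cfg$stdp_mode == "nearest_neighbor") 0L else 1L,
    nn_dep = if (identical(cfg$nn_depression, "nearest_post")) 1L else 0L,
    plastic = plastic, lateral_scale = lateral_scale,
    w_ei = res$w_ei, w_ie = res$w_ie,
    seed = as.integer(noise_seed),
    snapshot_every = snap_bins, snapshot_ff = snapshot_ff,
    v_record_neuron = as.integer(v_record_neuron))
  spikes <- data.frame(neuron = raw$spike_neuron + 1L,
                       time = raw$spike_bin * dt)
  list(spikes = spikes, w_ff = raw$w_ff, w_lat = raw$w_lat,
       snapshots = list(time = raw$snapshots$bins * dt,
                        w_lat = raw$snapshots$w_lat,
                        w_ff = raw$snapshots$w_ff),
       v_trace = raw$v_trace)
}

#' Train the network on one or more frozen patterns
#'
#' Runs the full training loop: the stimulus (frozen pattern(s) embedded in
#' Poisson carrier and background noise) drives the excitatory neurons
#' through plastic feed-forward synapses; every excitatory spike excites the
#' inhibitory neuron (static weight) and the lateral alpha synapses of the
#' other excitatory neurons; inhibitory spikes transiently suppress the
#' excitatory population (winner-takes-all); STDP acts on feed-forward and
#' lateral weights throughout, with the lateral incoming sums normalized to
#' `wl_max`.
#'
#' @param cfg A [network_config()].
#' @param n_patterns Number of distinct frozen patterns interleaved in the
#'   schedule (default 1).
#' @return An object of class `sim_record`: spikes (1-based neuron id,
#'   `n_exc + 1` = inhibitory neuron), final and periodic-snapshot weights,
#'   the frozen pattern(s), the schedule, resolved parameters, and the
#'   configuration echo.
#' @export
run_training <- function(cfg, n_patterns = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  seeds <- spawn_seeds(cfg$seed,
                       c("pattern", "schedule", "noise", "weights", "test"))
  res <- resolve_config(cfg)
  st <- cfg$stimulus
  patterns <- lapply(seq_len(n_patterns), function(i) {
    generate_pattern(st, seed = seeds[["pattern"]], stream = i)
  })
  schedule <- if (cfg$train_duration > st$pattern_duration + st$min_gap) {
    build_schedule(st, n_patterns = n_patterns, seed = seeds[["schedule"]],
                   total_duration = cfg$train_duration)
  } else {
    # too short to schedule a presentation (including zero-duration runs)
    structure(data.frame(onset = numeric(0), pattern = integer(0)),
              class = c("presentation_schedule", "data.frame"),
              pattern_duration = st$pattern_duration,
              total_duration = cfg$train_duration)
  }
  w <- init_weights(st$n_afferents, cfg$n_exc, res$wp_max, cfg$wl_max,
                    seeds[["weights"]])
  sim <- run_sim(cfg, res, patterns, schedule, w,
                 duration = cfg$train_duration, plastic = TRUE,
                 noise_seed = seeds[["noise"]],
                 snapshot_every = cfg$snapshot_every)
  structure(list(
    cfg = cfg, seeds = seeds, resolved = res,
    patterns = patterns, schedule = schedule,
    spikes = sim$spikes, w_ff = sim$w_ff, w_lat = sim$w_lat,
    snapshots = sim$snapshots, initial_weights = w
  ), class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  n_exc_spk <- sum(x$spikes$neuron <= x$cfg$n_exc)
  cat(sprintf(
    "<sim_record> %d excitatory neurons, %.0f s training, %s STDP\n  %d excitatory spikes, %d presentations, wp_max = %.4g, wl_max = %g\n",
    x$cfg$n_exc, x$cfg$train_duration / 1000, x$cfg$stdp_mode,
    n_exc_spk, nrow(x$schedule), x$resolved$wp_max, x$cfg$wl_max))
  invisible(x)
}

# Scale / reverse a frozen pattern for test-time probes.
transform_pattern <- function(pattern, dt, speed_factor = 1, reverse = FALSE) {
  rel <- as.integer(round(pattern$spikes$time / dt))
  dur_bins <- as.integer(round(pattern$duration / dt))
  if (reverse) rel <- dur_bins - 1L - rel
  if (speed_factor != 1) {
    rel <- as.integer(round(rel / speed_factor))
    dur_bins <- as.integer(ceiling(dur_bins / speed_factor))
    rel <- pmin(rel, dur_bins - 1L)
  }
  key <- paste(pattern$spikes$afferent, rel)
  keep <- !duplicated(key)  # collapse collisions from rounding
  ord <- order(rel[keep], pattern$spikes$afferent[keep])
  structure(list(
    spikes = data.frame(afferent = pattern$spikes$afferent[keep][ord],
                        time = rel[keep][ord] * dt),
    duration = dur_bins * dt,
    n_afferents = pattern$n_afferents, dt = dt
  ), class = "frozen_pattern")
}

#' Test a trained network with repeated pattern presentations
#'
#' Presents the stored frozen pattern `n_presentations` times, embedded in
#' fresh carrier/background noise, with plasticity frozen by default, and
#' returns the output spikes together with the presentation onsets. Lateral
#' connections can be severed (`lateral_enabled = FALSE`) to probe how much
#' each neuron depends on its predecessors, the pattern can be reversed, and
#' its speed can be scaled.
#'
#' @param record A [run_training()] result (or any `sim_record`).
#' @param n_presentations Number of test presentations (default 10).
#' @param lateral_enabled If `FALSE`, lateral weights are zeroed at test
#'   time (severed-lateral probe).
#' @param plasticity_frozen Keep synapses fixed during the test (default
#'   `TRUE`, for reproducible evaluation).
#' @param pattern_id Which stored pattern to present (default 1).
#' @param reverse Present the time-reversed pattern.
#' @param speed_factor Scale factor for the pattern replay speed (> 1 =
#'   faster, spike times compressed).
#' @param theta Optional firing-threshold override for the excitatory
#'   neurons during the test.
#' @param weights Optional list(w_ff, w_lat) overriding the record's final
#'   weights (e.g. a training snapshot).
#' @param gap Inter-presentation gap in ms (default 150).
#' @param seed Optional integer seed for the fresh test noise; defaults to
#'   the record's test stream.
#' @return An object of class `chain_test` with `spikes`, `onsets`,
#'   `pattern_duration`, `n_presentations` and `n_exc`.
#' @export
run_test <- function(record, n_presentations = 10, lateral_enabled = TRUE,
                     plasticity_frozen = TRUE, pattern_id = 1L,
                     reverse = FALSE, speed_factor = 1, theta = NULL,
                     weights = NULL, gap = 150, seed = NULL) {
  stopifnot(inherits(record, "sim_record"))
  cfg <- record$cfg
  if (speed_factor <= 0) stop("`speed_factor` must be positive")
  pat <- transform_pattern(record$patterns[[pattern_id]], cfg$dt,
                           speed_factor = speed_factor, reverse = reverse)
  dur <- pat$duration
  onsets <- 100 + (seq_len(n_presentations) - 1) * (dur + gap)
  schedule <- data.frame(onset = onsets, pattern = 1L)
  duration <- max(onsets) + dur + gap
  w <- if (is.null(weights)) {
    list(w_ff = record$w_ff, w_lat = record$w_lat)
  } else weights
  if (is.null(seed)) seed <- record$seeds[["test"]]
  sim <- run_sim(cfg, record$resolved, list(pat), schedule, w,
                 duration = duration, plastic = !plasticity_frozen,
                 lateral_scale = if (lateral_enabled) 1 else 0,
                 theta = theta, noise_seed = seed)
  structure(list(
    spikes = sim$spikes, onsets = onsets, pattern_duration = dur,
    n_presentations = n_presentations, n_exc = cfg$n_exc,
    lateral_enabled = lateral_enabled, speed_factor = speed_factor,
    reverse = reverse
  ), class = "chain_test")
}

#' Train on several interleaved patterns
#'
#' Identical to [run_training()] but with `n_patterns` distinct frozen
#' patterns presented in random non-overlapping order.
#'
#' @inheritParams run_training
#' @param n_patterns Number of distinct patterns (default 2).
#' @return A `sim_record` whose `patterns` field holds all patterns.
#' @export
run_multi_pattern_training <- function(cfg, n_patterns = 2L) {
  if (n_patterns < 1) stop("`n_patterns` must be at least 1")
  run_training(cfg, n_patterns = n_patterns)
}

#' Concatenation training: stitch two learnt chains together
#'
#' Continues training a network previously trained on two patterns, now
#' presenting the two patterns back-to-back (by default pattern 2
#' immediately followed by pattern 1) in every presentation slot. Lateral
#' plasticity links the tail of the first-presented chain to the head of the
#' second, forming one longer recognizer while the sub-chains remain usable.
#'
#' @param record A `sim_record` from [run_multi_pattern_training()].
#' @param duration Phase-2 training duration in ms (default 50000).
#' @param order Length-2 integer vector: presentation order of the two
#'   patterns within a slot (default `c(2, 1)`).
#' @param seed Optional integer seed for phase 2 (defaults to a stream
#'   derived from the record's master seed).
#' @return A new `sim_record` with the continued weights; `phase1` holds the
#'   input record.
#' @export
run_concatenation_training <- function(record, duration = 50000,
                                       order = c(2, 1), seed = NULL) {
  stopifnot(inherits(record, "sim_record"), length(order) == 2)
  if (length(record$patterns) < 2) {
    stop("`record` must come from training on at least two patterns")
  }
  cfg <- record$cfg
  if (duration == 0) {
    out <- record
    out$phase1 <- record
    return(out)
  }
  seeds2 <- spawn_seeds(record$seeds[["schedule"]] + 7L,
                        c("schedule", "noise"))
  if (!is.null(seed)) seeds2[] <- spawn_seeds(seed, c("schedule", "noise"))
  st <- cfg$stimulus
  dur <- st$pattern_duration
  # schedule slots of two back-to-back presentations; gaps are drawn for the
  # double-length slot so the minimum-gap invariant holds after the pair
  st2 <- st
  st2$pattern_duration <- 2 * dur
  base <- build_schedule(st2, n_patterns = 1L, seed = seeds2[["schedule"]],
                         total_duration = duration)
  schedule <- data.frame(
    onset = as.vector(rbind(base$onset, base$onset + dur)),
    pattern = rep(as.integer(order), length(base$onset)))
  sim <- run_sim(cfg, record$resolved, record$patterns, schedule,
                 list(w_ff = record$w_ff, w_lat = record$w_lat),
                 duration = duration, plastic = TRUE,
                 noise_seed = seeds2[["noise"]],
                 snapshot_every = cfg$snapshot_every)
  structure(list(
    cfg = cfg, seeds = record$seeds, resolved = record$resolved,
    patterns = record$patterns, schedule = schedule,
    spikes = sim$spikes, w_ff = sim$w_ff, w_lat = sim$w_lat,
    snapshots = sim$snapshots, phase1 = record, concat_order = order
  ), class = "sim_record")
}

#' Probe recognition robustness against input speed variations
#'
#' Determines the learnt chain (members and accepting neurons) from a
#' standard test, then presents the pattern with all spike times scaled by
#' `1 / speed_factor` and reports whether the sequence is still recognized.
#' Because firing requires threshold crossings on the brief rising edges of
#' the post-synaptic potentials, only small speed changes are tolerated; an
#' optional threshold override probes the compensation mechanism (a lower
#' threshold tolerates slower, stretched input and vice versa).
#'
#' @param record A trained `sim_record`.
#' @param speed_factor Pattern speed scale (> 1 = faster).
#' @param theta_override Optional excitatory threshold used during the
#'   scaled test.
#' @param n_presentations Presentations per test (default 10).
#' @return List with the scaled-test `recognition_rate` (fraction of
#'   presentations in which every chain member fired) and
#'   `accepting_rate` (accepting neuron(s) fired), the baseline
#'   `reference_rate` at speed 1, the member set, and the two `chain_test`
#'   objects.
#' @export
run_speed_variation_test <- function(record, speed_factor,
                                     theta_override = NULL,
                                     n_presentations = 10) {
  base <- run_test(record, n_presentations = n_presentations)
  rel <- compute_reliability(base)
  members <- assess_pattern_learnt(rel)$members
  if (!length(members)) {
    stop("no reliable chain members; train the network first")
  }
  graph <- extract_chain_graph(record, members = members, reliability = rel)
  scaled <- run_test(record, n_presentations = n_presentations,
                     speed_factor = speed_factor, theta = theta_override)
  list(
    speed_factor = speed_factor,
    recognition_rate = recognition_rate(scaled, members),
    accepting_rate = recognition_rate(scaled, graph$accepting),
    reference_rate = recognition_rate(base, members),
    members = members, accepting = graph$accepting,
    test = scaled, reference = base
  )
}
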