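# Stimulus generation: a frozen spatio-temporal spike pattern embedded in a
# statistically identical Poisson carrier, plus background noise on every
# afferent.
#
# Half of the afferents (the "pattern half") alternate between the frozen
# pattern and fresh Poisson spikes at the carrier rate; the other half carry
# continuous Poisson spikes. A low-rate Poisson background is superposed on
# all afferents at all times, so the per-afferent long-run rate is the same
# (carrier + background) everywhere and the pattern is statistically
# invisible in the rates.

#' Stimulus configuration
#'
#' Parameters of the afferent input: a frozen spatio-temporal spike pattern
#' repeatedly inserted into half of the afferents, embedded in Poisson
#' carrier spikes at the same rate, with Poisson background on all afferents.
#'
#' @param n_afferents Total number of afferents (default 2000).
#' @param n_pattern_afferents Number of afferents carrying the frozen pattern
#'   during presentations (default 1000, the first half).
#' @param carrier_rate Poisson rate of the carrier trains and of the frozen
#'   pattern itself, in Hz (default 54).
#' @param background_rate Poisson background rate superposed on every
#'   afferent at all times, in Hz (default 10).
#' @param pattern_duration Duration of the frozen pattern in ms (default 50).
#' @param min_gap Minimum gap between the end of one presentation and the
#'   next onset, in ms (default 50).
#' @param gap_mean_extra Mean of the exponential distribution added on top of
#'   `min_gap` when drawing inter-presentation gaps, in ms (default 50; gives
#'   a mean presentation cycle of about 150 ms and a pattern duty cycle of
#'   about one third).
#' @param total_duration Total stimulus duration in ms (default 200000).
#' @param dt Time step in ms used to discretize spike trains into binary
#'   per-bin spikes (default 0.1).
#' @param seed Optional integer seed; component streams (pattern, schedule,
#'   noise) are derived from it deterministically.
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(n_afferents = 2000, n_pattern_afferents = 1000,
                            carrier_rate = 54, background_rate = 10,
                            pattern_duration = 50, min_gap = 50,
                            gap_mean_extra = 50,
                            total_duration = 200000, dt = 0.1, seed = NULL) {
  stop_if_not_scalar_pos(n_afferents, "n_afferents")
  stop_if_not_scalar_pos(dt, "dt")
  stop_if_not_scalar_pos(total_duration, "total_duration")
  stop_if_not_scalar_pos(pattern_duration, "pattern_duration", strict = FALSE)
  stop_if_not_scalar_pos(min_gap, "min_gap", strict = FALSE)
  stop_if_not_scalar_pos(gap_mean_extra, "gap_mean_extra", strict = FALSE)
  stop_if_not_scalar_pos(carrier_rate, "carrier_rate", strict = FALSE)
  stop_if_not_scalar_pos(background_rate, "background_rate", strict = FALSE)
  if (n_pattern_afferents > n_afferents) {
    stop("`n_pattern_afferents` cannot exceed `n_afferents`")
  }
  structure(list(
    n_afferents = as.integer(n_afferents),
    n_pattern_afferents = as.integer(n_pattern_afferents),
    carrier_rate = carrier_rate, background_rate = background_rate,
    pattern_duration = pattern_duration, min_gap = min_gap,
    gap_mean_extra = gap_mean_extra,
    total_duration = total_duration, dt = dt,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "stimulus_config")
}

# per-bin spike probability for a rate in Hz
rate_to_p <- function(rate_hz, dt) rate_hz / 1000 * dt

#' Generate a frozen spatio-temporal spike pattern
#'
#' Draws one realization of independent Poisson trains at the carrier rate
#' over the pattern duration, one train per pattern afferent, discretized to
#' binary per-bin spikes. The result is immutable: the identical spike list
#' is re-inserted at every presentation.
#'
#' @param cfg A [stimulus_config()].
#' @param seed Integer seed for the pattern stream (defaults to a stream
#'   derived from `cfg$seed`).
#' @param stream Stream index, used to draw several distinct patterns from
#'   the same seed (default 1).
#' @return An object of class `frozen_pattern`: a list with `spikes` (a
#'   data.frame with 1-based `afferent` and `time` in ms), `duration`, and
#'   `n_afferents`.
#' @export
generate_pattern <- function(cfg, seed = NULL, stream = 1L) {
  stopifnot(inherits(cfg, "stimulus_config"))
  if (is.null(seed)) {
    if (is.null(cfg$seed)) stop("provide `seed` or set `cfg$seed`")
    seed <- spawn_seeds(cfg$seed, "pattern")[["pattern"]]
  }
  n_bins <- as.integer(round(cfg$pattern_duration / cfg$dt))
  p <- rate_to_p(cfg$carrier_rate, cfg$dt)
  raw <- .bernoulli_raster_cpp(cfg$n_pattern_afferents, n_bins, p,
                               as.integer(seed), as.integer(stream))
  ord <- order(raw$bin, raw$aff)
  structure(list(
    spikes = data.frame(afferent = raw$aff[ord] + 1L,
                        time = raw$bin[ord] * cfg$dt),
    duration = cfg$pattern_duration,
    n_afferents = cfg$n_pattern_afferents,
    dt = cfg$dt
  ), class = "frozen_pattern")
}

#' Build a presentation schedule
#'
#' Draws pattern onset times covering the whole stimulus duration. Gaps
#' between the end of one presentation and the next onset are
#' `min_gap + Exponential(mean = gap_mean_extra)`, so every gap satisfies the
#' minimum and the long-run pattern duty cycle stays below 50%.
#'
#' @param cfg A [stimulus_config()].
#' @param n_patterns Number of distinct patterns interleaved at random
#'   (uniformly, non-overlapping) over the presentation slots (default 1).
#' @param seed Integer seed for the schedule stream.
#' @param total_duration Override of `cfg$total_duration`.
#' @return An object of class `presentation_schedule`: a data.frame with
#'   columns `onset` (ms) and `pattern` (1-based pattern id), with the
#'   pattern duration and total duration as attributes.
#' @export
build_schedule <- function(cfg, n_patterns = 1L, seed = NULL,
                           total_duration = NULL) {
  stopifnot(inherits(cfg, "stimulus_config"))
  total <- if (is.null(total_duration)) cfg$total_duration else total_duration
  if (total <= cfg$pattern_duration + cfg$min_gap) {
    stop("`total_duration` too short to schedule a presentation plus a gap")
  }
  if (is.null(seed)) {
    if (is.null(cfg$seed)) stop("provide `seed` or set `cfg$seed`")
    seed <- spawn_seeds(cfg$seed, "schedule")[["schedule"]]
  }
  dur <- cfg$pattern_duration
  onsets <- with_seed(seed, {
    out <- numeric(0)
    t <- cfg$min_gap + stats::rexp(1, 1 / max(cfg$gap_mean_extra, 1e-12))
    while (t + dur <= total) {
      out <- c(out, t)
      t <- t + dur + cfg$min_gap +
        if (cfg$gap_mean_extra > 0) stats::rexp(1, 1 / cfg$gap_mean_extra) else 0
    }
    out
  })
  ids <- if (n_patterns > 1L) {
    with_seed(seed + 1L, sample.int(n_patterns, length(onsets), replace = TRUE))
  } else {
    rep(1L, length(onsets))
  }
  structure(data.frame(onset = onsets, pattern = ids),
            class = c("presentation_schedule", "data.frame"),
            pattern_duration = dur, total_duration = total)
}

#' Render the full afferent stimulus as a labeled spike raster
#'
#' Produces one realization of the shared input view: the noise half carries
#' continuous Poisson spikes at carrier + background rate; the pattern half
#' carries the frozen pattern during presentations and Poisson carrier spikes
#' between them, with background superposed throughout. Spikes falling in the
#' same bin on the same afferent are collapsed to one binary spike with label
#' precedence pattern > carrier > background.
#'
#' @param pattern A [generate_pattern()] result, or a list of them when the
#'   schedule interleaves several patterns.
#' @param schedule A [build_schedule()] result.
#' @param cfg A [stimulus_config()].
#' @param seed Integer seed for the noise stream.
#' @return An object of class `spike_raster`: a data.frame with columns
#'   `source` (1-based afferent), `time` (ms) and `label` (factor with
#'   levels pattern/carrier/background), with `n_sources` and `duration`
#'   attributes.
#' @export
render_stimulus <- function(pattern, schedule, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "stimulus_config"),
            inherits(schedule, "presentation_schedule"))
  if (inherits(pattern, "frozen_pattern")) pattern <- list(pattern)
  if (is.null(seed)) {
    if (is.null(cfg$seed)) stop("provide `seed` or set `cfg$seed`")
    seed <- spawn_seeds(cfg$seed, "noise")[["noise"]]
  }
  dt <- cfg$dt
  n_bins <- as.integer(round(cfg$total_duration / dt))
  n_pat <- cfg$n_pattern_afferents
  n_noise <- cfg$n_afferents - n_pat
  p_c <- rate_to_p(cfg$carrier_rate, dt)
  p_b <- rate_to_p(cfg$background_rate, dt)

  onset_bins <- as.integer(round(schedule$onset / dt))
  dur_bins <- as.integer(round(cfg$pattern_duration / dt))

  # background: all afferents, whole duration
  bg <- .bernoulli_raster_cpp(cfg$n_afferents, n_bins, p_b, seed, 1L)
  # continuous carrier on the noise half
  nc <- .bernoulli_raster_cpp(n_noise, n_bins, p_c, seed, 2L)
  nc$aff <- nc$aff + n_pat

  # carrier on the pattern half only between presentations: draw on the
  # concatenated gap timeline, then map back to absolute bins
  pres_start <- onset_bins
  pres_end <- onset_bins + dur_bins
  gap_start <- c(0L, pres_end)
  gap_end <- c(pres_start, n_bins)
  keep <- gap_end > gap_start
  gap_start <- gap_start[keep]; gap_end <- gap_end[keep]
  gap_len <- gap_end - gap_start
  gap_off <- cumsum(c(0L, gap_len[-length(gap_len)]))
  n_gap_bins <- sum(gap_len)
  gc_ <- .bernoulli_raster_cpp(n_pat, n_gap_bins, p_c, seed, 3L)
  if (length(gc_$bin)) {
    # segment containing each concatenated bin, then shift to absolute bins
    seg <- findInterval(gc_$bin, c(0, cumsum(gap_len)))
    gc_$bin <- gc_$bin - gap_off[seg] + gap_start[seg]
  }

  # frozen pattern spikes at each presentation
  pat_aff <- integer(0); pat_bin <- integer(0)
  for (i in seq_len(nrow(schedule))) {
    pp <- pattern[[schedule$pattern[i]]]
    rel <- as.integer(round(pp$spikes$time / dt))
    pat_aff <- c(pat_aff, pp$spikes$afferent - 1L)
    pat_bin <- c(pat_bin, rel + onset_bins[i])
  }

  aff <- c(pat_aff, nc$aff, gc_$aff, bg$aff)
  bin <- c(pat_bin, nc$bin, gc_$bin, bg$bin)
  lab <- rep.int(c(1L, 2L, 2L, 3L),
                 c(length(pat_aff), length(nc$aff), length(gc_$aff), length(bg$aff)))

  # collapse duplicates with precedence pattern > carrier > background
  # (input vectors are already grouped by precedence)
  id <- as.numeric(aff) * n_bins + bin
  dup <- duplicated(id)
  aff <- aff[!dup]; bin <- bin[!dup]; lab <- lab[!dup]
  ord <- order(bin, aff)

  structure(data.frame(
    source = aff[ord] + 1L,
    time = bin[ord] * dt,
    label = factor(c("pattern", "carrier", "background")[lab[ord]],
                   levels = c("pattern", "carrier", "background"))
  ), class = c("spike_raster", "data.frame"),
  n_sources = cfg$n_afferents, duration = cfg$total_duration)
}

#' Fraction of noise spikes in a labeled raster
#'
#' Returns the proportion of spikes labeled carrier or background (as opposed
#' to frozen-pattern spikes). Under the default configuration this exceeds
#' 0.75: half of the afferents never carry the pattern, the pattern is
#' presented for under half of the time on the other half, and background
#' spikes land everywhere.
#'
#' @param raster A labeled [render_stimulus()] raster.
#' @return A proportion in \[0, 1\].
#' @export
label_noise_fraction <- function(raster) {
  if (!inherits(raster, "spike_raster") || is.null(raster$label)) {
    stop("`raster` must be a labeled spike_raster")
  }
  mean(raster$label != "pattern")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d events, %d sources, %.1f ms\n",
              nrow(x), attr(x, "n_sources"), attr(x, "duration")))
  invisible(x)
}

#' @export
print.frozen_pattern <- function(x, ...) {
  cat(sprintf("<frozen_pattern> %d spikes on %d afferents over %.1f ms\n",
              nrow(x$spikes), x$n_afferents, x$duration))
  invisible(x)
}
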