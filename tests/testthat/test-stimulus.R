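# Stimulus generator: frozen pattern, presentation schedule, rendered raster.

test_that("frozen pattern is a carrier-rate Poisson draw, immutable under seed", {
  cfg <- stimulus_config(seed = 7)
  pat <- generate_pattern(cfg)
  expected <- 1000 * 54 / 1000 * 50  # afferents x rate x duration
  expect_lt(abs(nrow(pat$spikes) - expected), 3 * sqrt(expected))
  expect_true(all(pat$spikes$time >= 0 & pat$spikes$time < cfg$pattern_duration))
  expect_true(all(pat$spikes$afferent >= 1 &
                    pat$spikes$afferent <= cfg$n_pattern_afferents))
  expect_identical(pat, generate_pattern(cfg))
  expect_false(identical(pat$spikes, generate_pattern(cfg, stream = 2)$spikes))
})

test_that("zero-duration pattern is empty", {
  cfg <- stimulus_config(pattern_duration = 0, seed = 1)
  expect_equal(nrow(generate_pattern(cfg)$spikes), 0)
})

test_that("schedule keeps minimum gaps and a bounded duty cycle", {
  cfg <- stimulus_config(total_duration = 10000, seed = 11)
  sch <- build_schedule(cfg)
  expect_true(all(diff(sch$onset) - cfg$pattern_duration >= cfg$min_gap))
  duty <- nrow(sch) * cfg$pattern_duration / cfg$total_duration
  expect_lte(duty, 0.5)
  # at most total/(duration+gap) presentations fit
  short <- build_schedule(cfg, total_duration = 1000)
  expect_lte(nrow(short), 10)
  expect_error(build_schedule(cfg, total_duration = 60), "too short")
})

test_that("rendered raster has the right rates, labels and frozen pattern", {
  cfg <- stimulus_config(total_duration = 20000, seed = 42)
  pat <- generate_pattern(cfg)
  sch <- build_schedule(cfg)
  ras <- render_stimulus(pat, sch, cfg)

  mean_rate <- nrow(ras) / cfg$n_afferents / (cfg$total_duration / 1000)
  expect_lt(abs(mean_rate - 64), 1)

  expect_gte(label_noise_fraction(ras), 0.75)

  # pattern-labeled events in a presentation window are exactly the frozen
  # pattern, shifted to the (bin-aligned) onset
  on_bin <- round(sch$onset[3] / cfg$dt) * cfg$dt
  sub <- ras[ras$time >= on_bin & ras$time < on_bin + cfg$pattern_duration &
               ras$label == "pattern", ]
  got <- sub[order(sub$time, sub$source), ]
  want <- pat$spikes[order(pat$spikes$time, pat$spikes$afferent), ]
  expect_equal(got$source, want$afferent)
  expect_equal(got$time - on_bin, want$time, tolerance = 1e-9)

  # reproducibility
  ras2 <- render_stimulus(pat, sch, cfg)
  expect_identical(ras, ras2)
})

test_that("noise fraction handles trivial and degenerate rasters", {
  mk <- function(labels) {
    structure(data.frame(source = seq_along(labels), time = seq_along(labels),
                         label = factor(labels, levels = c("pattern", "carrier",
                                                           "background"))),
              class = c("spike_raster", "data.frame"),
              n_sources = 10, duration = 100)
  }
  expect_equal(label_noise_fraction(mk(c("carrier", "background", "carrier",
                                         "pattern"))), 0.75)
  expect_equal(label_noise_fraction(mk(rep("carrier", 5))), 1.0)
  unlabeled <- structure(data.frame(source = 1, time = 1),
                         class = c("spike_raster", "data.frame"))
  expect_error(label_noise_fraction(unlabeled), "labeled")
})

test_that("stimulus configuration is validated", {
  expect_error(stimulus_config(n_afferents = -1), "positive")
  expect_error(stimulus_config(n_pattern_afferents = 3000), "exceed")
  expect_error(stimulus_config(carrier_rate = -5), "non-negative")
})
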