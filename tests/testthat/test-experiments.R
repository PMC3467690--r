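# Experiment drivers, configuration echo, fixtures.

test_that("config echo round-trips into an identical run", {
  cfg <- network_config(
    n_exc = 5, train_duration = 5000,
    stimulus = stimulus_config(n_afferents = 200, n_pattern_afferents = 100),
    snapshot_every = 0, seed = 9)
  echo <- config_echo(cfg)
  # through JSON, as written next to suite outputs
  json <- jsonlite::fromJSON(jsonlite::toJSON(echo, auto_unbox = TRUE,
                                              digits = NA, null = "null"))
  cfg2 <- config_from_echo(json)
  r1 <- run_training(cfg)
  r2 <- run_training(cfg2)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$w_ff, r2$w_ff)
})

test_that("unknown experiment ids are rejected with the valid list", {
  expect_error(run_suite("frobnicate", n_seeds = 1), "train-nn")
})

test_that("the scaled-down preset shrinks stimulus and duration", {
  cfg <- fast_preset(network_config())
  expect_equal(cfg$stimulus$n_afferents, 500L)
  expect_equal(cfg$stimulus$n_pattern_afferents, 250L)
  expect_equal(cfg$train_duration, 50000)
  # bound and rates follow the smaller pattern-afferent count
  res <- spikechain:::resolve_config(cfg)
  expect_equal(res$wp_max, compute_wmax_ff(a_const = cfg$a_const,
                                           n_input = 250))
})

test_that("suite outputs include a reproducible config echo", {
  out_dir <- withr::local_tempdir()
  cfg <- network_config(
    n_exc = 4, train_duration = 3000,
    stimulus = stimulus_config(n_afferents = 100, n_pattern_afferents = 50),
    snapshot_every = 0, seed = 2)
  s <- run_suite("train-nn", n_seeds = 1, cfg = cfg, out_dir = out_dir)
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  expect_true(file.exists(file.path(out_dir, "config.json")))
  echo <- jsonlite::read_json(file.path(out_dir, "config.json"),
                              simplifyVector = TRUE)
  cfg2 <- config_from_echo(echo)
  cfg2$seed <- cfg$seed + 1L  # trial 1 seed
  expect_identical(run_training(cfg2)$spikes, s$trials[[1]]$record$spikes)
})

test_that("raster and weight CSV round-trips preserve the data", {
  path <- withr::local_tempfile(fileext = ".csv")
  cfg <- stimulus_config(n_afferents = 50, n_pattern_afferents = 25,
                         total_duration = 2000, seed = 4)
  ras <- render_stimulus(generate_pattern(cfg), build_schedule(cfg), cfg)
  write_raster_csv(ras, path)
  back <- read_raster_csv(path, n_sources = 50, duration = 2000)
  expect_equal(back$source, ras$source)
  expect_equal(back$time, ras$time)
  expect_equal(as.character(back$label), as.character(ras$label))
})

test_that("chain graph exports list every member and edge", {
  wl <- matrix(0, 4, 4); wl[1, 2] <- 30; wl[2, 3] <- 20
  g <- extract_chain_graph(w_lat = wl, wl_max = 50, members = 1:3)
  dot <- withr::local_tempfile(fileext = ".dot")
  write_chain_dot(g, dot)
  txt <- readLines(dot)
  expect_true(any(grepl("doublecircle", txt)))  # accepting neuron
  expect_length(grep("->", txt), 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_chain_edges_csv(g, csv)
  expect_equal(nrow(utils::read.csv(csv)), 2)
})
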