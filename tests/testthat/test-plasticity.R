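# STDP: window formulas, weight bound, oracle/trace equivalence,
# normalization, initialization.

test_that("feed-forward weight bound follows the threshold/rate/step formula", {
  # theta/(tau_m * r * dt) * A / N with times in ms, r in spikes/ms
  expect_equal(compute_wmax_ff(1, 10, 64, 0.1, 20, 1000), 0.3125)
  expect_equal(compute_wmax_ff(1, 10, 64, 0.1, 20, 1), 312.5)
  # binary one-step spikes: halving dt doubles the bound
  expect_equal(compute_wmax_ff(dt = 0.05), 2 * compute_wmax_ff(dt = 0.1))
  expect_error(compute_wmax_ff(mean_rate = 0), "positive")
})

test_that("learning rates scale with the class bound, depression dominant", {
  lr <- compute_learning_rates(1)
  expect_equal(lr$a_p, 0.002)
  expect_equal(lr$a_d, -0.002 * 1.05)
  lr2 <- compute_learning_rates(0.035625)
  expect_equal(lr2$a_p, 7.125e-5)
  # tau_p = tau_d implies a_d = -1.05 a_p regardless of scale
  lr3 <- compute_learning_rates(50, tau_p = 20, tau_d = 20)
  expect_equal(lr3$a_d / lr3$a_p, -1.05)
})

test_that("pair-sum oracle reproduces hand-computed pairings", {
  pr <- stdp_params(a_p = 1, mode = "all_to_all")
  # single pre->post pair at 10 ms
  expect_equal(pair_sum_oracle(0, 10, pr), exp(-0.5))
  # no post spikes: nothing happens
  expect_equal(pair_sum_oracle(c(0, 0), numeric(0), pr), 0)
  # coincident pre/post counts as potentiation at full amplitude
  expect_equal(pair_sum_oracle(5, 5, stdp_params(a_p = 1)), 1)
  # all-to-all potentiation sums over both pre spikes
  expect_equal(pair_sum_oracle(c(95, 75), 100, pr),
               exp(-0.25) + exp(-1.25))
  # all-to-all depression sums over both earlier posts
  expect_equal(pair_sum_oracle(100, c(90, 70), pr),
               pr$a_d * (exp(-0.5) + exp(-1.5)))
  # nearest-neighbor potentiation keeps only the most recent pre
  nn <- stdp_params(a_p = 1, mode = "nearest_neighbor")
  expect_equal(pair_sum_oracle(c(95, 75), 100, nn), exp(-0.25))
  # nearest-post depression: single post paired with its following pre
  expect_equal(pair_sum_oracle(20, 0, nn), nn$a_d * exp(-1))
  # all-post depression variant pairs the pre with every earlier post
  nna <- stdp_params(a_p = 1, mode = "nearest_neighbor",
                     nn_depression = "all_post")
  expect_equal(pair_sum_oracle(100, c(90, 70), nna),
               nna$a_d * (exp(-0.5) + exp(-1.5)))
})

test_that("online trace updates equal the pair-sum oracle on random trains", {
  withr::with_seed(99, {
    for (rep in 1:12) {
      pre <- random_train(sample(5:25, 1))
      post <- random_train(sample(5:25, 1))
      for (mode in c("all_to_all", "nearest_neighbor")) {
        for (dep in c("nearest_post", "all_post")) {
          pr <- stdp_params(a_p = 0.01, mode = mode, nn_depression = dep)
          expect_equal(stdp_trace_deltas(pre, post, pr),
                       pair_sum_oracle(pre, post, pr),
                       tolerance = 1e-9)
        }
      }
    }
  })
})

test_that("nearest-neighbor potentiation never exceeds all-to-all", {
  withr::with_seed(123, {
    for (rep in 1:8) {
      pre <- random_train(20)
      post <- random_train(15)
      # negligible depression isolates the potentiation side
      a2a <- stdp_params(a_p = 1, a_d = -1e-300, mode = "all_to_all")
      nn <- stdp_params(a_p = 1, a_d = -1e-300, mode = "nearest_neighbor")
      expect_lte(pair_sum_oracle(pre, post, nn),
                 pair_sum_oracle(pre, post, a2a) + 1e-12)
    }
  })
})

test_that("uncorrelated Poisson trains are depressed on average", {
  # expected pairing integral is negative by the 1.05 margin
  withr::with_seed(7, {
    deltas <- vapply(1:40, function(i) {
      pre <- random_train(64, t_max = 1000)
      post <- random_train(30, t_max = 1000)
      pair_sum_oracle(pre, post, stdp_params(a_p = 1e-3))
    }, numeric(1))
    expect_lt(mean(deltas), 0)
  })
})

test_that("lateral normalization rescales proportionally above the bound", {
  expect_equal(normalize_lateral(c(30, 30), 50), c(25, 25))
  expect_equal(normalize_lateral(c(10, 20), 50), c(10, 20))
  expect_equal(normalize_lateral(c(50, 50, 0), 50), c(25, 25, 0))
  expect_error(normalize_lateral(c(-1, 2), 50), "non-negative")
  # proportions preserved
  w <- c(5, 15, 40)
  out <- normalize_lateral(w, 30)
  expect_equal(sum(out), 30)
  expect_equal(out / sum(out), w / sum(w))
})

test_that("initial weights are uniform within bounds, zero self-connections", {
  w <- init_weights(2000, 20, 0.2, 50, seed = 5)
  expect_true(all(w$w_ff >= 0 & w$w_ff <= 0.2))
  expect_equal(mean(w$w_ff), 0.1, tolerance = 0.01)
  expect_true(all(diag(w$w_lat) == 0))
  expect_true(all(w$w_lat >= 0 & w$w_lat <= 50 / 20))
  # initial incoming lateral sums stay below the bound
  expect_true(all(colSums(w$w_lat) <= (20 - 1) * 50 / 20))
  expect_identical(w, init_weights(2000, 20, 0.2, 50, seed = 5))
})
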