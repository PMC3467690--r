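# LIF + alpha-synapse dynamics: Euler integration against closed forms.

test_that("membrane decays exponentially without input", {
  p <- neuron_params()
  k <- synapse_kinetics()
  state <- list(v = 0.5, s_r = c(ff = 0, inh = 0), s_f = c(ff = 0, inh = 0))
  n <- 100  # 10 ms
  for (i in seq_len(n)) state <- lif_step(state, c(ff = 0), p, k)
  expect_equal(state$v, 0.5 * exp(-1), tolerance = 0.01)
})

test_that("constant drive converges to the DC gain and triggers reset", {
  p <- neuron_params()
  k <- synapse_kinetics()
  # drive below threshold: V approaches I0 (unit DC gain through both
  # filter stages and the membrane)
  i0 <- 0.8
  sim <- simulate_neuron(seq(0, 100, by = p$dt), i0, duration = 100,
                         params = p, kinetics = k)
  expect_equal(sim$v[length(sim$v)], i0, tolerance = 0.01)
  expect_length(sim$spikes, 0)
  # drive above threshold: fires, and v is reset to exactly 0 on that step
  sim2 <- simulate_neuron(seq(0, 100, by = p$dt), 1.5, duration = 100,
                          params = p, kinetics = k)
  expect_gt(length(sim2$spikes), 0)
  first_bin <- round(sim2$spikes[1] / p$dt) + 1
  expect_identical(sim2$v[first_bin], 0)
})

test_that("steady filter state has unit DC gain per stage", {
  p <- neuron_params()
  k <- synapse_kinetics()
  state <- list(v = 0.3, s_r = c(ff = 0.3), s_f = c(ff = 0.3))
  out <- lif_step(state, c(ff = 0.3), p, k)
  expect_equal(out$s_r[["ff"]], 0.3)
  expect_equal(out$s_f[["ff"]], 0.3)
  expect_equal(out$v, 0.3)
})

test_that("closed-form PSP matches the Euler trajectory to first order", {
  p <- neuron_params()
  k <- synapse_kinetics()
  w <- 10
  sim <- simulate_neuron(0, w, duration = 60, params = p, kinetics = k,
                         threshold_active = FALSE)
  ana <- psp_closed_form(sim$time, w, p, k)
  err1 <- max(abs(sim$v - ana))
  peak <- psp_peak(w, p, k)
  expect_equal(max(sim$v), peak$v_peak, tolerance = 0.05)
  expect_equal(sim$time[which.max(sim$v)], peak$t_peak, tolerance = 1)

  # halving dt at least halves the maximum deviation (the forward-Euler
  # O(dt) bound; in this configuration the step error largely cancels
  # against the one-step pulse alignment, so the observed ratio is ~4)
  p2 <- neuron_params(dt = 0.05)
  sim2 <- simulate_neuron(0, w, duration = 60, params = p2, kinetics = k,
                          threshold_active = FALSE)
  err2 <- max(abs(sim2$v - psp_closed_form(sim2$time, w, p2, k)))
  expect_gt(err1 / err2, 1.8)

  # causality and stability of the closed form
  expect_identical(psp_closed_form(0, w, p, k), 0)
  expect_lt(psp_closed_form(500, w, p, k), 1e-12)
})

test_that("subthreshold response is exactly linear in the input", {
  p <- neuron_params()
  k <- synapse_kinetics()
  a <- simulate_neuron(5, 3, duration = 50, params = p, kinetics = k,
                       threshold_active = FALSE)
  b <- simulate_neuron(12, 4, duration = 50, params = p, kinetics = k,
                       threshold_active = FALSE)
  ab <- simulate_neuron(c(5, 12), c(3, 4), duration = 50, params = p,
                        kinetics = k, threshold_active = FALSE)
  expect_equal(ab$v, a$v + b$v, tolerance = 1e-12)
})

test_that("inputs are validated", {
  p <- neuron_params()
  k <- synapse_kinetics()
  state <- list(v = 0, s_r = c(ff = 0), s_f = c(ff = 0))
  expect_error(lif_step(state, c(ff = NaN), p, k), "finite")
  expect_error(synapse_kinetics(tau_r = 5, tau_f = 5), "differ")
  expect_error(neuron_params(dt = 20), "smaller")
  expect_error(psp_closed_form(1, 1, neuron_params(tau_m = 5),
                               synapse_kinetics(tau_r = 1, tau_f = 5)),
               "distinct")
})
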