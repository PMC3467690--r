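# Leaky integrate-and-fire dynamics with alpha-function synapses.
#
# The membrane follows tau_m dV/dt = -V + S_f with reset to 0 at threshold;
# each synaptic channel is a cascade of two first-order low-pass stages,
# tau_r dS_r/dt = -S_r + I and tau_f dS_f/dt = -S_f + S_r, driven by binary
# spikes of height w lasting one integration step. Integration is plain
# forward Euler: all state updates within a step use start-of-step values,
# then thresholds are applied.
#
# This R implementation is the reference for the compiled network simulator;
# it handles a single neuron and is used by the tests and to derive the
# static winner-takes-all loop weights.

#' Neuron parameters
#'
#' @param tau_m Membrane time constant in ms (default 10).
#' @param theta Firing threshold (default 1); the membrane is reset to
#'   `v_reset` when `V >= theta`.
#' @param v_reset Reset potential (default 0).
#' @param dt Forward-Euler integration step in ms (default 0.1).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 10, theta = 1, v_reset = 0, dt = 0.1) {
  stop_if_not_scalar_pos(tau_m, "tau_m")
  stop_if_not_scalar_pos(dt, "dt")
  if (dt >= tau_m) stop("`dt` must be much smaller than `tau_m`")
  structure(list(tau_m = tau_m, theta = theta, v_reset = v_reset, dt = dt),
            class = "neuron_params")
}

#' Alpha-synapse kinetics
#'
#' @param tau_r Rise time constant in ms (default 1).
#' @param tau_f Fall (decay) time constant in ms (default 5).
#' @return An object of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(tau_r = 1, tau_f = 5) {
  stop_if_not_scalar_pos(tau_r, "tau_r")
  stop_if_not_scalar_pos(tau_f, "tau_f")
  if (tau_r == tau_f) stop("`tau_r` and `tau_f` must differ")
  structure(list(tau_r = tau_r, tau_f = tau_f), class = "synapse_kinetics")
}

#' One forward-Euler step of a LIF neuron with grouped alpha synapses
#'
#' Advances a neuron state by one step. `input` is the summed weighted spike
#' input per channel group for this step; the `inh` group enters the membrane
#' equation with a negative sign.
#'
#' @param state List with `v` (scalar) and `s_r`, `s_f` (named numeric
#'   vectors over channel groups, e.g. `c(ff = 0, lat = 0, inh = 0)`).
#' @param input Named numeric vector of summed weighted spikes per channel
#'   group (missing groups count as 0).
#' @param params A [neuron_params()].
#' @param kinetics A [synapse_kinetics()].
#' @return The updated state, with logical `fired` set for this step.
#' @export
lif_step <- function(state, input, params, kinetics) {
  if (any(!is.finite(input))) stop("non-finite synaptic input")
  groups <- names(state$s_r)
  inp <- stats::setNames(numeric(length(groups)), groups)
  if (length(input)) inp[names(input)] <- input
  sgn <- ifelse(groups == "inh", -1, 1)
  dt <- params$dt
  v_new <- state$v + dt / params$tau_m * (-state$v + sum(sgn * state$s_f))
  s_r_new <- state$s_r + dt / kinetics$tau_r * (-state$s_r + inp)
  s_f_new <- state$s_f + dt / kinetics$tau_f * (-state$s_f + state$s_r)
  fired <- v_new >= params$theta
  if (fired) v_new <- params$v_reset
  list(v = v_new, s_r = s_r_new, s_f = s_f_new, fired = fired)
}

#' Simulate a single neuron driven by weighted input spikes
#'
#' Reference forward-Euler simulation of one LIF neuron with one excitatory
#' and (optionally) one inhibitory alpha-synapse channel. Spikes are binary
#' pulses of height `weight` lasting one step.
#'
#' @param spike_times Numeric vector of input spike times in ms.
#' @param spike_weights Numeric vector of weights (recycled); negative
#'   weights are routed through the inhibitory channel.
#' @param duration Simulation length in ms.
#' @param params A [neuron_params()].
#' @param kinetics A [synapse_kinetics()].
#' @param threshold_active If `FALSE`, the threshold/reset is disabled so the
#'   subthreshold trajectory can be compared against closed forms.
#' @return A list with `time`, `v` (membrane trace sampled after each step)
#'   and `spikes` (output spike times in ms).
#' @export
simulate_neuron <- function(spike_times, spike_weights = 1, duration,
                            params = neuron_params(),
                            kinetics = synapse_kinetics(),
                            threshold_active = TRUE) {
  dt <- params$dt
  n <- as.integer(round(duration / dt))
  spike_weights <- rep_len(spike_weights, length(spike_times))
  bins <- as.integer(floor(spike_times / dt)) + 1L
  ok <- bins >= 1L & bins <= n
  i_exc <- numeric(n); i_inh <- numeric(n)
  for (k in which(ok)) {
    w <- spike_weights[k]
    if (w >= 0) i_exc[bins[k]] <- i_exc[bins[k]] + w
    else i_inh[bins[k]] <- i_inh[bins[k]] - w
  }
  v <- numeric(n)
  out <- numeric(0)
  sr_e <- sf_e <- sr_i <- sf_i <- 0
  vv <- 0
  cr <- dt / kinetics$tau_r; cf <- dt / kinetics$tau_f; cm <- dt / params$tau_m
  for (t in seq_len(n)) {
    v_new <- vv + cm * (-vv + sf_e - sf_i)
    sr_e_new <- sr_e + cr * (-sr_e + i_exc[t])
    sf_e_new <- sf_e + cf * (-sf_e + sr_e)
    sr_i_new <- sr_i + cr * (-sr_i + i_inh[t])
    sf_i_new <- sf_i + cf * (-sf_i + sr_i)
    if (threshold_active && v_new >= params$theta) {
      out <- c(out, (t - 1L) * dt)
      v_new <- params$v_reset
    }
    vv <- v_new; sr_e <- sr_e_new; sf_e <- sf_e_new
    sr_i <- sr_i_new; sf_i <- sf_i_new
    v[t] <- vv
  }
  list(time = seq_len(n) * dt, v = v, spikes = out)
}

#' Closed-form post-synaptic potential of the filter cascade
#'
#' Exact response of the linear cascade V <- S_f <- S_r to a single binary
#' spike of weight `w` lasting one step (approximated as an impulse of area
#' `w * dt` into the rise stage):
#' \deqn{V(t) = w\,dt \sum_i \frac{e^{-t/\tau_i}}{\tau_i}
#'       \prod_{j \ne i} \frac{\tau_i}{\tau_i - \tau_j}}
#' over the three distinct time constants (rise, fall, membrane). Serves as
#' the analytic oracle for the forward-Euler integration, which matches it to
#' first order in `dt`.
#'
#' @param t Time(s) since the spike, in ms (vectorized).
#' @param w Synaptic weight.
#' @param params A [neuron_params()].
#' @param kinetics A [synapse_kinetics()].
#' @return Membrane potential value(s); 0 for `t <= 0`.
#' @export
psp_closed_form <- function(t, w = 1, params = neuron_params(),
                            kinetics = synapse_kinetics()) {
  taus <- c(kinetics$tau_r, kinetics$tau_f, params$tau_m)
  if (anyDuplicated(taus)) {
    stop("closed form requires pairwise distinct time constants")
  }
  coef <- vapply(seq_along(taus), function(i) {
    prod(taus[i] / (taus[i] - taus[-i])) / taus[i]
  }, numeric(1))
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    out[pos] <- w * params$dt *
      colSums(coef * exp(-outer(1 / taus, t[pos])))
  }
  out
}

#' Peak of the single-spike post-synaptic potential
#'
#' @inheritParams psp_closed_form
#' @return List with `t_peak` (ms) and `v_peak`.
#' @export
psp_peak <- function(w = 1, params = neuron_params(),
                     kinetics = synapse_kinetics()) {
  horizon <- 5 * max(params$tau_m, kinetics$tau_f)
  opt <- stats::optimize(function(t) psp_closed_form(t, w, params, kinetics),
                         interval = c(0, horizon), maximum = w > 0)
  if (w > 0) list(t_peak = opt$maximum, v_peak = opt$objective)
  else list(t_peak = opt$minimum, v_peak = opt$objective)
}
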