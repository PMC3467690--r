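# Additive exponential STDP: pairing window, learning-rate and weight-bound
# formulas, trace-based online evaluation, brute-force pair-sum oracle, and
# lateral weight-sum normalization.
#
# Potentiation pairs (pre before or at post) use the window
# A_p * exp(-tau/tau_p); depression pairs (pre after post) use
# A_d * exp(tau/tau_d) with A_d < 0. Depression slightly dominates
# (|A_d * tau_d| = 1.05 * |A_p * tau_p|), so uncorrelated Poisson input
# depresses synapses on average. The two pairing schemes differ in how many
# presynaptic spikes are considered: all-to-all sums over every pre/post
# pair (exponential traces); nearest-neighbor potentiates each postsynaptic
# spike only from the nearest pre spike at-or-before it. The depression
# side of nearest-neighbor pairing is configurable: "nearest_post"
# (default) pairs each post spike only with the nearest pre after it,
# preserving the exact 1.05 balance for uncorrelated trains; "all_post"
# depresses every pre spike by the full postsynaptic trace, which makes
# uncorrelated input strongly net-depressing.

#' STDP parameters
#'
#' @param a_p Potentiation amplitude (> 0).
#' @param a_d Depression amplitude (< 0); defaults to
#'   `-a_p * (tau_p / tau_d) * 1.05` so that total depression slightly
#'   outweighs total potentiation.
#' @param tau_p,tau_d Potentiation/depression window time constants in ms
#'   (default 20 each).
#' @param mode `"nearest_neighbor"` (each post spike pairs with the most
#'   recent pre spike only) or `"all_to_all"` (sum over all pairs).
#' @param nn_depression Depression pairing in nearest-neighbor mode:
#'   `"nearest_post"` (default; each post spike pairs only with the nearest
#'   pre spike after it, preserving the exact 1.05 balance of the pairing
#'   window for uncorrelated trains) or `"all_post"` (every post/pre pair
#'   with the pre after the post contributes, via the postsynaptic trace).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(a_p, a_d = NULL, tau_p = 20, tau_d = 20,
                        mode = c("nearest_neighbor", "all_to_all"),
                        nn_depression = c("nearest_post", "all_post")) {
  mode <- match.arg(mode)
  nn_depression <- match.arg(nn_depression)
  stop_if_not_scalar_pos(a_p, "a_p")
  stop_if_not_scalar_pos(tau_p, "tau_p")
  stop_if_not_scalar_pos(tau_d, "tau_d")
  if (is.null(a_d)) a_d <- -a_p * (tau_p / tau_d) * 1.05
  if (a_d >= 0) stop("`a_d` must be negative")
  structure(list(a_p = a_p, a_d = a_d, tau_p = tau_p, tau_d = tau_d,
                 mode = mode, nn_depression = nn_depression),
            class = "stdp_params")
}

#' STDP pairing window
#'
#' The weight change contributed by a single pre/post pair at temporal
#' distance `tau = t_post - t_pre`: potentiation `a_p * exp(-tau/tau_p)` for
#' `tau >= 0`, depression `a_d * exp(tau/tau_d)` for `tau < 0`.
#'
#' @param tau Temporal distance(s) `t_post - t_pre` in ms.
#' @param params A [stdp_params()].
#' @return Weight change(s).
#' @export
stdp_window <- function(tau, params) {
  ifelse(tau >= 0, params$a_p * exp(-tau / params$tau_p),
         params$a_d * exp(tau / params$tau_d))
}

#' Maximum feed-forward synaptic weight for Poisson afferents
#'
#' Sets the per-synapse cap on feed-forward weights from the firing
#' threshold, the membrane time constant, the mean afferent rate, the
#' integration step and the number of pattern-carrying afferents:
#' \deqn{W^P_{max} = \frac{\theta}{\tau_m \langle r\rangle\, dt}
#'       \cdot \frac{A}{N_{input}}}
#' with times in ms and the rate converted to spikes/ms. The `1/dt` factor
#' compensates the binary one-step spike convention (shorter steps inject
#' proportionally less charge per spike); the constant `A` modulates the
#' overall maximal synaptic strength. At the defaults this puts a fully
#' potentiated afferent set at a mean drive of the order of the threshold,
#' so a trained neuron fires reliably on its pattern segment while random
#' input alone produces only occasional spikes.
#'
#' @param theta Firing threshold (default 1).
#' @param tau_m Membrane time constant in ms (default 10).
#' @param mean_rate Mean afferent rate in Hz (default 64 = carrier +
#'   background).
#' @param dt Integration step in ms (default 0.1).
#' @param a_const Strength-modulating constant `A` (default 20).
#' @param n_input Number of pattern-carrying afferents (default 1000).
#' @return The weight bound (scalar).
#' @export
compute_wmax_ff <- function(theta = 1, tau_m = 10, mean_rate = 64, dt = 0.1,
                            a_const = 20, n_input = 1000) {
  for (v in c(theta, tau_m, mean_rate, dt, a_const, n_input)) {
    stop_if_not_scalar_pos(v, "all arguments")
  }
  r_ms <- mean_rate / 1000
  theta / (tau_m * r_ms * dt) * a_const / n_input
}

#' Learning rates from a weight bound
#'
#' `a_p = 0.002 * w_max`; `a_d = -a_p * (tau_p / tau_d) * 1.05`. Applied per
#' synapse class with that class's weight bound, so lateral synapses (bound
#' `W^L_max`) learn on the same relative scale as feed-forward ones
#' (bound `W^P_max`).
#'
#' @param w_max Weight bound of the synapse class.
#' @param tau_p,tau_d STDP window time constants in ms.
#' @return List with `a_p` and `a_d`.
#' @export
compute_learning_rates <- function(w_max, tau_p = 20, tau_d = 20) {
  stop_if_not_scalar_pos(w_max, "w_max")
  a_p <- 0.002 * w_max
  list(a_p = a_p, a_d = -a_p * (tau_p / tau_d) * 1.05)
}

#' Brute-force pair-sum STDP oracle
#'
#' Evaluates the total weight change for given pre- and postsynaptic spike
#' trains by explicit double loop over spike pairs. In `all_to_all` mode
#' every pre/post pair contributes. In `nearest_neighbor` mode each
#' postsynaptic spike is potentiated only by the nearest pre spike
#' at-or-before it; the depression side follows `nn_depression`: all
#' post/pre pairs (`"all_post"`) or only the nearest pre strictly after
#' each post (`"nearest_post"`). Intended as an independent reference for
#' the online trace implementation.
#'
#' @param pre,post Numeric vectors of spike times in ms.
#' @param params A [stdp_params()].
#' @return Total weight change (scalar).
#' @export
pair_sum_oracle <- function(pre, post, params) {
  delta <- 0
  for (tp in post) {
    before <- pre[pre <= tp]
    if (length(before)) {
      if (params$mode == "nearest_neighbor") {
        delta <- delta + params$a_p * exp(-(tp - max(before)) / params$tau_p)
      } else {
        delta <- delta + sum(params$a_p * exp(-(tp - before) / params$tau_p))
      }
    }
  }
  nearest_dep <- params$mode == "nearest_neighbor" &&
    identical(params$nn_depression, "nearest_post")
  if (nearest_dep) {
    for (tp in post) {
      after <- pre[pre > tp]
      if (length(after)) {
        delta <- delta + params$a_d * exp(-(min(after) - tp) / params$tau_d)
      }
    }
  } else {
    for (tq in pre) {
      earlier <- post[post < tq]
      if (length(earlier)) {
        delta <- delta + sum(params$a_d * exp(-(tq - earlier) / params$tau_d))
      }
    }
  }
  delta
}

#' Online trace-based STDP evaluation
#'
#' Event-driven implementation using exponential traces, as run inside the
#' network simulator: a presynaptic trace (time constant `tau_p`,
#' incremented at pre spikes) read out at post spikes for potentiation, and
#' a postsynaptic trace (time constant `tau_d`, incremented at post spikes)
#' read out at pre spikes for depression. In nearest-neighbor mode the
#' potentiation readout uses only the most recent pre spike; with
#' `nn_depression = "nearest_post"` the depression readout additionally
#' subtracts the part of the postsynaptic trace already seen by the previous
#' pre spike, so each post spike is paired exactly once (with its nearest
#' following pre). Simultaneous pre and post events are ordered pre-first,
#' so a coincident pair counts as potentiation at full amplitude.
#'
#' @inheritParams pair_sum_oracle
#' @return Total weight change (scalar).
#' @export
stdp_trace_deltas <- function(pre, post, params) {
  ev_t <- c(pre, post)
  ev_is_pre <- rep(c(TRUE, FALSE), c(length(pre), length(post)))
  ord <- order(ev_t, !ev_is_pre)  # pre before post at equal times
  delta <- 0
  pre_trace <- 0; pre_last <- -Inf
  post_trace <- 0; post_last <- -Inf
  post_snap <- 0
  nn <- params$mode == "nearest_neighbor" &&
    identical(params$nn_depression, "nearest_post")
  for (i in ord) {
    t <- ev_t[i]
    if (ev_is_pre[i]) {
      if (is.finite(post_last)) {
        dep <- post_trace * exp(-(t - post_last) / params$tau_d)
        if (nn) {
          if (is.finite(pre_last)) {
            dep <- dep - post_snap * exp(-(t - pre_last) / params$tau_d)
          }
          dep <- max(dep, 0)
          post_snap <- post_trace * exp(-(t - post_last) / params$tau_d)
        }
        delta <- delta + params$a_d * dep
      }
      pre_trace <- if (is.finite(pre_last)) {
        pre_trace * exp(-(t - pre_last) / params$tau_p) + 1
      } else 1
      pre_last <- t
    } else {
      if (is.finite(pre_last)) {
        fac <- exp(-(t - pre_last) / params$tau_p)
        delta <- delta + params$a_p *
          (if (params$mode == "nearest_neighbor") fac else pre_trace * fac)
      }
      post_trace <- if (is.finite(post_last)) {
        post_trace * exp(-(t - post_last) / params$tau_d) + 1
      } else 1
      post_last <- t
    }
  }
  delta
}

#' Normalize a vector of incoming lateral weights
#'
#' If the sum exceeds `wl_max`, rescales all weights proportionally so the
#' sum equals `wl_max`; otherwise returns the weights unchanged. Relative
#' proportions (and zeros) are preserved.
#'
#' @param w Non-negative numeric vector of incoming lateral weights.
#' @param wl_max Bound on the summed incoming lateral weight.
#' @return The (possibly rescaled) weight vector.
#' @export
normalize_lateral <- function(w, wl_max) {
  if (any(w < 0)) stop("lateral weights must be non-negative")
  stop_if_not_scalar_pos(wl_max, "wl_max")
  s <- sum(w)
  if (s > wl_max) w * (wl_max / s) else w
}

#' Initialize feed-forward and lateral weight matrices
#'
#' Feed-forward weights are i.i.d. uniform on (0, `wp_max`]; lateral weights
#' i.i.d. uniform on (0, `wl_max / n_exc`] with a zero diagonal (no
#' self-connections).
#'
#' @param n_aff Number of afferents.
#' @param n_exc Number of excitatory neurons.
#' @param wp_max Feed-forward weight bound.
#' @param wl_max Lateral incoming-sum bound.
#' @param seed Integer seed.
#' @return List with `w_ff` (`n_aff x n_exc`) and `w_lat`
#'   (`n_exc x n_exc`, rows = source, columns = target).
#' @export
init_weights <- function(n_aff, n_exc, wp_max, wl_max, seed) {
  stop_if_not_scalar_pos(wp_max, "wp_max")
  stop_if_not_scalar_pos(wl_max, "wl_max")
  with_seed(seed, {
    w_ff <- matrix(stats::runif(n_aff * n_exc, 0, wp_max), n_aff, n_exc)
    w_lat <- matrix(stats::runif(n_exc * n_exc, 0, wl_max / n_exc), n_exc, n_exc)
    diag(w_lat) <- 0
    list(w_ff = w_ff, w_lat = w_lat)
  })
}
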