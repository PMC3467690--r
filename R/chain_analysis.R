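# Evaluation criteria and chain-graph extraction.
#
# "Pattern learnt": a fixed set of neurons responds reliably (firing
# probability >= 50% over repeated test presentations) to segments of the
# pattern. "Sequence learnt": additionally, with lateral input severed only
# chain-head start neurons remain reliable, and with lateral input present
# the members fire in a fixed order. "Sequence recognized" in a
# presentation: every member of the learnt chain fired, in particular the
# accepting (terminal) neuron(s), signaling that the complete pattern was
# seen.

#' Per-neuron reliability and latency over test presentations
#'
#' For each excitatory neuron, the fraction of presentations with at least
#' one spike inside the response window `[onset, onset + pattern_duration +
#' margin]`, plus first-spike latency statistics (mean, sd, median, in ms
#' from pattern onset).
#'
#' @param test A [run_test()] result.
#' @param margin Extra time after pattern offset still counted as a pattern
#'   response, in ms (default 20; membrane and synaptic lag let late chain
#'   neurons respond shortly after the pattern ends).
#' @return A data.frame with one row per excitatory neuron: `neuron`,
#'   `n_responses`, `p_fire`, `latency_mean`, `latency_sd`,
#'   `latency_median`.
#' @export
compute_reliability <- function(test, margin = 20) {
  stopifnot(inherits(test, "chain_test"))
  if (test$n_presentations < 1) stop("need at least one presentation")
  n_exc <- test$n_exc
  win <- test$pattern_duration + margin
  spk <- test$spikes[test$spikes$neuron <= n_exc, ]
  first <- matrix(NA_real_, test$n_presentations, n_exc)
  for (i in seq_along(test$onsets)) {
    on <- test$onsets[i]
    sel <- spk$time >= on & spk$time <= on + win
    if (any(sel)) {
      lat <- tapply(spk$time[sel] - on, factor(spk$neuron[sel], levels = seq_len(n_exc)), min)
      first[i, ] <- as.numeric(lat)
    }
  }
  n_resp <- colSums(!is.na(first))
  data.frame(
    neuron = seq_len(n_exc),
    n_responses = n_resp,
    p_fire = n_resp / test$n_presentations,
    latency_mean = suppressWarnings(colMeans(first, na.rm = TRUE)),
    latency_sd = apply(first, 2, stats::sd, na.rm = TRUE),
    latency_median = apply(first, 2, stats::median, na.rm = TRUE)
  )
}

#' Assess the pattern-learnt criterion
#'
#' A pattern counts as learnt when a non-empty set of neurons responds
#' reliably: firing probability at least `p_min` (default 0.5) over the test
#' presentations.
#'
#' @param reliability A [compute_reliability()] table.
#' @param p_min Reliability threshold (default 0.5, inclusive).
#' @return List with `learnt` (logical) and `members` (neuron ids sorted by
#'   median first-spike latency).
#' @export
assess_pattern_learnt <- function(reliability, p_min = 0.5) {
  members <- reliability$neuron[reliability$p_fire >= p_min]
  if (length(members)) {
    members <- members[order(reliability$latency_median[members])]
  }
  list(learnt = length(members) > 0, members = members)
}

# Fraction of presentations in which the firing order of the responding
# members matches the canonical (latency-sorted) order. Neurons whose
# first spikes fall within `tie_tol` of each other are treated as
# order-indistinguishable: response jitter is of the order of a few
# milliseconds (and several neurons may legitimately code the same segment
# in parallel chains), so only inversions larger than the jitter scale
# count as disorder.
order_consistency <- function(test, members, margin = 20, tie_tol = 2) {
  if (length(members) < 2) return(1)
  win <- test$pattern_duration + margin
  spk <- test$spikes[test$spikes$neuron %in% members, ]
  canon <- match(spk$neuron, members)  # canonical position
  ok <- vapply(test$onsets, function(on) {
    sel <- spk$time >= on & spk$time <= on + win
    if (!any(sel)) return(FALSE)
    lat <- tapply(spk$time[sel] - on, canon[sel], min)
    pos <- as.integer(names(lat))
    lat <- as.numeric(lat)
    for (i in seq_along(pos)) for (j in seq_along(pos)) {
      if (pos[i] < pos[j] && lat[i] > lat[j] + tie_tol) return(FALSE)
    }
    TRUE
  }, logical(1))
  mean(ok)
}

#' Assess the sequence-learnt criterion
#'
#' A sequence counts as learnt when (a) the pattern is learnt with lateral
#' input present, (b) with lateral input severed only chain-start neurons
#' remain reliable (every non-start neuron needs both its feed-forward
#' segment and the firing of its predecessors), and (c) the members fire in
#' a fixed order: over the lateral-on presentations, the first-spike order
#' of the responding members matches the canonical latency order in at
#' least `order_min` of presentations (inversions within the jitter scale
#' are ignored, see `tie_tol`).
#'
#' Several chains may form in parallel, each recognizing the same pattern
#' with its own start neuron; when a `graph` (or `record`) is supplied,
#' clause (b) therefore admits any start node that heads a strengthened
#' chain (has an outgoing edge to a later member). Without a graph it falls
#' back to the single earliest-latency neuron.
#'
#' @param test_on A lateral-on [run_test()] result.
#' @param test_off The matching severed-lateral test
#'   (`lateral_enabled = FALSE`).
#' @param record Optional trained `sim_record`, used to extract the chain
#'   graph for clause (b).
#' @param graph Optional [extract_chain_graph()] result (takes precedence
#'   over `record`).
#' @param p_min Reliability threshold (default 0.5).
#' @param order_min Required order-consistency fraction (default 0.5).
#' @param margin Response-window margin in ms (default 20).
#' @param tie_tol Latency difference (ms) below which two members count as
#'   simultaneous for the order check (default 2).
#' @return List with `learnt`, `pattern_learnt`, `members` (canonical
#'   order), `off_reliable` (members still reliable without lateral input),
#'   `allowed_off` (chain-start neurons excused from clause b),
#'   `order_consistency`.
#' @export
assess_sequence_learnt <- function(test_on, test_off, record = NULL,
                                   graph = NULL, p_min = 0.5,
                                   order_min = 0.5, margin = 20,
                                   tie_tol = 2) {
  rel_on <- compute_reliability(test_on, margin = margin)
  rel_off <- compute_reliability(test_off, margin = margin)
  pat <- assess_pattern_learnt(rel_on, p_min = p_min)
  members <- pat$members
  off_reliable <- intersect(rel_off$neuron[rel_off$p_fire >= p_min], members)
  oc <- order_consistency(test_on, members, margin = margin,
                          tie_tol = tie_tol)
  if (is.null(graph) && !is.null(record)) {
    graph <- extract_chain_graph(record, members = members,
                                 reliability = rel_on)
  }
  allowed <- if (!is.null(graph)) {
    # start nodes that actually head a chain (outgoing edge to a later
    # member); an isolated member is not a chain head
    heads <- unique(graph$edges$src[graph$edges$gap > 0])
    intersect(graph$start, heads)
  } else if (length(members)) {
    members[1]
  } else {
    integer(0)
  }
  clause_b <- length(setdiff(off_reliable, allowed)) == 0
  list(
    learnt = pat$learnt && clause_b && oc >= order_min &&
      length(members) >= 2,
    pattern_learnt = pat$learnt,
    members = members,
    off_reliable = off_reliable,
    allowed_off = allowed,
    order_consistency = oc
  )
}

#' Fraction of presentations in which a set of neurons all fired
#'
#' With `neurons` set to the chain members this is the sequence-recognition
#' rate: the fraction of presentations in which the complete chain —
#' including the accepting neuron — was activated. With
#' `require_order = TRUE` the neurons must additionally fire in the order
#' given (first-spike order, inversions within `tie_tol` ignored), which is
#' the finite-automaton reading of recognition: the states must be
#' traversed in sequence, not merely visited.
#'
#' @param test A [run_test()] result.
#' @param neurons Neuron ids that must all fire within the response window,
#'   in canonical order when `require_order = TRUE`.
#' @param margin Response-window margin in ms (default 20).
#' @param require_order Require the first-spike order to match `neurons`.
#' @param tie_tol Latency difference (ms) treated as simultaneous.
#' @return A proportion in \[0, 1\].
#' @export
recognition_rate <- function(test, neurons, margin = 20,
                             require_order = FALSE, tie_tol = 2) {
  if (!length(neurons)) return(0)
  win <- test$pattern_duration + margin
  spk <- test$spikes[test$spikes$neuron %in% neurons, ]
  ok <- vapply(test$onsets, function(on) {
    sel <- spk$time >= on & spk$time <= on + win
    if (length(unique(spk$neuron[sel])) != length(neurons)) return(FALSE)
    if (!require_order) return(TRUE)
    lat <- tapply(spk$time[sel] - on, match(spk$neuron[sel], neurons), min)
    pos <- as.integer(names(lat)); lat <- as.numeric(lat)
    for (i in seq_along(pos)) for (j in seq_along(pos)) {
      if (pos[i] < pos[j] && lat[i] > lat[j] + tie_tol) return(FALSE)
    }
    TRUE
  }, logical(1))
  mean(ok)
}

#' Extract the learnt chain as a directed graph
#'
#' Edges are strengthened lateral synapses (weight above
#' `edge_threshold * wl_max`) among the chain members; nodes are annotated
#' with their canonical position and median latency. Start nodes have no
#' incoming edge from an earlier member; accepting nodes have no outgoing
#' edge to a later member (chain terminals, the neurons whose firing signals
#' complete-pattern recognition). Because converged lateral weights are
#' bimodal (near zero or near the effective maximum), the extracted graph is
#' insensitive to the exact threshold.
#'
#' @param record A trained `sim_record` (its final `w_lat` is used), or a
#'   matrix of lateral weights via `w_lat`.
#' @param members Chain member neuron ids; defaults to the reliable set of a
#'   fresh lateral-on test when `reliability` is not given.
#' @param reliability Optional [compute_reliability()] table used to order
#'   members by median latency.
#' @param edge_threshold Fraction of `wl_max` above which a lateral synapse
#'   counts as strengthened (default 0.08). Because the sum-normalization
#'   spreads a converged neuron's incoming lateral budget over its ~5-10
#'   chain predecessors, individual strengthened synapses sit near
#'   `wl_max / k` for small `k`; the threshold lies in the gap between that
#'   population and the depressed near-zero population.
#' @param w_lat,wl_max Weight matrix and bound, taken from `record` when
#'   supplied.
#' @return An object of class `chain_graph`: list with `graph` (an igraph),
#'   `members` (canonical order), `start`, `accepting`, `edges` (data.frame
#'   src, dst, weight, gap in merged canonical positions, and `gap_comp`,
#'   the gap within the edge's own connected component — the meaningful
#'   measure of a straddling connection when several chains respond in
#'   parallel), and `order_violations` (edges pointing from a later to an
#'   earlier canonical position; expected rare).
#' @export
extract_chain_graph <- function(record = NULL, members = NULL,
                                reliability = NULL, edge_threshold = 0.08,
                                w_lat = NULL, wl_max = NULL) {
  if (!is.null(record)) {
    stopifnot(inherits(record, "sim_record"))
    if (is.null(w_lat)) w_lat <- record$w_lat
    if (is.null(wl_max)) wl_max <- record$cfg$wl_max
    if (is.null(members)) {
      if (is.null(reliability)) {
        reliability <- compute_reliability(run_test(record))
      }
      members <- assess_pattern_learnt(reliability)$members
    }
  }
  if (is.null(w_lat) || is.null(wl_max)) {
    stop("supply `record` or both `w_lat` and `wl_max`")
  }
  if (!is.null(reliability) && length(members)) {
    members <- members[order(reliability$latency_median[members])]
  }
  thr <- edge_threshold * wl_max
  n_m <- length(members)
  edges <- data.frame(src = integer(0), dst = integer(0),
                      weight = numeric(0), gap = integer(0))
  if (n_m >= 2) {
    sub <- w_lat[members, members, drop = FALSE]
    idx <- which(sub > thr, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(
        src = members[idx[, 1]], dst = members[idx[, 2]],
        weight = sub[idx], gap = idx[, 2] - idx[, 1])
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$src), to = as.character(edges$dst),
               weight = edges$weight),
    directed = TRUE,
    vertices = data.frame(name = as.character(members),
                          position = seq_len(n_m)))
  # gap within the edge's own (weakly) connected component: positions are
  # recounted among that component's members only
  edges$gap_comp <- edges$gap
  if (nrow(edges)) {
    comp <- igraph::components(g, mode = "weak")$membership
    comp_of <- stats::setNames(comp, igraph::V(g)$name)
    for (ci in unique(comp_of)) {
      nodes <- members[members %in% as.integer(names(comp_of)[comp_of == ci])]
      pos <- stats::setNames(seq_along(nodes), nodes)
      sel <- edges$src %in% nodes & edges$dst %in% nodes
      edges$gap_comp[sel] <- pos[as.character(edges$dst[sel])] -
        pos[as.character(edges$src[sel])]
    }
  }
  start <- members[!(members %in% edges$dst[edges$gap > 0])]
  accepting <- members[!(members %in% edges$src[edges$gap > 0])]
  structure(list(
    graph = g, members = members, start = start, accepting = accepting,
    edges = edges, order_violations = edges[edges$gap < 0, ],
    edge_threshold = edge_threshold, wl_max = wl_max
  ), class = "chain_graph")
}

#' @export
print.chain_graph <- function(x, ...) {
  cat(sprintf("<chain_graph> %d members, %d edges (threshold %.2g)\n",
              length(x$members), nrow(x$edges),
              x$edge_threshold * x$wl_max))
  if (length(x$members)) {
    cat("  order:", paste(x$members, collapse = " -> "), "\n")
    cat("  start:", paste(x$start, collapse = ", "),
        " accepting:", paste(x$accepting, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Detect directed cycles in a chain graph
#'
#' Stimulus-driven training is expected to produce acyclic chains (the
#' repeated patterns are separated by unlearnt random activity, which
#' deters loop formation); any cycle is reported. Cycles are returned as the
#' non-trivial strongly connected components, each of which contains at
#' least one directed cycle.
#'
#' @param graph A [extract_chain_graph()] result.
#' @return A list of integer vectors (neuron ids), one per cyclic component;
#'   empty when the graph is acyclic.
#' @export
detect_cycles <- function(graph) {
  stopifnot(inherits(graph, "chain_graph"))
  g <- graph$graph
  if (igraph::gorder(g) == 0 || igraph::is_dag(g)) return(list())
  comp <- igraph::components(g, mode = "strong")
  keep <- which(comp$csize > 1)
  lapply(keep, function(k) {
    as.integer(igraph::V(g)$name[comp$membership == k])
  })
}

#' Directness versus strength of lateral connections
#'
#' With all-to-all STDP, connections may straddle several chain positions;
#' generally the more direct the connection, the stronger the synapse. For
#' every ordered pair of edges sharing a source (or sharing a target) whose
#' component-relative position gaps differ, this reports the fraction in
#' which the shorter-gap edge carries the larger weight.
#'
#' @param graph A [extract_chain_graph()] result.
#' @return List with `fraction_direct_stronger`, `n_pairs`, and `defined`
#'   (`FALSE`, with an `NA` fraction, when fewer than two comparable edges
#'   exist).
#' @export
edge_directness_vs_strength <- function(graph) {
  stopifnot(inherits(graph, "chain_graph"))
  e <- graph$edges[graph$edges$gap_comp > 0, ]
  e$gap <- e$gap_comp
  wins <- 0L; total <- 0L
  if (nrow(e) >= 2) {
    for (key in c("src", "dst")) {
      for (v in unique(e[[key]])) {
        sub <- e[e[[key]] == v, ]
        if (nrow(sub) < 2) next
        for (i in seq_len(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
          if (sub$gap[i] == sub$gap[j]) next
          total <- total + 1L
          shorter <- which.min(c(sub$gap[i], sub$gap[j]))
          if (c(sub$weight[i], sub$weight[j])[shorter] ==
              max(sub$weight[i], sub$weight[j])) wins <- wins + 1L
        }
      }
    }
  }
  if (total == 0) {
    list(fraction_direct_stronger = NA_real_, n_pairs = 0L, defined = FALSE)
  } else {
    list(fraction_direct_stronger = wins / total, n_pairs = total,
         defined = TRUE)
  }
}

#' Full evaluation of a trained network
#'
#' Runs the lateral-on and severed-lateral tests, applies the learning
#' criteria, extracts the chain graph and computes the recognition rate.
#'
#' @param record A trained `sim_record`.
#' @param n_presentations Presentations per test (default 10).
#' @param pattern_id Which stored pattern to evaluate (default 1).
#' @param margin Response-window margin in ms (default 20).
#' @param weights Optional list(w_ff, w_lat) snapshot override.
#' @param seed Optional test-noise seed.
#' @return An object of class `evaluation_report`: list with
#'   `pattern_learnt`, `sequence_learnt`, `members`, `chain_length`,
#'   `recognition_rate`, `reliability`, `graph`, and the two tests.
#' @export
evaluate_run <- function(record, n_presentations = 10, pattern_id = 1L,
                         margin = 20, weights = NULL, seed = NULL) {
  test_on <- run_test(record, n_presentations = n_presentations,
                      pattern_id = pattern_id, weights = weights, seed = seed)
  test_off <- run_test(record, n_presentations = n_presentations,
                       pattern_id = pattern_id, lateral_enabled = FALSE,
                       weights = weights, seed = seed)
  seq_res <- assess_sequence_learnt(
    test_on, test_off, margin = margin,
    record = if (is.null(weights)) record else NULL,
    graph = if (!is.null(weights)) {
      extract_chain_graph(w_lat = weights$w_lat, wl_max = record$cfg$wl_max,
                          members = assess_pattern_learnt(
                            compute_reliability(test_on, margin = margin))$members)
    })
  rel <- compute_reliability(test_on, margin = margin)
  graph <- extract_chain_graph(record, members = seq_res$members,
                               reliability = rel,
                               w_lat = if (!is.null(weights)) weights$w_lat)
  structure(list(
    pattern_learnt = seq_res$pattern_learnt,
    sequence_learnt = seq_res$learnt,
    members = seq_res$members,
    chain_length = length(seq_res$members),
    recognition_rate = recognition_rate(test_on, seq_res$members,
                                        margin = margin),
    off_reliable = seq_res$off_reliable,
    order_consistency = seq_res$order_consistency,
    reliability = rel, graph = graph,
    test_on = test_on, test_off = test_off
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> pattern learnt: %s | sequence learnt: %s\n  chain: %s (%d members), recognition rate %.2f\n",
    x$pattern_learnt, x$sequence_learnt,
    paste(x$members, collapse = " -> "), x$chain_length,
    x$recognition_rate))
  invisible(x)
}

#' Sweep the lateral weight bound
#'
#' For each value of `wl_max`, trains fresh networks and measures the
#' percentage of chain members that still respond reliably with lateral
#' input severed. As `wl_max` grows, neurons come to depend on the input
#' from their predecessors, so the percentage decreases.
#'
#' @param cfg A [network_config()]; `wl_max` and `seed` are overridden per
#'   trial.
#' @param wlmax_values Numeric vector of bounds to test.
#' @param n_seeds Trials per value (default 3).
#' @param n_presentations Presentations per test (default 10).
#' @return A data.frame with one row per bound: `wl_max`, `mean_pct`
#'   (mean percentage of members responsive without lateral input),
#'   `sd_pct`, `n_seeds`.
#' @export
sweep_wlmax <- function(cfg, wlmax_values, n_seeds = 3,
                        n_presentations = 10) {
  if (any(wlmax_values <= 0)) stop("`wlmax_values` must be positive")
  rows <- lapply(wlmax_values, function(wl) {
    pct <- vapply(seq_len(n_seeds), function(s) {
      cfg_i <- cfg
      cfg_i$wl_max <- wl
      cfg_i$seed <- cfg$seed + 1000L * s + as.integer(round(wl))
      rec <- run_training(cfg_i)
      test_on <- run_test(rec, n_presentations = n_presentations)
      test_off <- run_test(rec, n_presentations = n_presentations,
                           lateral_enabled = FALSE)
      members <- assess_pattern_learnt(compute_reliability(test_on))$members
      if (!length(members)) return(NA_real_)
      rel_off <- compute_reliability(test_off)
      100 * sum(rel_off$p_fire[members] >= 0.5) / length(members)
    }, numeric(1))
    pct <- pct[!is.na(pct)]
    data.frame(wl_max = wl, mean_pct = mean(pct),
               sd_pct = if (length(pct) > 1) stats::sd(pct) else NA_real_,
               n_seeds = length(pct))
  })
  do.call(rbind, rows)
}
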