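# Learning criteria and chain-graph extraction on hand-built objects.

test_that("reliability counts presence per presentation, 50% inclusive", {
  # neuron 1: 5/10 presentations; neuron 2: 4/10; neuron 3: twice in one
  pres <- lapply(1:10, function(i) {
    df <- NULL
    if (i <= 5) df <- rbind(df, data.frame(neuron = 1, time = 10))
    if (i <= 4) df <- rbind(df, data.frame(neuron = 2, time = 20))
    if (i == 1) df <- rbind(df, data.frame(neuron = 3, time = c(5, 30)))
    df
  })
  tst <- fake_test(pres)
  rel <- compute_reliability(tst)
  expect_equal(rel$p_fire[1:3], c(0.5, 0.4, 0.1))
  expect_equal(rel$n_responses[3], 1)  # two spikes count once
  pat <- assess_pattern_learnt(rel)
  expect_true(pat$learnt)
  expect_equal(pat$members, 1)
  # all below threshold: not learnt, empty set
  none <- assess_pattern_learnt(compute_reliability(fake_test(
    lapply(1:10, function(i) if (i == 1) data.frame(neuron = 1, time = 1)))))
  expect_false(none$learnt)
  expect_length(none$members, 0)
})

test_that("latency statistics order members canonically", {
  pres <- lapply(1:10, function(i) {
    data.frame(neuron = c(2, 4, 1), time = c(10, 25, 40) + i * 0.1)
  })
  rel <- compute_reliability(fake_test(pres))
  m <- assess_pattern_learnt(rel)$members
  expect_equal(m, c(2, 4, 1))
  expect_equal(rel$latency_median[2], 10.55)
})

test_that("sequence criterion requires lateral dependence and fixed order", {
  ordered <- lapply(1:10, function(i) {
    data.frame(neuron = c(1, 2, 3), time = c(10, 20, 30))
  })
  on <- fake_test(ordered)
  # severed-lateral test in which three neurons remain reliable: not a
  # sequence (the later neurons do not depend on their predecessors)
  off_bad <- fake_test(ordered)
  sq_bad <- assess_sequence_learnt(on, off_bad)
  expect_false(sq_bad$learnt)
  expect_true(sq_bad$pattern_learnt)  # ordering of criteria
  # only the first neuron survives severing: textbook sequence
  off_good <- fake_test(lapply(1:10, function(i) {
    data.frame(neuron = 1, time = 10)
  }))
  sq <- assess_sequence_learnt(on, off_good)
  expect_true(sq$learnt)
  expect_equal(sq$members, c(1, 2, 3))
  expect_equal(sq$order_consistency, 1)
  # scrambled firing order destroys the sequence
  scrambled <- fake_test(lapply(1:10, function(i) {
    data.frame(neuron = c(1, 2, 3),
               time = if (i %% 2) c(10, 20, 30) else c(30, 20, 10))
  }))
  sq_scr <- assess_sequence_learnt(scrambled, off_good)
  expect_lt(sq_scr$order_consistency, 0.7)
  # sequence_learnt always implies pattern_learnt
  for (s in list(sq_bad, sq, sq_scr)) {
    expect_true(!s$learnt || s$pattern_learnt)
  }
})

test_that("near-simultaneous first spikes do not count as disorder", {
  jittered <- fake_test(lapply(1:10, function(i) {
    data.frame(neuron = c(1, 2, 3),
               time = c(10, 10.5 + (i %% 2), 30))  # 1 and 2 within 2 ms
  }))
  off <- fake_test(lapply(1:10, function(i) data.frame(neuron = 1, time = 10)))
  expect_equal(assess_sequence_learnt(jittered, off)$order_consistency, 1)
})

test_that("chain graph identifies start, accepting and cycles", {
  wl <- matrix(0, 5, 5)
  wl[1, 2] <- 30; wl[2, 3] <- 28  # linear chain 1 -> 2 -> 3
  g <- extract_chain_graph(w_lat = wl, wl_max = 50, members = c(1, 2, 3))
  expect_equal(g$start, 1)
  expect_equal(g$accepting, 3)
  expect_equal(nrow(g$edges), 2)
  expect_length(detect_cycles(g), 0)
  # closing the loop creates a cycle
  wl[3, 1] <- 40
  g2 <- extract_chain_graph(w_lat = wl, wl_max = 50, members = c(1, 2, 3))
  cyc <- detect_cycles(g2)
  expect_length(cyc, 1)
  expect_setequal(cyc[[1]], c(1, 2, 3))
  # weak weights are not edges
  g3 <- extract_chain_graph(w_lat = wl * 0.1, wl_max = 50,
                            members = c(1, 2, 3))
  expect_equal(nrow(g3$edges), 0)
})

test_that("parallel chains get separate starts and accepting neurons", {
  wl <- matrix(0, 6, 6)
  wl[1, 3] <- 30; wl[3, 5] <- 30   # chain A: 1 -> 3 -> 5
  wl[2, 4] <- 30; wl[4, 6] <- 30   # chain B: 2 -> 4 -> 6
  g <- extract_chain_graph(w_lat = wl, wl_max = 50, members = 1:6)
  expect_setequal(g$start, c(1, 2))
  expect_setequal(g$accepting, c(5, 6))
})

test_that("directness versus strength compares gap-sharing edge pairs", {
  wl <- matrix(0, 4, 4)
  wl[1, 2] <- 30   # direct (gap 1)
  wl[1, 3] <- 15   # straddling (gap 2), weaker
  g <- extract_chain_graph(w_lat = wl, wl_max = 50, members = c(1, 2, 3))
  d <- edge_directness_vs_strength(g)
  expect_true(d$defined)
  expect_equal(d$fraction_direct_stronger, 1)
  # single edge: undefined, flagged
  wl2 <- matrix(0, 3, 3); wl2[1, 2] <- 30
  d2 <- edge_directness_vs_strength(
    extract_chain_graph(w_lat = wl2, wl_max = 50, members = c(1, 2)))
  expect_false(d2$defined)
  expect_true(is.na(d2$fraction_direct_stronger))
})

test_that("recognition rate requires the complete set to fire", {
  pres <- lapply(1:10, function(i) {
    if (i <= 6) data.frame(neuron = c(1, 2), time = c(10, 20))
    else data.frame(neuron = 1, time = 10)
  })
  tst <- fake_test(pres)
  expect_equal(recognition_rate(tst, c(1, 2)), 0.6)
  expect_equal(recognition_rate(tst, 1), 1)
  expect_equal(recognition_rate(tst, integer(0)), 0)
})
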