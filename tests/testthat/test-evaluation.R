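# Benchmark metrics and the exhaustive realizability oracle.

test_that("CN accuracy and total error follow their definitions", {
  expect_equal(cn_accuracy(rep(2, 8), rep(2, 8)), 1)
  expect_equal(cn_accuracy(c(rep(1, 7), rep(9, 5)), rep(1, 12)), 7 / 12)
  expect_equal(cn_accuracy(1:3, 4:6), 0)
  expect_error(cn_accuracy(1:3, 1:4), "mismatch")
  expect_equal(total_cn_error(c(1, 3, 4), c(1, 3, 3)), 1)
  expect_equal(total_cn_error(c(1, 3, 4), c(1, 3, 4)), 0)
  expect_equal(total_cn_error(c(5, 1), c(2, 9)), total_cn_error(c(2, 9), c(5, 1)))
})

test_that("SV metrics implement precision, recall and F1 with matching", {
  lay <- uniform_layout(4)
  truth <- rbind(fold_junction(lay, 2, "hh"), fold_junction(lay, 3, "tt"))
  expect_equal(sv_metrics(truth, truth)$f1, 1)
  # TP = 2, FP = 1 -> precision 2/3, recall 1, F1 0.8
  pred <- rbind(truth, fold_junction(lay, 4, "tt"))
  m <- sv_metrics(pred, truth)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 0.8)
  # nothing matched
  m0 <- sv_metrics(fold_junction(lay, 4, "tt"), truth)
  expect_equal(c(m0$precision, m0$recall, m0$f1), c(0, 0, 0))
  # empty vs empty: all 1 by convention, flagged
  e <- sv_metrics(empty_junction_table(), empty_junction_table())
  expect_true(e$degenerate)
  expect_equal(e$f1, 1)
  # tolerance: 30 bp jitter still matches at the default 50 bp
  jit <- truth
  jit$pos_a <- jit$pos_a + 30
  jit$pos_b <- jit$pos_b + 30
  expect_equal(sv_metrics(jit, truth)$recall, 1)
  # permutation invariance
  expect_equal(sv_metrics(pred[c(3, 1, 2), ], truth)$precision, 2 / 3)
})

test_that("the realizability oracle decides small instances exhaustively", {
  o <- bfb_realizability_oracle(c(1, 3, 3), fold_indices = c(2, 3))
  expect_true(o$feasible)
  expect_equal(o$min_cycles, 2L)
  # a fold only at segment 1 cannot explain a CN step at segment 2
  expect_false(bfb_realizability_oracle(c(1, 2), fold_indices = 1)$feasible)
  o0 <- bfb_realizability_oracle(c(1, 1, 1), fold_indices = integer(0))
  expect_true(o0$feasible)
  expect_equal(o0$min_cycles, 0L)
  expect_error(bfb_realizability_oracle(rep(3, 6)), "guard")
  expect_error(bfb_realizability_oracle(c(9, 9)), "guard")
})

test_that("reconstruction reports assemble the resolution criteria", {
  set.seed(31)
  p <- simulate_history(4, 2)
  truth <- bfb_path(p, uniform_layout(4))
  obs <- derive_observables(truth)
  res <- resolve_profile(truth$layout, obs$segments$observed_cn,
                         obs$junctions)
  ev <- evaluate_reconstruction(res$path, truth)
  expect_true(ev$resolved)
  expect_equal(ev$cn_accuracy, 1)
  expect_equal(ev$sv_f1, 1)
  expect_equal(ev$total_cn_error, 0)
  expect_equal(ev$fbi_recall, 1)
  # real-data criterion: resolution needs only FBI recall
  ev2 <- evaluate_reconstruction(res$path, truth, criterion = "real")
  expect_true(ev2$resolved)
})
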