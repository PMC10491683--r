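# Fusion-breakage simulator, archetype templates, observables, batches.

test_that("simulate_history applies exactly the requested cycles", {
  set.seed(1)
  expect_identical(simulate_history(4, 0), 1:4)
  for (rep in 1:20) {
    n <- sample(1:6, 1); k <- sample(1:5, 1)
    p <- simulate_history(n, k)
    expect_true(is_bfb_path(p))
    expect_identical(p[seq_len(n)], seq_len(n))   # reference prefix kept
    expect_gt(length(p), n)
  }
  # single segment: length at most doubles per cycle
  set.seed(2)
  p1 <- simulate_history(1, 3)
  expect_lte(length(p1), 8L)
  expect_true(all(abs(p1) == 1L))
})

test_that("minor duplications record their junction and respect prob = 0", {
  set.seed(5)
  p <- c(1L, 2L, 3L)
  expect_identical(add_minor_duplications(p, prob = 0)$path, p)
  hit <- add_minor_duplications(p, prob = 1)
  expect_false(is.null(hit$dup))
  expect_equal(length(hit$path), 3L + (hit$dup$j - hit$dup$i + 1L))
  run <- hit$dup$i:hit$dup$j
  expect_gte(length(bfbmap:::find_run(hit$path, c(run, run))), 1L)
})

test_that("all six archetype templates build valid, annotated truths", {
  set.seed(6)
  for (tpl in c("perfect", "imperfect", "insertion", "translocation",
                "dup_ins", "virus")) {
    inst <- apply_complex_template(tpl)
    expect_s3_class(inst$truth, "BfbPath")
    expect_gt(nrow(inst$junctions), 0L)
    if (tpl == "perfect") {
      expect_true(is_bfb_path(inst$truth$path))
      expect_equal(derive_history(inst$truth$path)$cycles, 4L)
    }
    if (tpl == "imperfect") {
      # one FBI junction has distinct breakpoints
      fbi <- inst$junctions[grepl("FBI", inst$junctions$jtype), ]
      expect_true(any(fbi$pos_a != fbi$pos_b))
    }
    if (tpl == "virus") {
      expect_true(any(inst$truth$layout$origin == "virus"))
      expect_true(any(inst$junctions$jtype == "VIT"))
    }
  }
  expect_error(apply_complex_template("perfect",
                                      params = list(fusions = 9L)))
})

test_that("observables are exact without noise and degrade as configured", {
  set.seed(7)
  p <- simulate_history(4, 3)
  truth <- bfb_path(p, uniform_layout(4))
  obs <- derive_observables(truth)
  expect_equal(obs$segments$observed_cn, as.numeric(segment_counts(p, 4)))
  fa <- fold_adjacencies(p)
  expect_equal(sum(obs$junctions$observed_cn), nrow(fa))
  # full dropout leaves CNs only
  obs2 <- derive_observables(truth, dropout = 1)
  expect_equal(nrow(obs2$junctions), 0L)
  # linkage lists the oriented adjacencies of the path
  obs3 <- derive_observables(bfb_path(c(1L, 2L, 3L, -3L, -2L, 2L, 3L),
                                      uniform_layout(3)),
                             with_linkage = TRUE)
  expect_true(any(obs3$linkage$seg_a == 3 & obs3$linkage$or_a == "+" &
                    obs3$linkage$seg_b == 3 & obs3$linkage$or_b == "-"))
  expect_true(any(obs3$linkage$seg_a == 2 & obs3$linkage$or_a == "-" &
                    obs3$linkage$seg_b == 2 & obs3$linkage$or_b == "+"))
})

test_that("batches respect the configured ranges and are seed-stable", {
  cfg <- list(batch_size = 12L, seed = 99L)
  b1 <- simulate_batch(cfg)
  b2 <- simulate_batch(cfg)
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(b1$paths, b2$paths)
  m <- b1$manifest
  expect_equal(nrow(m), 12L)
  expect_true(all(m$n_segments >= 6 & m$n_segments <= 15))
  expect_true(all(m$n_fbis >= 2 & m$n_fbis <= 7))
  expect_true(all(m$total_cn >= 13 & m$total_cn <= 105))
  expect_true(all(m$max_cn >= 3 & m$max_cn <= 11))
  # conservation: manifest totals equal path lengths
  expect_equal(m$total_cn, vapply(b1$paths, length, 1L))
  expect_equal(nrow(simulate_batch(list(batch_size = 0L))$manifest), 0L)
})
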