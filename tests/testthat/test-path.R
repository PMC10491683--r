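# Signed-path algebra, the fusion-breakage grammar and history recovery.

test_that("reverse complement and palindromic suffixes behave", {
  expect_identical(rc_path(c(1L, 2L, -2L)), c(2L, -2L, -1L))
  expect_identical(rc_path(integer(0)), integer(0))
  # y == rc(y) holds for every even suffix of a fused path
  p <- c(1L, 2L, 3L, -3L, -2L, 2L, 3L)
  expect_identical(palindromic_suffix_length(p), 4L)
  expect_identical(palindromic_suffix_length(1:3), 0L)
})

test_that("adjacency classification distinguishes reference and folds", {
  expect_equal(adjacency_kind(2L, 3L), "ref")
  expect_equal(adjacency_kind(-3L, -2L), "ref")
  expect_equal(adjacency_kind(3L, -3L), "fold-tt")
  expect_equal(adjacency_kind(-2L, 2L), "fold-hh")
  expect_equal(adjacency_kind(1L, 3L), "other")
})

test_that("fold adjacencies and segment counts are read off correctly", {
  p <- c(1L, 2L, 3L, -3L, -2L, 2L, 3L)
  fa <- fold_adjacencies(p)
  expect_equal(fa$index, c(3L, 2L))
  expect_equal(fa$dir, c("tt", "hh"))
  expect_identical(segment_counts(p), c(1L, 3L, 3L))
})

test_that("derive_history recovers minimal cycle counts", {
  expect_equal(derive_history(1:4)$cycles, 0L)
  h <- derive_history(c(1L, 2L, 3L, -3L, -2L, 2L, 3L))
  expect_equal(h$cycles, 2L)
  expect_false(h$approximate)
  expect_equal(h$events$fold_index, c(3L, 2L))
  # fragment pattern F rc(F) F: two cycles
  expect_equal(derive_history(c(1L, -1L, 1L))$cycles, 2L)
  # alternating five-fragment pattern: three cycles
  expect_equal(derive_history(c(1L, -1L, 1L, -1L, 1L))$cycles, 3L)
  # a path that no fusion-breakage sequence generates
  bad <- derive_history(c(1L, -1L, 1L, 2L))
  expect_false(bad$consistent)
  expect_true(is.na(bad$cycles))
})

test_that("simulated paths always satisfy the grammar and peel back", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    k <- sample(0:5, 1)
    p <- simulate_history(n, k)
    expect_true(is_bfb_path(p))
    h <- derive_history(p, bfs_limit = 40L)
    expect_true(h$consistent)
    if (!h$approximate) expect_lte(h$cycles, k)
    if (k > 0) expect_gte(palindromic_suffix_length(p), 2L)
  }
})

test_that("minimal history equals exhaustive forward search on short paths", {
  for (n in 1:3) {
    enum <- enumerate_bfb_paths(n, max_len = 10L)
    for (k in seq_along(enum$paths)) {
      h <- derive_history(enum$paths[[k]])
      expect_true(h$consistent)
      expect_equal(h$cycles, enum$cycles[k],
                   info = paste(enum$paths[[k]], collapse = ","))
    }
  }
})

test_that("rendering produces readable oriented labels", {
  expect_equal(render_path(c(1L, -2L)), "H1 -H2")
  expect_equal(render_path(integer(0)), "")
})
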