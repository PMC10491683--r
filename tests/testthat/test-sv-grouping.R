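# Proximity clustering of SVs into candidate complex events.

mkj <- function(ct1, p1, e1, ct2, p2, e2) {
  junction_row(breakpoint(ct1, p1, e1), breakpoint(ct2, p2, e2))
}

test_that("clustering is a transitive closure over breakpoint proximity", {
  # A-B within gap, B-C within gap, A-C beyond: still one group
  jn <- rbind(
    mkj("chr1", 1e6, "tail", "chr1", 1.0e6, "tail"),
    mkj("chr1", 1.8e6, "head", "chr1", 1.8e6, "head"),
    mkj("chr1", 2.6e6, "tail", "chr1", 2.6e6, "tail"))
  groups <- cluster_svs(jn, max_gap = 1e6)
  expect_length(groups, 1L)
  expect_equal(nrow(groups[[1]]$junctions), 3L)
  expect_equal(groups[[1]]$fbi_count, 3L)
  # partition: shrinking the gap splits them
  expect_length(cluster_svs(jn, max_gap = 5e5), 3L)
})

test_that("grouping does not depend on input order", {
  set.seed(3)
  jn <- rbind(
    mkj("chr1", 1e6, "tail", "chr1", 1e6, "tail"),
    mkj("chr1", 1.5e6, "head", "chr1", 1.5e6, "head"),
    mkj("chr2", 9e6, "tail", "chr2", 9e6, "tail"))
  g1 <- cluster_svs(jn, max_gap = 1e6)
  g2 <- cluster_svs(jn[sample(nrow(jn)), ], max_gap = 1e6)
  key <- function(gs) lapply(gs, function(g) g$span)
  expect_equal(key(g1), key(g2))
})

test_that("fold-backs on two chromosomes group only via a bridging TRX", {
  fbi1 <- mkj("chr3", 26e6, "tail", "chr3", 26e6, "tail")
  fbi2 <- mkj("chr6", 26e6, "head", "chr6", 26e6, "head")
  expect_length(cluster_svs(rbind(fbi1, fbi2), max_gap = 1e6), 2L)
  trx <- mkj("chr3", 26.4e6, "tail", "chr6", 25.7e6, "head")
  groups <- cluster_svs(rbind(fbi1, fbi2, trx), max_gap = 1e6)
  expect_length(groups, 1L)
  expect_equal(groups[[1]]$fbi_count, 2L)
})

test_that("candidate selection requires more than one fold-back", {
  two <- cluster_svs(rbind(
    mkj("chr1", 1e6, "tail", "chr1", 1e6, "tail"),
    mkj("chr1", 1.5e6, "head", "chr1", 1.5e6, "head")), max_gap = 1e6)
  one <- cluster_svs(mkj("chr2", 1e6, "tail", "chr2", 1e6, "tail"),
                     max_gap = 1e6)
  expect_length(select_candidates(c(two, one)), 1L)
  expect_length(select_candidates(c(two, one), min_fbi = 1L), 2L)
  expect_error(select_candidates(two, min_fbi = 0L))
})

test_that("candidate windows pad the span and flag oversized groups", {
  g <- cluster_svs(rbind(
    mkj("chr1", 1e6, "tail", "chr1", 1e6, "tail"),
    mkj("chr1", 3e6, "head", "chr1", 3e6, "head")), max_gap = 1e7)[[1]]
  w <- candidate_window(g, flank = 1e4)
  expect_false(w$flagged)
  expect_equal(w$windows$start, 0.99e6)
  expect_equal(w$windows$end, 3.01e6)
  big <- cluster_svs(rbind(
    mkj("chr1", 1e6, "tail", "chr1", 1e6, "tail"),
    mkj("chr1", 13e6, "head", "chr1", 13e6, "head")), max_gap = 5e7)[[1]]
  expect_true(candidate_window(big)$flagged)
})
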