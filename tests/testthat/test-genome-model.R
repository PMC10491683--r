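# Junction typing, segmentation, depth conversion.

test_that("junction classification covers the end/contig grid symmetrically", {
  bp <- function(ct, pos, end) breakpoint(ct, pos, end)
  cases <- list(
    list(bp("chr1", 100, "tail"), bp("chr1", 500, "head"), "DEL-ht"),
    list(bp("chr1", 100, "head"), bp("chr1", 500, "tail"), "DUP-th"),
    list(bp("chr1", 100, "head"), bp("chr1", 500, "head"), "FBI-hh"),
    list(bp("chr1", 100, "tail"), bp("chr1", 500, "tail"), "FBI-tt"),
    list(bp("chr1", 100, "tail"), bp("chr2", 500, "tail"), "TRX-tt"),
    list(bp("chr1", 100, "head"), bp("chr2", 500, "tail"), "TRX-ht"),
    list(bp("chr1", 100, "tail"), bp("chr2", 500, "head"), "TRX-th"),
    list(bp("chr1", 100, "head"), bp("chr2", 500, "head"), "TRX-hh")
  )
  for (cs in cases) {
    expect_equal(classify_junction(cs[[1]], cs[[2]]), cs[[3]])
    # symmetric under endpoint swap
    expect_equal(classify_junction(cs[[2]], cs[[1]]), cs[[3]])
  }
  expect_equal(classify_junction(bp("chr1", 100, "tail"),
                                 bp("hbv", 0, "head"),
                                 virus_contigs = "hbv"), "VIT")
  expect_error(classify_junction(bp("chr1", 100, "tail"),
                                 bp("chr1", 100, "tail")),
               "degenerate")
})

test_that("segmentation tiles the region and deduplicates breakpoints", {
  lay <- build_segmentation("chr1", 0, 400, c(100, 250, 300), snap_tol = 0)
  expect_equal(nrow(lay), 4L)
  expect_equal(lay$start, c(0, 100, 250, 300))
  expect_equal(lay$end, c(100, 250, 300, 400))
  expect_equal(lay$index, 1:4)
  # no internal breakpoints -> one segment
  expect_equal(nrow(build_segmentation("chr1", 0, 400)), 1L)
  # duplicates collapse
  expect_equal(nrow(build_segmentation("chr1", 0, 400, c(100, 100),
                                       snap_tol = 0)), 2L)
  # snapping: a 30 bp neighbour does not open a sliver segment
  expect_equal(nrow(build_segmentation("chr1", 0, 400, c(100, 130),
                                       snap_tol = 50)), 2L)
  expect_error(build_segmentation("chr1", 0, 400, 500), "outside")
})

test_that("depth converts to CN by purity-weighted ploidy", {
  expect_equal(depth_to_copy_number(30, 30, 1, 2, 2), 2)
  # D_h = 30 / (0.5*4 + 0.5*2) = 10; C = 40/10
  expect_equal(depth_to_copy_number(40, 30, 0.5, 4, 2), 4)
  expect_equal(depth_to_copy_number(0, 30), 0)
  # linear in depth
  d_h <- 30 / (0.8 * 3 + 0.2 * 2)
  for (k in 0:4) {
    expect_equal(depth_to_copy_number(d_h * k, 30, 0.8, 3, 2), k)
  }
  expect_error(depth_to_copy_number(10, 0), "positive")
})

test_that("junction endpoints resolve onto segment boundaries", {
  lay <- uniform_layout(4)
  jn <- rbind(
    junction_row(breakpoint("chr1", 2e4, "tail"), breakpoint("chr1", 2e4, "tail")),
    junction_row(breakpoint("chr1", 1e4, "head"), breakpoint("chr1", 3e4, "head")))
  jn <- resolve_junction_segments(jn, list(chr1 = lay))
  expect_equal(jn$seg_a, c(2L, 2L))
  expect_equal(jn$seg_b, c(2L, 4L))
})
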