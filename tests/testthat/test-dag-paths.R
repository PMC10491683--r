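# DAG construction, topological composition, post-composition edits.

test_that("the child relation follows shared endpoints and strict length", {
  e <- function(kind, a, b) data.frame(kind = kind, a = a, b = b)
  expect_true(is_child(e("m", 3, 6), e("m", 1, 6)))
  expect_false(is_child(e("m", 2, 4), e("m", 1, 6)))
  expect_false(is_child(e("m", 1, 6), e("m", 1, 6)))
  # a loop is the child of the same-span mono-chain (degenerate spans)
  expect_true(is_child(e("l", 1, 1), e("m", 1, 1)))
  expect_false(is_child(e("m", 1, 1), e("l", 1, 1)))
})

test_that("the DAG links every positive entity under the root", {
  d <- build_dag(make_config(3, m_1_3 = 1, l_2_3 = 1, l_3_3 = 1))
  ids <- d$vertices$id
  catal <- d$catalog
  expect_setequal(ids, c(entity_id(catal, "m", 1, 3),
                         entity_id(catal, "l", 2, 3),
                         entity_id(catal, "l", 3, 3)))
  expect_equal(nrow(d$edges), 3L)   # m->l23, m->l33, l23->l33
  expect_error(build_dag(make_config(3, l_2_3 = 1)), "root")
})

test_that("topological orders start canonical and enumerate extensions", {
  chain <- build_dag(make_config(3, m_1_3 = 1, l_2_3 = 1, l_3_3 = 1))
  expect_length(topological_orders(chain, 10L), 1L)
  # two incomparable loops of equal length: two linear extensions
  two <- build_dag(make_config(4, m_1_4 = 1, l_1_2 = 1, l_3_4 = 1))
  ords <- topological_orders(two, 10L)
  expect_length(ords, 2L)
  expect_length(topological_orders(two, 1L), 1L)
  # every order starts at the root
  for (o in ords) expect_equal(o[1], two$root_id)
})

test_that("composition reproduces hand-derived palindromic paths", {
  expect_identical(compose_path(build_dag(make_config(3, m_1_3 = 1, l_2_3 = 1))),
                   c(1L, 2L, 3L, -3L, -2L, 2L, 3L))
  expect_identical(compose_path(build_dag(make_config(1, m_1_1 = 1, l_1_1 = 2))),
                   c(1L, -1L, 1L, -1L, 1L))
  expect_identical(compose_path(build_dag(make_config(3, m_1_3 = 1))), 1:3)
  # conservation: multiplicities equal the configuration aggregates
  cfg <- make_config(6, m_1_6 = 1, m_2_6 = 1, m_2_4 = 1, l_3_4 = 1)
  p <- compose_path(build_dag(cfg))
  expect_identical(segment_counts(p, 6),
                   as.integer(config_segment_aggregate(cfg$catalog, cfg$cn)))
  expect_true(is_bfb_path(p))
})

test_that("fold-guided search realizes target CNs at allowed sites only", {
  # stair <1,3,3> with folds at 2 and 3
  p <- search_bfb_path(c(1, 3, 3), required = c(2, 3))
  expect_identical(segment_counts(p, 3), c(1L, 3L, 3L))
  expect_setequal(unique(fold_adjacencies(p)$index), c(2L, 3L))
  # infeasible targets return NULL
  expect_null(search_bfb_path(c(1, 0, 2)))
  caps <- matrix(0, 2, 2, dimnames = list(c("tt", "hh"), NULL))
  caps["tt", 1] <- Inf
  expect_null(search_bfb_path(c(3, 1), caps = caps, strict = TRUE))
})

test_that("imperfect fold restoration rewrites the return arm", {
  # tail-to-tail fold (5, 3): H4 H5 | -H5 -H4 -H3 -> H4 H5 | -H3
  p <- c(1L, 2L, 3L, 4L, 5L, -5L, -4L, -3L, -2L, -1L)
  out <- restore_imperfect_folds(p, data.frame(i = 3, j = 5, dir = "tt"))
  expect_identical(out, c(1L, 2L, 3L, 4L, 5L, -3L, -2L, -1L))
  # head-to-head fold (2, 4): -H4 -H3 -H2 | H2 -> -H4 | H2
  q <- c(1L, 2L, 3L, 4L, 5L, -5L, -4L, -3L, -2L, 2L, 3L, 4L, 5L)
  out2 <- restore_imperfect_folds(q, data.frame(i = 2, j = 4, dir = "hh"))
  expect_identical(out2, c(1L, 2L, 3L, 4L, 5L, -5L, -4L, 2L, 3L, 4L, 5L))
  # identity on empty map; error when the adjacency is absent
  expect_identical(restore_imperfect_folds(p, NULL), p)
  expect_error(restore_imperfect_folds(1:3,
                                       data.frame(i = 1, j = 2, dir = "tt")),
               "no matching")
})

test_that("intra-chromosomal edits splice, repeat and insert runs", {
  x <- bfb_path(c(1L, 2L, 3L, 4L), uniform_layout(4))
  del <- apply_intra_edits(x, list(list(type = "DEL", i = 1, j = 3)))
  expect_identical(del$path, c(1L, 3L, 4L))
  dup <- apply_intra_edits(x, list(list(type = "DUP", i = 2, j = 3)))
  expect_identical(dup$path, c(1L, 2L, 3L, 2L, 3L, 4L))
  ins <- apply_intra_edits(x, list(list(
    type = "INS", after = 2L, before = 3L,
    donor_layout = uniform_layout(2, "chr9"), donor = 1:2)))
  expect_identical(ins$path, c(1L, 2L, 5L, 6L, 3L, 4L))
  expect_equal(nrow(ins$layout), 6L)
  # an edit spanning a fold-back is rejected
  folded <- bfb_path(c(1L, 2L, -2L, 2L, 3L, 4L), uniform_layout(4))
  expect_error(apply_intra_edits(folded, list(list(type = "DEL", i = 1, j = 3))),
               "fold|intact")
  expect_equal(vapply(ins$history, function(h) h$stage, 1L), 2L)
})

test_that("translocations concatenate whole blocks with orientation algebra", {
  la <- uniform_layout(3, "chrA")
  lb <- uniform_layout(2, "chrB")
  pa <- bfb_path(c(1L, 2L, 3L), la)
  pb <- bfb_path(c(1L, 2L), lb)
  # tail(A3) -- head(B1): forward + forward
  trx <- junction_row(breakpoint("chrA", 3e4, "tail"),
                      breakpoint("chrB", 0, "head"))
  trx$seg_a <- 3L; trx$seg_b <- 1L
  trx$contig_a <- "chrA"; trx$contig_b <- "chrB"
  trx$end_a <- "tail"; trx$end_b <- "head"
  joined <- concat_translocations(list(chrA = pa, chrB = pb), trx)
  expect_identical(joined$path, c(1L, 2L, 3L, 4L, 5L))
  # tail(A3) -- tail(B2): the B block is reverse-complemented
  trx2 <- trx
  trx2$end_b <- "tail"; trx2$pos_b <- 2e4; trx2$seg_b <- 2L
  joined2 <- concat_translocations(list(chrA = pa, chrB = pb), trx2)
  expect_identical(joined2$path, c(1L, 2L, 3L, -5L, -4L))
  # interior endpoint: failure of this mode
  trx3 <- trx
  trx3$seg_a <- 2L; trx3$end_a <- "tail"; trx3$pos_a <- 2e4
  expect_error(concat_translocations(list(chrA = pa, chrB = pb), trx3),
               "interior")
})

test_that("virtual contigs fuse layouts along a junction chain", {
  host <- uniform_layout(5, "chr7")
  virus <- uniform_layout(3, "hbv", seg_len = 1e3, origin = "virus")
  vit <- junction_row(breakpoint("chr7", 2e4, "tail"),
                      breakpoint("hbv", 0, "head"), virus_contigs = "hbv")
  vit$seg_a <- 2L; vit$seg_b <- 1L
  vit$contig_a <- "chr7"; vit$end_a <- "tail"
  vit$contig_b <- "hbv"; vit$end_b <- "head"
  fused <- build_virtual_contig(list(host, virus), vit)
  expect_equal(nrow(fused), 5L)     # H1 H2 V1 V2 V3
  expect_equal(fused$src_contig, c("chr7", "chr7", "hbv", "hbv", "hbv"))
  expect_equal(fused$src_index, c(1L, 2L, 1L, 2L, 3L))
  expect_equal(fused$origin, c("human", "human", "virus", "virus", "virus"))
  # identity on a single layout
  expect_identical(build_virtual_contig(list(host)), host)
  # a non-chain junction errors
  bad <- vit; bad$contig_a <- "chrX"
  expect_error(build_virtual_contig(list(host, virus), bad))
})
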