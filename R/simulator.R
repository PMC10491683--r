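# Fusion-breakage simulator: ground-truth paths, complex-event templates,
# noisy observables and batch generation.
#
# All sampling uses the session RNG; seed with set.seed() (simulate_batch
# seeds itself from its config and records per-path seeds in the manifest).

#' Evenly spaced reference layout
#'
#' @param n number of segments.
#' @param contig contig name.
#' @param seg_len segment length in bp.
#' @param origin `"human"` or `"virus"`.
#' @param start region start.
#' @return A layout data.frame (see [build_segmentation()]).
#' @export
uniform_layout <- function(n, contig = "chr1", seg_len = 1e4,
                           origin = "human", start = 0) {
  build_segmentation(contig, start, start + n * seg_len,
                     positions = start + seg_len * seq_len(n - 1L),
                     snap_tol = 0, origin = origin)
}

#' Simulate a BFB path by iterated fusion and breakage
#'
#' Each cycle concatenates the current path with its reverse complement and
#' cuts off a random number of tailing segments, keeping a nonempty appended
#' block (uniform over admissible cuts).
#'
#' @param n_segments segments in the reference layout (>= 1).
#' @param n_cycles number of fusion-breakage cycles (>= 0).
#' @return Integer vector: the simulated path.
#' @export
simulate_history <- function(n_segments, n_cycles) {
  stopifnot(n_segments >= 1L, n_cycles >= 0L)
  p <- seq_len(n_segments)
  for (k in seq_len(n_cycles)) {
    w <- sample.int(length(p), 1L)
    p <- c(p, rc_path(p[(length(p) - w + 1L):length(p)]))
  }
  p
}

#' Overlay a minor duplication onto a path
#'
#' With probability `prob`, one short forward run (1-2 segments) is
#' duplicated in place and the corresponding tail-to-head duplication
#' junction is reported.
#'
#' @param path integer vector (signed indices).
#' @param prob duplication probability in `[0, 1]`.
#' @return List with `path` and `dup` (NULL, or list(i, j) of the duplicated
#'   run).
#' @export
add_minor_duplications <- function(path, prob = 0.3) {
  stopifnot(prob >= 0, prob <= 1)
  if (stats::runif(1) >= prob) return(list(path = path, dup = NULL))
  n <- max(abs(path))
  len <- sample(1:2, 1L)
  starts <- sample(seq_len(max(1L, n - len + 1L)))
  for (i in starts) {
    j <- min(n, i + len - 1L)
    hits <- find_run(path, i:j)
    if (length(hits) > 0L) {
      pos <- hits[sample.int(length(hits), 1L)]
      path <- append(path, i:j, after = pos + (j - i))
      return(list(path = path, dup = list(i = i, j = j)))
    }
  }
  list(path = path, dup = NULL)
}

# deterministic perfect-BFB construction: cycle k realizes the fold at
# fusions[k]; the cut after each fusion is chosen so the next fold lands on
# its segment (nearest occurrence from the path end); the last cut keeps
# `final_cut` segments.
perfect_bfb_path <- function(n_segments, fusions, final_cut = 1L) {
  p <- seq_len(n_segments)
  K <- length(fusions)
  for (k in seq_len(K)) {
    if (abs(p[length(p)]) != fusions[k]) {
      stop(sprintf("cycle %d cannot fuse at segment %d (path ends at %d)",
                   k, fusions[k], p[length(p)]))
    }
    if (k < K) {
      occ <- which(abs(p) == fusions[k + 1L])
      w <- length(p) - max(occ) + 1L   # nearest occurrence from the end
    } else {
      w <- final_cut
    }
    p <- c(p, rc_path(p[(length(p) - w + 1L):length(p)]))
  }
  p
}

#' Build one of the six in-silico complex-BFB archetypes
#'
#' @param template one of `"perfect"`, `"imperfect"`, `"insertion"`,
#'   `"translocation"`, `"dup_ins"`, `"virus"`.
#' @param params list of template knobs: `n_segments` (default 6),
#'   `fusions` (fold index per cycle, default c(6, 2, 4, 3)), `final_cut`,
#'   `n_imperfect` (imperfect template), `donor_segments`, `n_virus`,
#'   `virus_fusions`.
#' @return List with `truth` (a `BfbPath` carrying the full staged history),
#'   `stage1_path` (the pre-edit core), `junctions` (ground-truth junction
#'   table), `mode` (suggested resolution mode) and template bookkeeping.
#' @export
apply_complex_template <- function(template = c("perfect", "imperfect",
                                                "insertion", "translocation",
                                                "dup_ins", "virus"),
                                   params = list()) {
  template <- match.arg(template)
  n <- params$n_segments %||% 6L
  fusions <- params$fusions %||% c(6L, 2L, 4L, 3L)
  if (length(fusions) > 0 && max(fusions) > n) stop("fusion index beyond layout")
  final_cut <- params$final_cut %||% 1L
  layout <- uniform_layout(n, "chr1")

  core <- if (length(fusions) == 0L) seq_len(n) else {
    perfect_bfb_path(n, fusions, final_cut)
  }
  history <- lapply(seq_along(fusions), function(k) {
    list(stage = 1L, op = "fusion", detail = list(fold = fusions[k]))
  })

  if (template == "perfect") {
    x <- bfb_path(core, layout, history = history)
    return(list(truth = x, stage1_path = core,
                junctions = realized_junctions(x), mode = "single"))
  }

  if (template == "imperfect") {
    n_imp <- params$n_imperfect %||% 1L
    folds <- fold_adjacencies(core)
    path <- core
    fmap <- list()
    for (r in seq_len(nrow(folds))) {
      if (length(fmap) >= n_imp) break
      idx <- folds$index[r]; dir <- folds$dir[r]
      cand <- if (dir == "tt") {
        list(i = idx - 1L, j = idx)
      } else {
        list(i = idx, j = idx + 1L)
      }
      if (cand$i < 1L || cand$j > n) next
      revised <- try(restore_imperfect_folds(
        path, data.frame(i = cand$i, j = cand$j, dir = dir)), silent = TRUE)
      if (inherits(revised, "try-error")) next
      path <- revised
      fmap[[length(fmap) + 1L]] <- data.frame(i = cand$i, j = cand$j, dir = dir)
    }
    if (length(fmap) == 0L) stop("imperfect template needs a revisable fold")
    x <- bfb_path(path, layout, history = history)
    return(list(truth = x, stage1_path = core,
                junctions = realized_junctions(x), mode = "single",
                fold_map = do.call(rbind, fmap)))
  }

  if (template %in% c("insertion", "dup_ins")) {
    path <- core
    dup <- NULL
    if (template == "dup_ins") {
      md <- add_minor_duplications(path, prob = 1)
      path <- md$path; dup <- md$dup
    }
    x <- bfb_path(path, layout, history = history)
    m <- params$donor_segments %||% 2L
    donor_layout <- uniform_layout(m, "chr2")
    folds <- fold_adjacencies(x$path)
    if (nrow(folds) == 0L) stop("insertion template needs a fold on the path")
    at <- folds$pos[nrow(folds)]
    x <- apply_intra_edits(x, list(list(type = "INS",
                                        after = x$path[at],
                                        before = x$path[at + 1L],
                                        donor_layout = donor_layout,
                                        donor = seq_len(m))))
    return(list(truth = x, stage1_path = core,
                junctions = realized_junctions(x), mode = "single",
                dup = dup))
  }

  if (template == "translocation") {
    n2 <- params$n_segments_b %||% 4L
    fus2 <- params$fusions_b %||% c(n2, 2L)
    layout2 <- uniform_layout(n2, "chr2", start = 0)
    core2 <- perfect_bfb_path(n2, fus2, final_cut = 1L)
    p1 <- bfb_path(core, layout,
                   history = history)
    p2 <- bfb_path(core2, layout2, history = list())
    # join right end of path1 to left end (reference start) of path2
    ex1 <- terminal_exposure(p1$path, "right")
    trx <- junction_row(
      breakpoint("chr1",
                 if (ex1$end == "tail") layout$end[ex1$seg] else layout$start[ex1$seg],
                 ex1$end),
      breakpoint("chr2", layout2$start[1L], "head"))
    trx$seg_a <- ex1$seg; trx$seg_b <- 1L
    # junction_row canonicalizes order; keep endpoint/contig pairing explicit
    trx$contig_a <- "chr1"; trx$end_a <- ex1$end
    trx$pos_a <- if (ex1$end == "tail") layout$end[ex1$seg] else layout$start[ex1$seg]
    trx$contig_b <- "chr2"; trx$end_b <- "head"; trx$pos_b <- layout2$start[1L]
    joint <- concat_translocations(list(chr1 = p1, chr2 = p2), trx)
    return(list(truth = joint, stage1_path = core,
                junctions = realized_junctions(joint), mode = "bfb-to-trx",
                per_contig = list(chr1 = p1, chr2 = p2), trx = trx))
  }

  # virus: fuse a viral contig onto the host, then run cycles on the fusion
  nv <- params$n_virus %||% 2L
  host_break <- params$host_segment %||% max(2L, n %/% 2L)
  vlayout <- uniform_layout(nv, "virus1", seg_len = 1e3, origin = "virus")
  vit <- junction_row(breakpoint("chr1", host_break * 1e4, "tail"),
                      breakpoint("virus1", 0, "head"),
                      virus_contigs = "virus1")
  vit$seg_a <- host_break; vit$seg_b <- 1L
  fused <- build_virtual_contig(list(uniform_layout(n, "chr1"), vlayout), vit)
  vf <- params$virus_fusions %||% c(nrow(fused), 2L)
  vpath <- perfect_bfb_path(nrow(fused), vf, final_cut = 1L)
  x <- bfb_path(vpath, fused,
                history = list(list(stage = 1L, op = "VIT",
                                    detail = list(host_segment = host_break))))
  list(truth = x, stage1_path = vpath, junctions = realized_junctions(x),
       mode = "trx-to-bfb", vit = vit, fused_layout = fused)
}

#' Derive noisy observables from a ground-truth path
#'
#' Segment CNs are exact multiplicities plus optional rounded Gaussian
#' jitter; the junction list suffers independent dropout; linkage evidence
#' reports the oriented adjacencies of the true path (what linked/long reads
#' would phase).
#'
#' @param truth a `BfbPath`.
#' @param cn_jitter_sd standard deviation of the CN noise (default 0).
#' @param dropout probability each junction is missed (default 0).
#' @param with_linkage emit linkage adjacencies (default FALSE).
#' @return List with `segments` (layout + observed_cn), `junctions`
#'   (junction table with observed multiplicities as `observed_cn`),
#'   `linkage` (data.frame seg_a/or_a/seg_b/or_b or NULL).
#' @export
derive_observables <- function(truth, cn_jitter_sd = 0, dropout = 0,
                               with_linkage = FALSE) {
  layout <- truth$layout
  cn <- segment_counts(truth$path, n = nrow(layout))
  if (cn_jitter_sd > 0) {
    cn <- pmax(0, cn + round(stats::rnorm(length(cn), 0, cn_jitter_sd)))
  }
  segments <- layout
  segments$observed_cn <- as.numeric(cn)

  jn <- realized_junctions(truth)
  if (nrow(jn) > 0L) {
    key <- apply(jn[, c("contig_a", "pos_a", "end_a",
                        "contig_b", "pos_b", "end_b", "jtype")], 1L,
                 paste, collapse = "|")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    jn <- jn[!duplicated(key), , drop = FALSE]
    jn$observed_cn <- agg$Freq[match(key[!duplicated(key)], agg$key)]
    jn$support <- jn$observed_cn * 10L
    if (dropout > 0) {
      keep <- stats::runif(nrow(jn)) >= dropout
      jn <- jn[keep, , drop = FALSE]
    }
    rownames(jn) <- NULL
  }

  linkage <- NULL
  if (with_linkage) {
    p <- truth$path
    if (length(p) >= 2L) {
      adj <- unique(data.frame(
        seg_a = abs(p[-length(p)]),
        or_a = ifelse(p[-length(p)] > 0, "+", "-"),
        seg_b = abs(p[-1L]),
        or_b = ifelse(p[-1L] > 0, "+", "-"),
        stringsAsFactors = FALSE))
      rownames(adj) <- NULL
      linkage <- adj
    }
  }
  list(segments = segments, junctions = jn, linkage = linkage)
}

#' Simulate a batch of BFB paths with a manifest
#'
#' @param config list: `batch_size`, `n_segments` (range, default c(6, 15)),
#'   `n_cycles` (range, default c(2, 7)), `total_cn` (range, default
#'   c(13, 105)), `max_cn` (range, default c(3, 11)),
#'   `minor_dup_prob` (default 0.3), `seed`.
#' @return List with `paths` (list of integer vectors) and `manifest`
#'   (data.frame: id, seed, n_segments, n_fbis, total_cn, max_cn,
#'   minor_dup). Paths outside the CN ranges are rejection-resampled.
#' @export
simulate_batch <- function(config = list()) {
  bs <- config$batch_size %||% 10L
  rng_seed <- config$seed %||% 1L
  nseg_r <- config$n_segments %||% c(6L, 15L)
  ncyc_r <- config$n_cycles %||% c(2L, 7L)
  tot_r <- config$total_cn %||% c(13L, 105L)
  max_r <- config$max_cn %||% c(3L, 11L)
  dup_p <- config$minor_dup_prob %||% 0.3
  set.seed(rng_seed)
  paths <- vector("list", bs)
  rows <- vector("list", bs)
  for (b in seq_len(bs)) {
    repeat {
      n <- sample(nseg_r[1]:nseg_r[2], 1L)
      k <- sample(ncyc_r[1]:ncyc_r[2], 1L)
      p <- simulate_history(n, k)
      cnt <- segment_counts(p, n)
      if (sum(cnt) >= tot_r[1] && sum(cnt) <= tot_r[2] &&
          max(cnt) >= max_r[1] && max(cnt) <= max_r[2]) break
    }
    md <- add_minor_duplications(p, dup_p)
    paths[[b]] <- md$path
    cnt <- segment_counts(md$path, n)
    rows[[b]] <- data.frame(
      id = b, seed = rng_seed, n_segments = n, n_fbis = k,
      total_cn = sum(cnt), max_cn = max(cnt),
      minor_dup = !is.null(md$dup))
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id = integer(0), seed = integer(0), n_segments = integer(0),
               n_fbis = integer(0), total_cn = integer(0),
               max_cn = integer(0), minor_dup = logical(0))
  }
  list(paths = paths, manifest = manifest)
}

#' Per-contig solver inputs from a simulated instance
#'
#' Splits a ground-truth path's (possibly stacked or virtual) layout back
#' into per-contig layouts with local indices and per-contig observed CN
#' vectors -- the shape [bfb_solve()] consumes.
#'
#' @param truth a `BfbPath` from the simulator.
#' @param observables output of [derive_observables()] on `truth`.
#' @return List with `layouts` (named list) and `segment_cn` (named list).
#' @export
simulated_solver_inputs <- function(truth, observables) {
  lay <- truth$layout
  cn <- observables$segments$observed_cn
  if (!is.null(lay$src_contig)) {
    d <- data.frame(contig = lay$src_contig, start = lay$src_start,
                    end = lay$src_end, index = lay$src_index,
                    observed_cn = cn, origin = lay$origin,
                    stringsAsFactors = FALSE)
  } else {
    d <- data.frame(contig = lay$contig, start = lay$start, end = lay$end,
                    index = lay$index, observed_cn = cn,
                    origin = lay$origin, stringsAsFactors = FALSE)
  }
  layouts <- list(); cns <- list()
  for (ct in unique(d$contig)) {
    dd <- d[d$contig == ct, , drop = FALSE]
    dd <- dd[order(dd$start), , drop = FALSE]
    dd$index <- seq_len(nrow(dd))
    rownames(dd) <- NULL
    layouts[[ct]] <- dd[, c("contig", "start", "end", "index",
                            "observed_cn", "origin")]
    cns[[ct]] <- dd$observed_cn
  }
  list(layouts = layouts, segment_cn = cns)
}
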