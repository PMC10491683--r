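# Benchmarking metrics and the exhaustive fusion-breakage oracle.

#' Copy-number accuracy
#'
#' Fraction of segments whose predicted CN equals the truth.
#'
#' @param pred,truth numeric vectors over the same segmentation.
#' @return Value in `[0, 1]`.
#' @export
cn_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("segment count mismatch")
  mean(pred == truth)
}

#' Total copy-number error
#'
#' Sum of absolute per-segment CN differences.
#'
#' @inheritParams cn_accuracy
#' @return Non-negative number.
#' @export
total_cn_error <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("segment count mismatch")
  sum(abs(pred - truth))
}

junction_match_key <- function(j) {
  paste(j$contig_a, j$contig_b, j$jtype)
}

#' Structural-variant precision, recall and F1
#'
#' A predicted junction matches a truth junction when the type agrees and
#' both breakpoints lie within `tol` bp (one-to-one matching; distinct
#' junctions by default, multiset multiplicities optional).
#'
#' @param pred,truth junction tables (see [junction_row()]).
#' @param tol breakpoint tolerance in bp (default 50).
#' @param multiset count junction multiplicities via `observed_cn` when
#'   TRUE; default FALSE counts distinct junctions.
#' @return List with `precision`, `recall`, `f1`, `tp`, `fp`, `fn` and
#'   `degenerate` (TRUE when both sets were empty: all metrics 1 by
#'   convention).
#' @export
sv_metrics <- function(pred, truth, tol = 50, multiset = FALSE) {
  dedup <- function(j) {
    if (nrow(j) == 0L) return(j)
    key <- paste(j$contig_a, round(j$pos_a / max(tol, 1)), j$end_a,
                 j$contig_b, round(j$pos_b / max(tol, 1)), j$end_b, j$jtype)
    if (!multiset) j <- j[!duplicated(key), , drop = FALSE]
    j
  }
  pred <- dedup(pred); truth <- dedup(truth)
  if (nrow(pred) == 0L && nrow(truth) == 0L) {
    return(list(precision = 1, recall = 1, f1 = 1, tp = 0L, fp = 0L,
                fn = 0L, degenerate = TRUE))
  }
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(pred))) {
    for (k in seq_len(nrow(truth))) {
      if (used[k]) next
      if (pred$jtype[i] == truth$jtype[k] &&
          pred$contig_a[i] == truth$contig_a[k] &&
          pred$contig_b[i] == truth$contig_b[k] &&
          abs(pred$pos_a[i] - truth$pos_a[k]) <= tol &&
          abs(pred$pos_b[i] - truth$pos_b[k]) <= tol) {
        used[k] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  fp <- nrow(pred) - tp
  fn <- nrow(truth) - tp
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, degenerate = FALSE)
}

#' Exhaustive realizability oracle for small instances
#'
#' Enumerates every fusion-breakage path (forward search over the grammar)
#' and reports whether some path realizes the given segment CN vector --
#' and, when supplied, the given fold-back index set -- together with the
#' minimal cycle count. Guard rails: n <= 5 segments and total CN <= 14.
#'
#' @param cn_vector non-negative integer segment CN vector.
#' @param fold_indices optional integer set of segment indices at which
#'   fold-backs must (and may only) occur.
#' @param max_cycles cycle bound for the search.
#' @return List with `feasible` and `min_cycles` (NA when infeasible).
#' @export
bfb_realizability_oracle <- function(cn_vector, fold_indices = NULL,
                                     max_cycles = 8L) {
  n <- length(cn_vector)
  if (n > 5L || sum(cn_vector) > 14L) {
    stop("oracle guard rails: n <= 5 and total CN <= 14")
  }
  if (any(cn_vector < 1L)) return(list(feasible = FALSE, min_cycles = NA))
  enum <- enumerate_bfb_paths(n, max_len = sum(cn_vector),
                              max_cycles = max_cycles)
  best <- NA_integer_
  for (k in seq_along(enum$paths)) {
    p <- enum$paths[[k]]
    if (!identical(segment_counts(p, n), as.integer(cn_vector))) next
    if (!is.null(fold_indices)) {
      got <- sort(unique(fold_adjacencies(p)$index))
      if (!identical(got, sort(unique(as.integer(fold_indices))))) next
    }
    if (is.na(best) || enum$cycles[k] < best) best <- enum$cycles[k]
  }
  list(feasible = !is.na(best), min_cycles = best)
}

#' Evaluate a reconstruction against ground truth
#'
#' @param pred a `BfbPath` (reconstruction).
#' @param truth a `BfbPath` (ground truth over the same layout).
#' @param tol breakpoint matching tolerance in bp.
#' @param criterion `"simulation"` (resolved needs CN accuracy 1 and SV
#'   precision/recall/F1 1) or `"real"` (resolved needs FBI recall 1).
#' @return An `EvaluationReport` list: cn_accuracy, total_cn_error,
#'   sv_precision/recall/f1, fbi_recall, cycle_count, resolved,
#'   virtual_used.
#' @export
evaluate_reconstruction <- function(pred, truth, tol = 50,
                                    criterion = c("simulation", "real")) {
  criterion <- match.arg(criterion)
  pc <- realized_segment_cn(pred)
  tc <- realized_segment_cn(truth)
  key <- function(d) paste(d$contig, d$start, d$end)
  if (!setequal(key(pc), key(tc))) {
    stop("segmentation mismatch between pred and truth")
  }
  pc <- pc[match(key(tc), key(pc)), , drop = FALSE]
  pj <- realized_junctions(pred)
  tj <- realized_junctions(truth)
  sv <- sv_metrics(pj, tj, tol = tol)
  fbi_t <- tj[grepl("^FBI", tj$jtype), , drop = FALSE]
  fbi_p <- pj[grepl("^FBI", pj$jtype), , drop = FALSE]
  fbi <- sv_metrics(fbi_p, fbi_t, tol = tol)
  core <- pred$flags$core %||% pred$path
  hist <- derive_history(core)
  acc <- cn_accuracy(pc$cn, tc$cn)
  resolved <- if (criterion == "simulation") {
    acc == 1 && sv$precision == 1 && sv$recall == 1
  } else {
    fbi$recall == 1
  }
  list(cn_accuracy = acc,
       total_cn_error = total_cn_error(pc$cn, tc$cn),
       sv_precision = sv$precision, sv_recall = sv$recall, sv_f1 = sv$f1,
       fbi_recall = fbi$recall,
       cycle_count = hist$cycles,
       resolved = resolved,
       virtual_used = isTRUE(length(pred$flags$virtual_folds) > 0))
}
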