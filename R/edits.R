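# Post-composition revisions: imperfect fold-backs, intra-chromosomal
# DEL/DUP/INS edits, translocation concatenation and virtual contigs.

#' Rewrite perfect fold-backs into their observed imperfect form
#'
#' Imperfect fold-backs (s_i, s_bar_j) are solved as perfect folds at one
#' canonical index (the endpoint on the longer retained arm: the higher
#' index for tail-to-tail, the lower for head-to-head); after composition
#' the realized perfect adjacency is revised back, dropping the skipped
#' segments on the shorter arm.
#'
#' @param path integer vector (signed segment indices).
#' @param fold_map data.frame with columns `i`, `j` (i < j), `dir` ("tt" or
#'   "hh") and optional `copies` (default 1): for "tt" the canonical fold is
#'   at j and the return arm resumes at -i (dropping -j..-(i+1)); for "hh"
#'   the canonical fold is at i and the incoming arm stops at -j (dropping
#'   -(j-1)..-i).
#' @return The revised path.
#' @export
restore_imperfect_folds <- function(path, fold_map) {
  if (is.null(fold_map) || nrow(fold_map) == 0L) return(path)
  if (is.null(fold_map$copies)) fold_map$copies <- 1L
  for (r in seq_len(nrow(fold_map))) {
    i <- fold_map$i[r]; j <- fold_map$j[r]; dir <- fold_map$dir[r]
    stopifnot(i < j)
    for (cp in seq_len(fold_map$copies[r])) {
      done <- FALSE
      if (dir == "tt") {
        # ... +j | -j -(j-1) .. -(i+1) -i ...  ->  ... +j | -i ...
        for (pos in seq_len(length(path) - 1L)) {
          span <- pos + seq_len(j - i)
          if (path[pos] == j && max(span) < length(path) &&
              identical(path[span], -(j:(i + 1L))) &&
              path[max(span) + 1L] == -i) {
            path <- path[-span]
            done <- TRUE
            break
          }
        }
      } else {
        # ... -j -(j-1) .. -i | +i ...  ->  ... -j | +i ...
        for (pos in seq_len(length(path) - 1L)) {
          span <- (pos - (j - i) + 1L):pos
          if (path[pos] == -i && path[pos + 1L] == i && min(span) > 1L &&
              path[min(span) - 1L] == -j &&
              identical(path[span], -((j - 1L):i))) {
            path <- path[-span]
            done <- TRUE
            break
          }
        }
      }
      if (!done) {
        stop(sprintf("imperfect fold (%d,%d,%s): no matching perfect adjacency in path",
                     i, j, dir))
      }
    }
  }
  path
}

#' Apply intra-chromosomal DEL/DUP/INS edits to a composed path
#'
#' Each edit revises one path copy (the leftmost matching occurrence by
#' default). Deletions remove the spanned reference run inside a forward
#' copy; duplications repeat it; insertions splice a donor run at a given
#' oriented adjacency. Edits spanning a fold-back adjacency are rejected.
#'
#' @param x a `BfbPath`.
#' @param edits list of edits: `list(type = "DEL", i =, j =)` removes
#'   segments i+1..j-1 between +i and +j; `list(type = "DUP", i =, j =)`
#'   repeats the run +i..+j; `list(type = "INS", after =, before =,
#'   donor_layout =, donor =)` inserts the oriented donor run at the
#'   (after, before) adjacency, extending the layout.
#' @param occurrence which matching occurrence to edit (default 1 =
#'   leftmost).
#' @return The edited `BfbPath`, history extended with stage-2 events.
#' @export
apply_intra_edits <- function(x, edits, occurrence = 1L) {
  for (ed in edits) {
    p <- x$path
    if (ed$type == "DEL") {
      if (ed$j < ed$i + 2L) stop("DEL edit must span at least one interior segment")
      run <- ed$i:ed$j
      hits <- find_run(p, run)
      if (length(hits) < occurrence) {
        stop(sprintf("DEL edit %d-%d: no intact forward run to edit (fold inside the span?)",
                     ed$i, ed$j))
      }
      pos <- hits[occurrence]
      drop <- (pos + 1L):(pos + length(run) - 2L)
      x$path <- p[-drop]
    } else if (ed$type == "DUP") {
      run <- ed$i:ed$j
      hits <- find_run(p, run)
      if (length(hits) < occurrence) {
        stop(sprintf("DUP edit %d-%d: no intact forward run to edit", ed$i, ed$j))
      }
      pos <- hits[occurrence]
      x$path <- append(p, run, after = pos + length(run) - 1L)
    } else if (ed$type == "INS") {
      at <- which(p[-length(p)] == ed$after & p[-1L] == ed$before)
      if (length(at) < occurrence) {
        stop("INS edit: oriented adjacency not present in path")
      }
      donor <- ed$donor
      if (!is.null(ed$donor_layout)) {
        off <- nrow(x$layout)
        dl <- ed$donor_layout
        dl$index <- dl$index + off
        x$layout <- rbind_layouts(x$layout, dl)
        donor <- ifelse(donor > 0, donor + off, donor - off)
      }
      x$path <- append(p, donor, after = at[occurrence])
    } else {
      stop("unknown edit type: ", ed$type)
    }
    x$history[[length(x$history) + 1L]] <-
      list(stage = 2L, op = ed$type, detail = ed[names(ed) != "donor_layout"])
  }
  x
}

# starting positions of the exact forward run in p
find_run <- function(p, run) {
  L <- length(run)
  out <- integer(0)
  for (pos in seq_len(length(p) - L + 1L)) {
    if (identical(p[pos:(pos + L - 1L)], as.integer(run))) {
      out <- c(out, pos)
    }
  }
  out
}

rbind_layouts <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cl in setdiff(cols, names(a))) a[[cl]] <- NA
  for (cl in setdiff(cols, names(b))) b[[cl]] <- NA
  rbind(a[cols], b[cols])
}

# terminal exposure of a path vector: the (segment, end) facing out
terminal_exposure <- function(vec, side) {
  u <- if (side == "right") vec[length(vec)] else vec[1L]
  if (side == "right") {
    list(seg = abs(u), end = if (u > 0L) "tail" else "head")
  } else {
    list(seg = abs(u), end = if (u > 0L) "head" else "tail")
  }
}

#' Concatenate per-contig BFB paths with translocation junctions
#'
#' BFB-to-TRX mode: each contig's path is composed independently, then
#' blocks are joined at translocation junctions. A junction must attach at a
#' terminal segment of each block (after an optional whole-block reverse
#' complement); junctions interior to both blocks are a composition failure
#' for this mode (use the virtual-contig mode instead).
#'
#' @param paths named list (by contig) of `BfbPath`s over per-contig
#'   layouts.
#' @param trx junction table of TRX junctions, applied in row order.
#' @return A single `BfbPath` over the stacked layout; each input path
#'   appears as one contiguous, possibly reverse-complemented, block.
#' @export
concat_translocations <- function(paths, trx) {
  stopifnot(length(paths) >= 1L)
  # stack layouts with global indices
  offs <- integer(0); combined <- NULL
  for (ct in names(paths)) {
    offs[ct] <- if (is.null(combined)) 0L else nrow(combined)
    lay <- paths[[ct]]$layout
    lay$index <- lay$index + offs[ct]
    combined <- if (is.null(combined)) lay else rbind_layouts(combined, lay)
  }
  blocks <- lapply(names(paths), function(ct) {
    v <- paths[[ct]]$path
    ifelse(v > 0, v + offs[ct], v - offs[ct])
  })
  names(blocks) <- names(paths)
  block_of <- stats::setNames(names(paths), names(paths))  # contig -> slot
  history <- unlist(lapply(paths, function(p) p$history), recursive = FALSE)

  for (r in seq_len(nrow(trx))) {
    ca <- trx$contig_a[r]; cb <- trx$contig_b[r]
    sa <- trx$seg_a[r] + offs[ca]; sb <- trx$seg_b[r] + offs[cb]
    ea <- trx$end_a[r]; eb <- trx$end_b[r]
    ba <- block_of[ca]; bb <- block_of[cb]
    if (is.na(ba) || is.na(bb) || ba == bb) {
      stop("translocation junction does not join two distinct blocks")
    }
    left <- orient_block(blocks[[ba]], sa, ea, "right")
    right <- orient_block(blocks[[bb]], sb, eb, "left")
    if (is.null(left) || is.null(right)) {
      stop(composition_failure(sprintf("TRX %s:%s-%s:%s (endpoint interior to a block)",
                                       ca, ea, cb, eb)))
    }
    blocks[[ba]] <- c(left, right)
    blocks[[bb]] <- NULL
    block_of[block_of == bb] <- ba
    history[[length(history) + 1L]] <-
      list(stage = 2L, op = "TRX",
           detail = list(contigs = c(ca, cb), jtype = trx$jtype[r]))
  }
  if (length(blocks) != 1L) {
    stop("translocation junctions leave more than one block")
  }
  bfb_path(blocks[[1L]], combined, history = history)
}

# return the block oriented so that (seg, end) is exposed on `want` side,
# or NULL when the endpoint is interior
orient_block <- function(vec, seg, end, want) {
  for (v in list(vec, rc_path(vec))) {
    ex <- terminal_exposure(v, want)
    if (ex$seg == seg && ex$end == end) return(v)
  }
  NULL
}

#' Fuse layouts across translocation/integration junctions
#'
#' TRX-to-BFB (and virus) mode: chromosomes are fused along a simple chain
#' of junctions first, and the synthesis is treated as one virtual contig on
#' which BFB cycles are then solved. Junction k joins `layouts[[k]]` to
#' `layouts[[k + 1]]`; retained arms follow the junction ends (a "tail"
#' endpoint keeps the segments to its left in forward orientation, a "head"
#' endpoint the segments to its right; entering arms mirror this).
#'
#' @param layouts ordered list of per-contig layouts.
#' @param junctions junction table, row k joining contig k to contig k+1
#'   (`seg_a`/`end_a` on layout k, `seg_b`/`end_b` on layout k+1).
#' @return A virtual-contig layout with `src_*` columns mapping back to
#'   source coordinates.
#' @export
build_virtual_contig <- function(layouts, junctions = NULL) {
  if (length(layouts) == 1L) return(layouts[[1L]])
  if (is.null(junctions) || nrow(junctions) != length(layouts) - 1L) {
    stop("need exactly one junction per consecutive layout pair (simple chain)")
  }
  pieces <- list()
  for (k in seq_along(layouts)) {
    lay <- layouts[[k]]
    n <- nrow(lay)
    if (k > 1L && junctions$contig_b[k - 1L] != lay$contig[1L]) {
      stop("junction chain does not match the layout order (not a simple path)")
    }
    if (k < length(layouts) && junctions$contig_a[k] != lay$contig[1L]) {
      stop("junction chain does not match the layout order (not a simple path)")
    }
    enter <- if (k > 1L) list(seg = junctions$seg_b[k - 1L],
                              end = junctions$end_b[k - 1L]) else NULL
    leave <- if (k < length(layouts)) list(seg = junctions$seg_a[k],
                                           end = junctions$end_a[k]) else NULL
    for (side in list(enter, leave)) {
      if (!is.null(side) && (is.na(side$seg) || side$seg < 1L || side$seg > n)) {
        stop("junction endpoint does not resolve to a segment of its layout")
      }
    }
    rows_strand <- arm_rows(n, enter, leave)
    piece <- lay[rows_strand$rows, , drop = FALSE]
    piece$src_strand <- rows_strand$strand
    pieces[[k]] <- piece
  }
  fused <- do.call(rbind, pieces)
  data.frame(
    contig = "virtual",
    start = c(0, cumsum(fused$end - fused$start))[seq_len(nrow(fused))],
    end = cumsum(fused$end - fused$start),
    index = seq_len(nrow(fused)),
    observed_cn = fused$observed_cn,
    origin = fused$origin,
    src_contig = fused$contig,
    src_start = fused$start,
    src_end = fused$end,
    src_index = fused$index,
    src_strand = fused$src_strand,
    stringsAsFactors = FALSE
  )
}

# rows and strand of the retained arm of one chain member
arm_rows <- function(n, enter, leave) {
  if (is.null(enter)) {                      # first contig
    if (leave$end == "tail") {
      list(rows = seq_len(leave$seg), strand = 1L)
    } else {
      list(rows = n:leave$seg, strand = -1L)
    }
  } else if (is.null(leave)) {               # last contig
    if (enter$end == "head") {
      list(rows = enter$seg:n, strand = 1L)
    } else {
      list(rows = enter$seg:1L, strand = -1L)
    }
  } else {                                   # middle contig
    if (enter$end == "head" && leave$end == "tail" && enter$seg <= leave$seg) {
      list(rows = enter$seg:leave$seg, strand = 1L)
    } else if (enter$end == "tail" && leave$end == "head" &&
               enter$seg >= leave$seg) {
      list(rows = enter$seg:leave$seg, strand = -1L)
    } else {
      stop("junction chain is not a simple path through the middle contig")
    }
  }
}
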