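# BfbPath: an oriented segment path over a layout, plus its staged history.

#' Construct a BfbPath
#'
#' @param path integer vector of signed segment indices into `layout`.
#' @param layout layout data.frame (see [build_segmentation()]); virtual
#'   contigs may carry `src_contig`/`src_index`/`src_strand` columns mapping
#'   fused segments back to their origin.
#' @param history list of staged events (fusions, edits, concatenations).
#' @param flags named list of provenance flags (e.g. virtual fold-backs).
#' @return A `BfbPath` object.
#' @export
bfb_path <- function(path, layout, history = list(), flags = list()) {
  stopifnot(all(abs(path) >= 1L), all(abs(path) <= nrow(layout)))
  structure(list(path = as.integer(path), layout = layout,
                 history = history, flags = flags),
            class = "BfbPath")
}

#' @export
print.BfbPath <- function(x, ...) {
  cat("BfbPath over", nrow(x$layout), "segments:\n ",
      render_path(x$path), "\n")
  if (length(x$history)) {
    cat(" history:", length(x$history), "events;",
        "stages:", paste(unique(vapply(x$history, function(e) e$stage, 1L)),
                         collapse = ","), "\n")
  }
  invisible(x)
}

# Exposed (contig, position, end-label) of the right edge of an oriented
# segment u and the left edge of its successor, in source coordinates.
oriented_edge <- function(layout, u, side) {
  i <- abs(u)
  row <- layout[layout$index == i, ]
  fwd <- u > 0L
  # side "right": the edge met when leaving u; "left": when entering u
  tail_side <- if (side == "right") fwd else !fwd
  if (!is.null(layout$src_contig)) {
    strand <- row$src_strand * sign(u)
    tail_src <- if (side == "right") strand > 0 else strand < 0
    list(contig = row$src_contig,
         pos = if (tail_src) row$src_end else row$src_start,
         end = if (tail_src) "tail" else "head",
         origin = row$origin)
  } else {
    list(contig = row$contig,
         pos = if (tail_side) row$end else row$start,
         end = if (tail_side) "tail" else "head",
         origin = row$origin)
  }
}

#' Junctions realized by a path
#'
#' Walks consecutive oriented segments and reports every non-reference
#' adjacency as a junction (fold-backs, deletions, duplications,
#' translocations, virus integrations), typed exactly as
#' [classify_junction()] types caller output.
#'
#' @param x a `BfbPath`.
#' @param virus_contigs contigs of viral origin (defaults to layout rows
#'   with origin == "virus").
#' @return A junction table (see [junction_row()]).
#' @export
realized_junctions <- function(x, virus_contigs = NULL) {
  layout <- x$layout
  if (is.null(virus_contigs)) {
    vc <- unique(layout$contig[layout$origin == "virus"])
    if (!is.null(layout$src_contig)) {
      vc <- unique(layout$src_contig[layout$origin == "virus"])
    }
    virus_contigs <- vc
  }
  p <- x$path
  out <- empty_junction_table()
  if (length(p) < 2L) return(out)
  same_contig <- function(u, v) {
    layout$contig[layout$index == abs(u)] ==
      layout$contig[layout$index == abs(v)]
  }
  for (k in seq_len(length(p) - 1L)) {
    u <- p[k]; v <- p[k + 1L]
    if (is.null(layout$src_contig) && same_contig(u, v) &&
        adjacency_kind(u, v) == "ref") next
    eu <- oriented_edge(layout, u, "right")
    ev <- oriented_edge(layout, v, "left")
    # adjacency that is a reference join in source coordinates (virtual
    # contigs renumber segments, so recheck there)
    if (identical(eu$contig, ev$contig) && eu$pos == ev$pos &&
        eu$end != ev$end) next
    jr <- junction_row(breakpoint(eu$contig, eu$pos, eu$end),
                       breakpoint(ev$contig, ev$pos, ev$end),
                       virus_contigs = virus_contigs)
    out <- rbind(out, jr)
  }
  rownames(out) <- NULL
  out
}

#' Segment copy numbers realized by a path, in source coordinates
#'
#' @param x a `BfbPath`.
#' @return data.frame with contig, start, end and cn per layout segment
#'   (source coordinates for virtual contigs).
#' @export
realized_segment_cn <- function(x) {
  layout <- x$layout
  cn <- segment_counts(x$path, n = nrow(layout))
  if (!is.null(layout$src_contig)) {
    data.frame(contig = layout$src_contig, start = layout$src_start,
               end = layout$src_end, cn = cn, stringsAsFactors = FALSE)
  } else {
    data.frame(contig = layout$contig, start = layout$start,
               end = layout$end, cn = cn, stringsAsFactors = FALSE)
  }
}
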