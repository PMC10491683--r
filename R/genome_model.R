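# Coordinate / segment / junction data model.
#
# Coordinates are 0-based half-open internally; VCF readers convert at the
# boundary. A segment's "head" is its lower-coordinate (5' on the forward
# reference strand) end, "tail" the higher-coordinate end. Junction tables,
# layouts and copy-number profiles are plain data.frames throughout.

JUNCTION_TYPES <- c("DEL-ht", "DUP-th", "FBI-hh", "FBI-tt",
                    "TRX-ht", "TRX-th", "TRX-hh", "TRX-tt", "VIT")

#' Construct a breakpoint
#'
#' @param contig contig name.
#' @param pos base-pair position (0-based).
#' @param end which segment end abuts the junction: `"head"` (lower-coordinate
#'   end) or `"tail"` (higher-coordinate end).
#' @return A one-row data.frame with columns contig, pos, end.
#' @export
breakpoint <- function(contig, pos, end) {
  end <- match.arg(end, c("head", "tail"))
  if (!is.numeric(pos) || length(pos) != 1L || is.na(pos) || pos < 0) {
    stop("breakpoint position must be a single non-negative number")
  }
  data.frame(contig = as.character(contig), pos = as.numeric(pos), end = end,
             stringsAsFactors = FALSE)
}

#' Classify a junction from its two breakpoints
#'
#' Same-contig junctions: head-to-tail deletion (DEL-ht), tail-to-head
#' duplication (DUP-th), head-to-head fold-back (FBI-hh), tail-to-tail
#' fold-back (FBI-tt). Cross-contig junctions are translocations
#' (TRX-<end><end>, ends in canonical (contig, pos) order), or VIT when
#' exactly one endpoint lies on a virus contig. The classification is
#' symmetric in its arguments.
#'
#' @param bp_a,bp_b breakpoints (see [breakpoint()]).
#' @param virus_contigs character vector of contig names of viral origin.
#' @return A junction type string.
#' @export
classify_junction <- function(bp_a, bp_b, virus_contigs = character()) {
  for (bp in list(bp_a, bp_b)) {
    if (!all(c("contig", "pos", "end") %in% names(bp))) {
      stop("breakpoints need contig, pos and end fields")
    }
  }
  if (identical(bp_a$contig, bp_b$contig) && bp_a$pos == bp_b$pos &&
      identical(bp_a$end, bp_b$end)) {
    stop("degenerate self-junction: both breakpoints identical")
  }
  # Canonical order by (contig, pos, end).
  if (bp_a$contig > bp_b$contig ||
      (bp_a$contig == bp_b$contig &&
       (bp_a$pos > bp_b$pos ||
        (bp_a$pos == bp_b$pos && bp_a$end > bp_b$end)))) {
    tmp <- bp_a; bp_a <- bp_b; bp_b <- tmp
  }
  if (!identical(bp_a$contig, bp_b$contig)) {
    a_virus <- bp_a$contig %in% virus_contigs
    b_virus <- bp_b$contig %in% virus_contigs
    if (xor(a_virus, b_virus)) return("VIT")
    return(paste0("TRX-", substr(bp_a$end, 1L, 1L), substr(bp_b$end, 1L, 1L)))
  }
  if (bp_a$end == "tail" && bp_b$end == "head") return("DEL-ht")
  if (bp_a$end == "head" && bp_b$end == "tail") return("DUP-th")
  if (bp_a$end == "head") return("FBI-hh")
  "FBI-tt"
}

#' Build a junction table row
#'
#' @inheritParams classify_junction
#' @param support supporting read count.
#' @param observed_cn observed junction copy number (NA when unknown).
#' @return One-row data.frame with the flattened breakpoint pair, `jtype`,
#'   `support`, `observed_cn` and unresolved `seg_a`/`seg_b` indices.
#' @export
junction_row <- function(bp_a, bp_b, support = 1L, observed_cn = NA_real_,
                         virus_contigs = character()) {
  identical_bp <- identical(bp_a$contig, bp_b$contig) &&
    bp_a$pos == bp_b$pos && identical(bp_a$end, bp_b$end)
  jt <- if (identical_bp) {
    # a perfect fold-back joins a segment end to itself on the sister copy
    if (bp_a$end == "head") "FBI-hh" else "FBI-tt"
  } else {
    classify_junction(bp_a, bp_b, virus_contigs)
  }
  # store in the same canonical order classify_junction uses
  if (bp_a$contig > bp_b$contig ||
      (bp_a$contig == bp_b$contig &&
       (bp_a$pos > bp_b$pos ||
        (bp_a$pos == bp_b$pos && bp_a$end > bp_b$end)))) {
    tmp <- bp_a; bp_a <- bp_b; bp_b <- tmp
  }
  data.frame(contig_a = bp_a$contig, pos_a = bp_a$pos, end_a = bp_a$end,
             contig_b = bp_b$contig, pos_b = bp_b$pos, end_b = bp_b$end,
             jtype = jt, support = as.integer(support),
             observed_cn = as.numeric(observed_cn),
             seg_a = NA_integer_, seg_b = NA_integer_,
             stringsAsFactors = FALSE)
}

empty_junction_table <- function() {
  data.frame(contig_a = character(0), pos_a = numeric(0), end_a = character(0),
             contig_b = character(0), pos_b = numeric(0), end_b = character(0),
             jtype = character(0), support = integer(0),
             observed_cn = numeric(0), seg_a = integer(0), seg_b = integer(0),
             stringsAsFactors = FALSE)
}

#' Partition a region into segments at breakpoint positions
#'
#' Internal breakpoint positions cut the region into a gap-free tiling;
#' positions closer than `snap_tol` to an already accepted boundary are
#' snapped onto it instead of creating a near-duplicate segment (caller
#' jitter across sequencing protocols).
#'
#' @param contig contig name of the region.
#' @param start,end region bounds (0-based half-open).
#' @param positions breakpoint positions (may repeat; boundary positions are
#'   ignored).
#' @param snap_tol snapping tolerance in bp (default 50).
#' @param origin segment origin, `"human"` or `"virus"`.
#' @return A reference layout: data.frame with columns contig, start, end,
#'   index, observed_cn (NA), origin.
#' @export
build_segmentation <- function(contig, start, end, positions = numeric(0),
                               snap_tol = 50, origin = "human") {
  if (end <= start) stop("empty region")
  positions <- as.numeric(positions)
  bad <- positions < start | positions > end
  if (any(bad)) {
    stop(sprintf("breakpoint at %s outside region %s:%s-%s",
                 paste(positions[bad], collapse = ","), contig, start, end))
  }
  inner <- sort(unique(positions[positions > start & positions < end]))
  keep <- numeric(0)
  last <- start
  for (p in inner) {
    if (p - last > snap_tol && end - p > snap_tol) {
      keep <- c(keep, p)
      last <- p
    }
  }
  bounds <- c(start, keep, end)
  data.frame(
    contig = contig,
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    index = seq_len(length(bounds) - 1L),
    observed_cn = NA_real_,
    origin = origin,
    stringsAsFactors = FALSE
  )
}

#' Convert read depth to observed copy number
#'
#' The haploid-path depth is `D_h = D_g / (rho * P_t + (1 - rho) * P_n)`
#' (genome depth scaled by purity-weighted ploidy); a feature of depth `D`
#' then has copy number `C = D / D_h`.
#'
#' @param depth observed read depth(s) `D`.
#' @param genome_depth genome-wide average depth `D_g` (> 0).
#' @param purity tumor purity `rho` in (0, 1].
#' @param tumor_ploidy,normal_ploidy average ploidies `P_t`, `P_n`.
#' @return Copy number(s) on the same scale as segment multiplicities.
#' @export
depth_to_copy_number <- function(depth, genome_depth, purity = 1,
                                 tumor_ploidy = 2, normal_ploidy = 2) {
  if (!is.numeric(genome_depth) || genome_depth <= 0) {
    stop("genome_depth must be positive")
  }
  denom <- purity * tumor_ploidy + (1 - purity) * normal_ploidy
  if (denom <= 0) stop("purity-weighted ploidy must be positive")
  d_h <- genome_depth / denom
  depth / d_h
}

# Map one breakpoint onto a segment index of a layout. A "tail" breakpoint
# sits on a segment's right boundary, a "head" breakpoint on a left boundary.
map_breakpoint_to_segment <- function(layout, pos, end, snap_tol = 50) {
  bnd <- if (end == "tail") layout$end else layout$start
  d <- abs(bnd - pos)
  i <- which.min(d)
  if (length(i) == 0L || d[i] > snap_tol) {
    # fall back to the containing segment
    j <- which(layout$start <= pos & pos < layout$end)
    if (length(j) == 0L) return(NA_integer_)
    return(layout$index[j[1L]])
  }
  layout$index[i]
}

#' Resolve junction endpoints to segment indices
#'
#' @param junctions junction table (see [junction_row()]).
#' @param layouts named list of per-contig layouts from
#'   [build_segmentation()].
#' @param snap_tol boundary snapping tolerance in bp.
#' @return The junction table with `seg_a`/`seg_b` filled in; endpoints on
#'   contigs without a layout stay NA.
#' @export
resolve_junction_segments <- function(junctions, layouts, snap_tol = 50) {
  if (nrow(junctions) == 0L) return(junctions)
  for (k in seq_len(nrow(junctions))) {
    la <- layouts[[junctions$contig_a[k]]]
    lb <- layouts[[junctions$contig_b[k]]]
    if (!is.null(la)) {
      junctions$seg_a[k] <- map_breakpoint_to_segment(
        la, junctions$pos_a[k], junctions$end_a[k], snap_tol)
    }
    if (!is.null(lb)) {
      junctions$seg_b[k] <- map_breakpoint_to_segment(
        lb, junctions$pos_b[k], junctions$end_b[k], snap_tol)
    }
  }
  junctions
}
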