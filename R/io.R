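# Readers and writers: SV VCF (breakend notation), segment/CN tables,
# junction and linkage tables, JSON results.
#
# Coordinates are 1-based inclusive in VCF and in the on-disk tables
# (bedtools-style TSVs use 0-based half-open starts, matching the internal
# convention), 0-based half-open internally.

# BND ALT bracket table (VCF 4.2): bracket after the base -> the local
# breakend is the segment tail; bracket before -> head. "[" means the mate
# joins via its head, "]" via its tail.
parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("^([ACGTNacgtn]*)([][])([^:]+):([0-9]+)([][])([ACGTNacgtn]*)$", alt))[[1L]]
  if (length(m) == 0L) return(NULL)
  before <- nzchar(m[2L])           # base precedes the bracket
  bracket <- m[3L]
  list(local_end = if (before) "tail" else "head",
       mate_contig = m[4L],
       mate_pos1 = as.numeric(m[5L]),
       mate_end = if (bracket == "[") "head" else "tail")
}

# 1-based VCF breakend position -> 0-based half-open boundary coordinate
bnd_to_boundary <- function(pos1, end) {
  if (end == "tail") pos1 else pos1 - 1
}
boundary_to_bnd <- function(pos0, end) {
  if (end == "tail") pos0 else pos0 + 1
}

#' Read structural-variant junctions from a VCF
#'
#' Supports breakend (BND) records with bracket ALTs, plus symbolic
#' SVTYPE=DEL/DUP records with INFO/END. INV records are promoted to
#' fold-back junctions only when INFO/CT gives the strand configuration
#' ("5to5" head-to-head, "3to3" tail-to-tail); otherwise they are skipped
#' with a warning. Each BND pair is reported once.
#'
#' @param path VCF file (uncompressed or bgzipped; needs the vcfR package).
#' @param virus_contigs contigs of viral origin (classifies VIT junctions).
#' @param min_support drop records whose support (INFO/SR + INFO/PE, or
#'   SVLEN-less QUAL fallback of 1) is below this (default 1).
#' @return A junction table (see [junction_row()]).
#' @export
read_sv_vcf <- function(path, virus_contigs = character(), min_support = 1L) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_sv_vcf needs the vcfR package")
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_junction_table())
  info <- vcfR::extract.info(v, "SVTYPE")
  getinfo <- function(key) suppressWarnings(vcfR::extract.info(v, key))
  ends <- suppressWarnings(as.numeric(getinfo("END")))
  cts <- getinfo("CT")
  sup_sr <- suppressWarnings(as.numeric(getinfo("SR")))
  sup_pe <- suppressWarnings(as.numeric(getinfo("PE")))
  cns <- suppressWarnings(as.numeric(getinfo("JCN")))
  out <- empty_junction_table()
  skipped <- 0L
  seen_mates <- character(0)
  for (r in seq_len(nrow(fix))) {
    chrom <- fix$CHROM[r]
    pos1 <- as.numeric(fix$POS[r])
    alt <- fix$ALT[r]
    svtype <- info[r]
    support <- sum(c(sup_sr[r], sup_pe[r]), na.rm = TRUE)
    if (support == 0) support <- 1L
    if (!is.na(support) && support < min_support) next
    jr <- NULL
    if (identical(svtype, "BND") || grepl("[\\[\\]]", alt)) {
      bnd <- parse_bnd_alt(alt)
      if (is.null(bnd)) { skipped <- skipped + 1L; next }
      key <- paste(pmin(chrom, bnd$mate_contig), pmax(chrom, bnd$mate_contig),
                   pmin(pos1, bnd$mate_pos1), pmax(pos1, bnd$mate_pos1))
      if (key %in% seen_mates) next
      seen_mates <- c(seen_mates, key)
      jr <- junction_row(
        breakpoint(chrom, bnd_to_boundary(pos1, bnd$local_end), bnd$local_end),
        breakpoint(bnd$mate_contig,
                   bnd_to_boundary(bnd$mate_pos1, bnd$mate_end),
                   bnd$mate_end),
        support = support, observed_cn = cns[r],
        virus_contigs = virus_contigs)
    } else if (identical(svtype, "DEL") && !is.na(ends[r])) {
      jr <- junction_row(breakpoint(chrom, pos1, "tail"),
                         breakpoint(chrom, ends[r] - 1, "head"),
                         support = support, observed_cn = cns[r],
                         virus_contigs = virus_contigs)
    } else if (identical(svtype, "DUP") && !is.na(ends[r])) {
      jr <- junction_row(breakpoint(chrom, pos1 - 1, "head"),
                         breakpoint(chrom, ends[r], "tail"),
                         support = support, observed_cn = cns[r],
                         virus_contigs = virus_contigs)
    } else if (identical(svtype, "INV") && !is.na(ends[r])) {
      if (identical(cts[r], "5to5")) {
        jr <- junction_row(breakpoint(chrom, pos1 - 1, "head"),
                           breakpoint(chrom, ends[r] - 1, "head"),
                           support = support, observed_cn = cns[r])
      } else if (identical(cts[r], "3to3")) {
        jr <- junction_row(breakpoint(chrom, pos1, "tail"),
                           breakpoint(chrom, ends[r], "tail"),
                           support = support, observed_cn = cns[r])
      } else {
        skipped <- skipped + 1L
      }
    } else {
      skipped <- skipped + 1L
    }
    if (!is.null(jr)) out <- rbind(out, jr)
  }
  if (skipped > 0L) {
    warning(skipped, " record(s) skipped (unparseable ALT or unsupported type)")
  }
  rownames(out) <- NULL
  out
}

#' Write junctions as a breakend VCF
#'
#' Two BND records per junction (mates), bracket notation per VCF 4.2.
#'
#' @param junctions junction table.
#' @param path output file.
#' @export
write_sv_vcf <- function(junctions, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate id\">",
           "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Support\">",
           "##INFO=<ID=JCN,Number=1,Type=Float,Description=\"Junction CN\">",
           "##INFO=<ID=JTYPE,Number=1,Type=String,Description=\"Junction class\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  for (r in seq_len(nrow(junctions))) {
    j <- junctions[r, ]
    mk <- function(id, chrom, pos0, end, mchrom, mpos0, mend, mate_id) {
      pos1 <- boundary_to_bnd(pos0, end)
      mpos1 <- boundary_to_bnd(mpos0, mend)
      br <- if (mend == "head") "[" else "]"
      ref <- "N"
      alt <- if (end == "tail") {
        paste0(ref, br, mchrom, ":", mpos1, br)
      } else {
        paste0(br, mchrom, ":", mpos1, br, ref)
      }
      cn <- if (is.na(j$observed_cn)) "" else paste0(";JCN=", j$observed_cn)
      sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s;SR=%d;JTYPE=%s%s",
              chrom, as.integer(pos1), id, ref, alt, mate_id,
              as.integer(j$support), j$jtype, cn)
    }
    ida <- sprintf("bnd_%d_a", r); idb <- sprintf("bnd_%d_b", r)
    rows <- c(rows,
              mk(ida, j$contig_a, j$pos_a, j$end_a,
                 j$contig_b, j$pos_b, j$end_b, idb),
              mk(idb, j$contig_b, j$pos_b, j$end_b,
                 j$contig_a, j$pos_a, j$end_a, ida))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a segment copy-number table
#'
#' TSV with header `contig  start  end  cn` (or `depth` instead of `cn`;
#' depths are converted with [depth_to_copy_number()] and the supplied
#' purity/ploidy). Rows per contig must tile the window without gaps.
#'
#' @param path TSV file.
#' @param genome_depth,purity,tumor_ploidy,normal_ploidy depth-conversion
#'   parameters (used in depth mode).
#' @return List with `layouts` (named list of per-contig layouts) and
#'   `segment_cn` (named list of numeric vectors).
#' @export
read_segments_table <- function(path, genome_depth = 30, purity = 1,
                                tumor_ploidy = 2, normal_ploidy = 2) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("contig", "start", "end") %in% names(d))) {
    stop("segments table needs contig/start/end columns")
  }
  if ("depth" %in% names(d)) {
    d$cn <- depth_to_copy_number(as.numeric(d$depth), genome_depth, purity,
                                 tumor_ploidy, normal_ploidy)
  }
  if (!"cn" %in% names(d)) stop("segments table needs a cn or depth column")
  if (any(is.na(suppressWarnings(as.numeric(d$cn))))) {
    stop("non-numeric CN in segments table")
  }
  if (is.null(d$origin)) d$origin <- "human"
  layouts <- list(); cns <- list()
  for (ct in unique(d$contig)) {
    dd <- d[d$contig == ct, , drop = FALSE]
    dd <- dd[order(dd$start), , drop = FALSE]
    gaps <- which(dd$end[-nrow(dd)] != dd$start[-1L])
    if (length(gaps)) {
      stop(sprintf("gap in %s between %d and %d", ct,
                   dd$end[gaps[1L]], dd$start[gaps[1L] + 1L]))
    }
    layouts[[ct]] <- data.frame(contig = ct, start = dd$start, end = dd$end,
                                index = seq_len(nrow(dd)),
                                observed_cn = as.numeric(dd$cn),
                                origin = dd$origin, stringsAsFactors = FALSE)
    cns[[ct]] <- as.numeric(dd$cn)
  }
  list(layouts = layouts, segment_cn = cns)
}

#' Write a segment copy-number table
#'
#' @param layouts named list of layouts carrying `observed_cn` (or a single
#'   layout data.frame).
#' @param path output TSV.
#' @export
write_segments_table <- function(layouts, path) {
  if (inherits(layouts, "data.frame")) layouts <- list(layouts)
  d <- do.call(rbind, lapply(layouts, function(l) {
    data.frame(contig = l$contig, start = l$start, end = l$end,
               cn = l$observed_cn, origin = l$origin,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain junction table
#'
#' TSV columns: contig_a, pos_a, end_a, contig_b, pos_b, end_b, optional
#' support and observed_cn.
#'
#' @param path TSV file.
#' @param virus_contigs contigs of viral origin.
#' @return A junction table.
#' @export
read_junction_table <- function(path, virus_contigs = character()) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- empty_junction_table()
  for (r in seq_len(nrow(d))) {
    out <- rbind(out, junction_row(
      breakpoint(d$contig_a[r], d$pos_a[r], d$end_a[r]),
      breakpoint(d$contig_b[r], d$pos_b[r], d$end_b[r]),
      support = if (is.null(d$support)) 1L else d$support[r],
      observed_cn = if (is.null(d$observed_cn)) NA_real_ else d$observed_cn[r],
      virus_contigs = virus_contigs))
  }
  rownames(out) <- NULL
  out
}

#' Write a junction table
#' @param junctions junction table.
#' @param path output TSV.
#' @export
write_junction_table <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read linkage evidence
#'
#' TSV columns: seg_a, or_a, seg_b, or_b (oriented segment adjacencies from
#' linked/long reads or optical maps, already expressed in candidate
#' segment indices), optional support.
#'
#' @param path TSV file.
#' @return data.frame usable by [add_linkage_constraints()].
#' @export
read_linkage_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("seg_a", "or_a", "seg_b", "or_b") %in% names(d)))
  d
}

#' Serialize a resolution result to JSON
#'
#' @param result a `BfbResult`.
#' @param path output file (NULL returns the JSON string).
#' @return The path (or JSON string), invisibly.
#' @export
write_result_json <- function(result, path = NULL) {
  obj <- list(
    schema = "bfbmap/result/v1",
    status = result$status,
    objective = result$objective
  )
  if (!is.null(result$path)) {
    lay <- result$path$layout
    obj$path <- list(
      rendered = render_path(result$path$path),
      oriented_segments = lapply(result$path$path, function(u) {
        row <- lay[lay$index == abs(u), ]
        list(contig = row$contig, start = row$start, end = row$end,
             orientation = if (u > 0) "+" else "-")
      }),
      history = result$path$history,
      flags = result$path$flags[setdiff(names(result$path$flags), "core")]
    )
    obj$realized_cn <- realized_segment_cn(result$path)
    obj$realized_junctions <- realized_junctions(result$path)
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", dataframe = "rows")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}
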