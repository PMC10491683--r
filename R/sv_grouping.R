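# Grouping of structural variants into candidate complex events.
#
# Two junctions belong to the same group when a chain of junctions connects
# them, each consecutive pair having breakpoints within `max_gap` on a shared
# contig (transitive closure of breakpoint proximity). Groups holding at
# least `min_fbi` fold-back inversions are BFB candidates.

junction_breakpoints_long <- function(junctions) {
  k <- seq_len(nrow(junctions))
  data.frame(
    id = c(k, k),
    contig = c(junctions$contig_a, junctions$contig_b),
    pos = c(junctions$pos_a, junctions$pos_b),
    stringsAsFactors = FALSE
  )
}

#' Cluster junctions into complex-event groups
#'
#' Breadth-first transitive closure: junctions sharing a contig with nearest
#' breakpoints within `max_gap` are linked; connected components form the
#' groups. Input order does not matter (junctions are canonically sorted
#' before clustering) and the result partitions the input.
#'
#' @param junctions junction table.
#' @param max_gap proximity threshold in bp (default 1e6).
#' @return List of `SvGroup`s, each a list with `junctions` (the member
#'   rows), `fbi_count` and `span` (per-contig breakpoint range). Groups are
#'   ordered by (contig, min breakpoint) of their span.
#' @export
cluster_svs <- function(junctions, max_gap = 1e6) {
  if (is.null(junctions) || nrow(junctions) == 0L) return(list())
  if (max_gap <= 0) stop("max_gap must be positive")
  ord <- order(junctions$contig_a, junctions$pos_a,
               junctions$contig_b, junctions$pos_b, junctions$jtype)
  junctions <- junctions[ord, , drop = FALSE]
  rownames(junctions) <- NULL
  m <- nrow(junctions)
  bps <- junction_breakpoints_long(junctions)

  linked <- function(i, j) {
    bi <- bps[bps$id == i, , drop = FALSE]
    bj <- bps[bps$id == j, , drop = FALSE]
    for (ci in seq_len(nrow(bi))) {
      same <- bj$contig == bi$contig[ci]
      if (any(same) && min(abs(bj$pos[same] - bi$pos[ci])) <= max_gap) {
        return(TRUE)
      }
    }
    FALSE
  }

  comp <- rep(NA_integer_, m)
  ncomp <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue) > 0L) {
      i <- queue[1L]; queue <- queue[-1L]
      for (j in seq_len(m)) {
        if (is.na(comp[j]) && linked(i, j)) {
          comp[j] <- ncomp
          queue <- c(queue, j)
        }
      }
    }
  }

  groups <- lapply(seq_len(ncomp), function(g) {
    mem <- junctions[comp == g, , drop = FALSE]
    rownames(mem) <- NULL
    gb <- junction_breakpoints_long(mem)
    span <- do.call(rbind, lapply(split(gb, gb$contig), function(d) {
      data.frame(contig = d$contig[1L], min = min(d$pos), max = max(d$pos),
                 stringsAsFactors = FALSE)
    }))
    rownames(span) <- NULL
    structure(list(junctions = mem,
                   fbi_count = sum(mem$jtype %in% c("FBI-hh", "FBI-tt")),
                   span = span),
              class = "SvGroup")
  })
  key <- vapply(groups, function(g) {
    paste(g$span$contig[1L], formatC(g$span$min[1L], width = 15, flag = "0"))
  }, character(1))
  groups[order(key)]
}

#' Select BFB candidate groups
#'
#' A group qualifies when it contains at least `min_fbi` fold-back
#' inversions (default 2: "more than one FBI").
#'
#' @param groups list of SvGroups from [cluster_svs()].
#' @param min_fbi minimum FBI count (>= 1).
#' @return The qualifying groups, input order preserved.
#' @export
select_candidates <- function(groups, min_fbi = 2L) {
  if (min_fbi < 1L) stop("min_fbi must be >= 1")
  Filter(function(g) g$fbi_count >= min_fbi, groups)
}

#' Per-contig analysis windows of a candidate group
#'
#' @param group an SvGroup.
#' @param flank padding added on both sides of the breakpoint range (bp).
#' @param max_span groups whose breakpoint range on any contig exceeds this
#'   are flagged and return `NULL` windows (default 10 Mb).
#' @return List with `windows` (data.frame contig/start/end, or NULL when
#'   flagged) and `flagged` (logical).
#' @export
candidate_window <- function(group, flank = 1e4, max_span = 1e7) {
  span <- group$span
  if (any(span$max - span$min > max_span)) {
    return(list(windows = NULL, flagged = TRUE))
  }
  list(windows = data.frame(contig = span$contig,
                            start = pmax(0, span$min - flank),
                            end = span$max + flank,
                            stringsAsFactors = FALSE),
       flagged = FALSE)
}
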