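# BFB DAG over positive-CN entities and palindrome-preserving composition.
#
# Vertices are entities with CN > 0; a directed edge joins a parent to each
# child (shared endpoint, strictly shorter). Paths are composed by walking a
# topological order and inserting each entity copy at a position that keeps
# the whole path inside the fusion-breakage grammar (checked by peeling) and
# preserves a palindromic suffix.

#' Build the BFB DAG of a solved configuration
#'
#' @param config a `CnConfiguration` (see [solve_configuration()]).
#' @return A `BfbDag`: list with `vertices` (entity rows + cn, sorted
#'   canonically: length descending, start ascending, mono-chains before
#'   loops) and `edges` (data.frame from/to of entity ids).
#' @export
build_dag <- function(config) {
  catalog <- config$catalog
  ent <- catalog$entities
  pos <- ent[config$cn[ent$id] > 0, , drop = FALSE]
  if (nrow(pos) == 0L) stop("configuration has no used entities")
  pos$cn <- config$cn[pos$id]
  pos <- pos[order(-pos$len, pos$a, pos$kind), , drop = FALSE]
  rownames(pos) <- NULL
  root_id <- entity_id(catalog, "m", 1L, catalog$n)
  if (!root_id %in% pos$id) stop("root mono-chain absent from configuration")
  edges <- list()
  for (i in seq_len(nrow(pos))) {
    for (j in seq_len(nrow(pos))) {
      if (i != j && is_child(pos[j, ], pos[i, ])) {
        edges[[length(edges) + 1L]] <- c(from = pos$id[i], to = pos$id[j])
      }
    }
  }
  edges <- if (length(edges)) {
    as.data.frame(do.call(rbind, edges))
  } else {
    data.frame(from = integer(0), to = integer(0))
  }
  orphan <- setdiff(pos$id, c(root_id, edges$to))
  if (length(orphan)) {
    stop("orphan entities without a parent in the DAG: ",
         paste(orphan, collapse = ","))
  }
  structure(list(vertices = pos, edges = edges, root_id = root_id,
                 catalog = catalog),
            class = "BfbDag")
}

#' Topological orders of a BFB DAG
#'
#' The first order returned is the canonical one (vertices sorted by length
#' descending, start ascending, mono-chain before loop, ties by id); further
#' orders enumerate alternative linear extensions up to `limit`.
#'
#' @param dag a `BfbDag`.
#' @param limit maximum number of orders.
#' @return List of integer vectors of entity ids, each starting at the root.
#' @export
topological_orders <- function(dag, limit = 1L) {
  ids <- dag$vertices$id               # already in canonical rank order
  rank <- seq_along(ids)
  names(rank) <- ids
  preds <- split(dag$edges$from, factor(dag$edges$to, levels = ids))
  out <- list()
  recurse <- function(placed, remaining) {
    if (length(out) >= limit) return()
    if (length(remaining) == 0L) {
      out[[length(out) + 1L]] <<- placed
      return()
    }
    ready <- remaining[vapply(remaining, function(v) {
      all(preds[[as.character(v)]] %in% placed)
    }, logical(1))]
    for (v in ready[order(rank[as.character(ready)])]) {
      recurse(c(placed, v), setdiff(remaining, v))
      if (length(out) >= limit) return()
    }
  }
  recurse(integer(0), ids)
  out
}

composition_failure <- function(entity_desc) {
  structure(class = c("bfb_composition_failure", "error", "condition"),
            list(message = paste0("no grammar-preserving insertion for entity ",
                                  entity_desc),
                 call = NULL, entity = entity_desc))
}

# All candidate blocks for one entity copy.
entity_blocks <- function(kind, a, b) {
  fwd <- a:b
  rev <- rc_path(fwd)
  if (kind == "m") list(rev, fwd) else list(c(rev, fwd), c(fwd, rev))
}

#' Compose a BFB path along a topological order
#'
#' Starting from one copy of the root mono-chain, every further entity copy
#' is inserted at the rightmost position (trying both orientations) where
#' (i) both new adjacencies are reference or fold-back adjacencies, (ii) the
#' path keeps a palindromic suffix, and (iii) the whole path remains
#' generable by fusion-breakage (peeling check). Throws a structured
#' `bfb_composition_failure` when an entity cannot be placed.
#'
#' @param dag a `BfbDag`.
#' @param order integer vector of entity ids (a topological order).
#' @param check assert the palindromic-suffix invariant and the conservation
#'   of the configuration's segment aggregates after composition (default TRUE).
#' @param budget maximum number of placement attempts in the backtracking
#'   search before giving up (default 4000).
#' @return Integer vector: the composed path (signed segment indices).
#' @export
compose_path <- function(dag, order = NULL, check = TRUE, budget = 4000L) {
  if (is.null(order)) order <- topological_orders(dag, 1L)[[1L]]
  v <- dag$vertices
  ent <- v[match(order, v$id), , drop = FALSE]
  stopifnot(ent$id[1L] == dag$root_id)
  copies <- ent$cn
  copies[1L] <- copies[1L] - 1L
  # flat list of entity copies to place, in topological order
  todo <- list()
  for (k in seq_len(nrow(ent))) {
    for (cp in seq_len(copies[k])) {
      todo[[length(todo) + 1L]] <- k
    }
  }
  attempts <- 0L
  failed_at <- 1L
  place <- function(path, t) {
    if (t > length(todo)) return(path)
    k <- todo[[t]]
    blocks <- entity_blocks(ent$kind[k], ent$a[k], ent$b[k])
    for (pos in rev(seq_len(length(path)))) {
      for (blk in blocks) {
        attempts <<- attempts + 1L
        if (attempts > budget) return(NULL)
        if (adjacency_kind(path[pos], blk[1L]) == "other") next
        if (pos < length(path) &&
            adjacency_kind(blk[length(blk)], path[pos + 1L]) == "other") next
        w <- length(blk)
        if (pos == length(path) && w <= pos &&
            identical(blk, rc_path(path[(pos - w + 1L):pos]))) {
          # appending rc(suffix) IS the fusion-breakage move: no search
          cand <- c(path, blk)
        } else {
          cand <- append(path, blk, after = pos)
          if (palindromic_suffix_length(cand) < 2L) next
          if (!is_bfb_path_fast(cand)) next
        }
        got <- place(cand, t + 1L)
        if (!is.null(got)) return(got)
        if (attempts > budget) return(NULL)
      }
    }
    failed_at <<- max(failed_at, t)
    NULL
  }
  path <- place(ent$a[1L]:ent$b[1L], 1L)
  if (is.null(path)) {
    k <- todo[[min(failed_at, length(todo))]]
    stop(composition_failure(sprintf("%s(%d,%d)", ent$kind[k], ent$a[k],
                                     ent$b[k])))
  }
  if (check) {
    stopifnot(length(path) == sum(ent$len * ent$cn *
                                    ifelse(ent$kind == "l", 2L, 1L)))
    agg <- config_segment_aggregate(
      dag$catalog,
      stats::setNames(ifelse(dag$catalog$entities$id %in% ent$id,
                             ent$cn[match(dag$catalog$entities$id, ent$id)], 0L),
                      dag$catalog$entities$id))
    stopifnot(identical(as.integer(agg),
                        as.integer(segment_counts(path, dag$catalog$n))))
  }
  path
}

#' Search a BFB path realizing target copy numbers and fold-backs
#'
#' Forward search over fusion-breakage moves (append the reverse complement
#' of a suffix): each move realizes a fold-back at the current path end, so
#' the search is guided to place folds only at detected (or virtual) sites
#' while segment counts stay dominated by the target vector. Used as the
#' composition fallback when entity insertion fails.
#'
#' @param target integer vector of target segment CNs (all >= 1).
#' @param required 2 x n logical matrix (rows "tt", "hh"): fold-back
#'   adjacencies that must appear in the path. A plain integer vector is
#'   accepted and requires either direction at those indices.
#' @param caps 2 x n numeric matrix (rows "tt", "hh"): maximum number of
#'   fold adjacencies per site and direction (Inf = unbounded).
#' @param strict restrict fold sites to those with cap > 0 (default TRUE).
#' @param budget node budget for the search.
#' @param max_moves upper bound on fusion-breakage moves tried (iterative
#'   deepening with doubling bounds).
#' @return The path (integer vector), or NULL when the search fails.
#' @export
search_bfb_path <- function(target, required = NULL, caps = NULL,
                            strict = TRUE, budget = 30000L,
                            max_moves = 24L) {
  n <- length(target)
  target <- as.integer(target)
  if (any(target < 1L)) return(NULL)
  simple_req <- NULL
  if (!is.matrix(required)) {
    simple_req <- as.integer(required %||% integer(0))
    required <- matrix(FALSE, 2L, n, dimnames = list(c("tt", "hh"), NULL))
  }
  if (is.null(caps)) {
    caps <- matrix(Inf, 2L, n, dimnames = list(c("tt", "hh"), NULL))
    if (strict) {
      caps[, ] <- 0
      caps[, unique(c(simple_req, which(colSums(required) > 0)))] <- Inf
      if (length(simple_req)) caps[, simple_req] <- Inf
    }
  }
  caps[is.na(caps)] <- Inf
  total <- sum(target)
  nodes <- 0L
  # direction row of a fold adjacency whose left mate is `el`
  dir_of <- function(el) if (el > 0L) 1L else 2L
  dfs <- function(path, counts, used, left) {
    if (identical(counts, target)) {
      ok <- all(used[1L, required[1L, ]] >= 1L) &&
        all(used[2L, required[2L, ]] >= 1L)
      if (ok && length(simple_req)) {
        ok <- all(colSums(used)[simple_req] >= 1L)
      }
      return(if (ok) path else NULL)
    }
    nodes <<- nodes + 1L
    if (nodes > budget) return(NULL)
    L <- length(path)
    # with `left` moves the length can at most double each time, and each
    # move adds at least one segment
    if (left < 1L || L * 2^left < total || L + left > total) return(NULL)
    e <- abs(path[L])
    de <- dir_of(path[L])
    if (counts[e] >= target[e]) return(NULL)    # any append overfills e
    if (used[de, e] >= caps[de, e]) return(NULL)
    if (strict && caps[de, e] <= 0) return(NULL)
    # scan suffix widths incrementally: nc grows by one segment per step,
    # fold usage by the junction fold (w = 1) plus each mirrored internal
    # fold of the suffix; the move introduces exactly those adjacencies
    feasible <- list()
    nc <- counts
    u2 <- used
    u2[de, e] <- u2[de, e] + 1L                  # junction fold at e
    bad_fold <- u2[de, e] > caps[de, e]
    for (w in seq_len(L)) {
      el <- path[L - w + 1L]
      i <- abs(el)
      nc[i] <- nc[i] + 1L
      if (nc[i] > target[i]) break               # longer suffixes only add
      if (w >= 2L && path[L - w + 1L] == -path[L - w + 2L]) {
        d2 <- dir_of(el)                         # mirrored internal fold
        u2[d2, i] <- u2[d2, i] + 1L
        if (u2[d2, i] > caps[d2, i]) bad_fold <- TRUE
      }
      if (bad_fold) break                        # only accumulates with w
      done <- !any(nc < target)
      if (!done) {
        # lookahead: the next fold happens at the new end -el
        nd <- dir_of(-el)
        if (strict && caps[nd, i] <= 0) next
        if (u2[nd, i] >= caps[nd, i] || nc[i] >= target[i]) next
      }
      feasible[[length(feasible) + 1L]] <- list(w = w, nc = nc, u2 = u2)
    }
    for (mv in rev(feasible)) {                  # biggest chunk first
      blk <- rc_path(path[(L - mv$w + 1L):L])
      got <- dfs(c(path, blk), mv$nc, mv$u2, left - 1L)
      if (!is.null(got)) return(got)
      if (nodes > budget) return(NULL)
    }
    NULL
  }
  counts0 <- tabulate(seq_len(n), nbins = n)
  if (identical(counts0, target) && !any(required) && !length(simple_req)) {
    return(seq_len(n))
  }
  used0 <- matrix(0L, 2L, n)
  m_min <- max(1L, ceiling(log2(total / n)))
  m_max <- max(m_min, min(max_moves, total - n))
  for (m in m_min:m_max) {
    got <- dfs(seq_len(n), counts0, used0, m)
    if (!is.null(got)) return(got)
    if (nodes > budget) break
  }
  NULL
}
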