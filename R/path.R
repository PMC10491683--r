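# Core algebra on BFB paths.
#
# A path over one layout of n segments is an integer vector of signed segment
# indices: +i is segment s_i on the forward strand, -i its reverse complement.
# The generative grammar of a BFB path: start from the reference run 1..n and
# repeatedly append the reverse complement of a suffix of the current path
# (one fusion-breakage cycle each). Everything here (validity, minimal
# histories, the simulator, composition checks) is phrased against that
# grammar.

#' Reverse complement of an oriented segment path
#'
#' @param p integer vector of signed segment indices.
#' @return The reverse complement path: orientation flipped, order reversed.
#' @examples
#' rc_path(c(1, 2, -2))  # c(2, -2, -1)
#' @export
rc_path <- function(p) {
  if (length(p) == 0L) return(integer(0))
  -rev(as.integer(p))
}

path_key <- function(p) paste(p, collapse = ",")

#' Length of the longest palindromic suffix
#'
#' A suffix y is palindromic when it equals its own reverse complement
#' (necessarily of even length). Every BFB path produced by at least one
#' fusion-breakage cycle carries one; it is the invariant checked after each
#' composition step.
#'
#' @param p integer vector of signed segment indices.
#' @return Longest even suffix length L >= 2 with that property, or 0L.
#' @export
palindromic_suffix_length <- function(p) {
  p <- as.integer(p)
  L <- length(p)
  best <- 0L
  w <- 2L
  while (w <= L) {
    y <- p[(L - w + 1L):L]
    if (identical(y, rc_path(y))) best <- w
    w <- w + 2L
  }
  best
}

#' Oriented adjacency classification within a path
#'
#' Consecutive elements u -> v are joined by a reference adjacency
#' (+i -> +(i+1) or -i -> -(i-1)) or by a fold-back (+i -> -i, tail-to-tail;
#' -i -> +i, head-to-head). Anything else needs an explicit junction.
#'
#' @param u,v signed segment indices.
#' @return One of "ref", "fold-tt", "fold-hh", "other".
#' @export
adjacency_kind <- function(u, v) {
  if (u > 0 && v == u + 1L) return("ref")
  if (u < 0 && v == u + 1L) return("ref")   # -i -> -(i-1)
  if (u > 0 && v == -u) return("fold-tt")
  if (u < 0 && v == -u) return("fold-hh")
  "other"
}

#' Fold-back adjacencies realized by a path
#'
#' @param p integer vector of signed segment indices.
#' @return data.frame with columns `index` (segment index folded at),
#'   `dir` ("tt" or "hh") and `pos` (position of the left mate in `p`).
#' @export
fold_adjacencies <- function(p) {
  p <- as.integer(p)
  if (length(p) < 2L) {
    return(data.frame(index = integer(0), dir = character(0), pos = integer(0)))
  }
  u <- p[-length(p)]
  v <- p[-1L]
  at <- which(v == -u)
  data.frame(
    index = abs(u[at]),
    dir = ifelse(u[at] > 0L, "tt", "hh"),
    pos = at,
    stringsAsFactors = FALSE
  )
}

#' Segment copy numbers realized by a path
#'
#' @param p integer vector of signed segment indices.
#' @param n number of segments in the layout (defaults to the largest index).
#' @return Integer vector of length n; entry i counts occurrences of +/- i.
#' @export
segment_counts <- function(p, n = max(abs(p))) {
  tabulate(abs(as.integer(p)), nbins = n)
}

# All peel moves applicable to p: p == Z . rc(Y) with Y a suffix of Z.
# Returns the vector of admissible peel widths w (block lengths removed).
peel_widths <- function(p) {
  L <- length(p)
  ws <- integer(0)
  w <- 1L
  while (2L * w <= L) {
    blk <- p[(L - w + 1L):L]
    y <- p[(L - 2L * w + 1L):(L - w)]
    if (identical(blk, rc_path(y))) ws <- c(ws, w)
    w <- w + 1L
  }
  ws
}

#' Minimal fusion-breakage history of a core BFB path
#'
#' Searches breadth-first over "peel" moves (undoing `P = Z | rc(Y)` with `Y`
#' a suffix of `Z`) until the pure reference run `1..n` remains, guaranteeing
#' a minimal cycle count for paths up to `bfs_limit` oriented segments; longer
#' paths fall back to greedy longest-peel and are flagged approximate.
#'
#' @param p integer vector of signed segment indices (the pre-edit core path;
#'   must start at segment 1 forward).
#' @param bfs_limit maximum path length for the exhaustive search (default 64).
#' @return List with `cycles` (integer, NA when not BFB-consistent), `events`
#'   (data.frame, one fusion per cycle in temporal order: `cycle`,
#'   `fold_index`, `dir`, `appended`), `approximate`, and `consistent` flags.
#' @examples
#' derive_history(c(1, 2, 3, -3, -2, 2, 3))$cycles  # 2
#' @export
derive_history <- function(p, bfs_limit = 64L) {
  p <- as.integer(p)
  n <- if (length(p)) max(abs(p)) else 0L
  ref <- seq_len(n)
  fail <- list(cycles = NA_integer_,
               events = data.frame(cycle = integer(0), fold_index = integer(0),
                                   dir = character(0), appended = integer(0),
                                   stringsAsFactors = FALSE),
               approximate = FALSE, consistent = FALSE)
  if (length(p) == 0L) return(fail)
  if (identical(p, ref)) {
    out <- fail; out$cycles <- 0L; out$consistent <- TRUE
    return(out)
  }
  if (!identical(p[seq_len(min(n, length(p)))], ref)) return(fail)

  # longest-peel-first depth-first search with dead-state memo; returns an
  # upper bound on the cycle count (approximate, not necessarily minimal)
  greedy <- function() {
    dead <- new.env(parent = emptyenv())
    dfs <- function(cur, depth) {
      if (identical(cur, ref)) return(depth)
      k <- path_key(cur)
      if (exists(k, envir = dead, inherits = FALSE)) return(NA_integer_)
      for (w in rev(peel_widths(cur))) {
        got <- dfs(cur[seq_len(length(cur) - w)], depth + 1L)
        if (!is.na(got)) return(got)
      }
      assign(k, TRUE, envir = dead)
      NA_integer_
    }
    cycles <- dfs(p, 0L)
    if (is.na(cycles)) return(fail)
    list(cycles = cycles, events = fail$events, approximate = TRUE,
         consistent = TRUE)
  }

  if (length(p) <= bfs_limit) {
    seen <- new.env(parent = emptyenv())
    start_key <- path_key(p)
    assign(start_key, list(parent = NA_character_, w = NA_integer_), envir = seen)
    frontier <- list(p)
    depth <- 0L
    goal_key <- NULL
    n_states <- 1L
    state_cap <- 50000L
    while (length(frontier) > 0L && is.null(goal_key) && n_states < state_cap) {
      depth <- depth + 1L
      nxt <- list()
      for (cur in frontier) {
        ck <- path_key(cur)
        for (w in peel_widths(cur)) {
          z <- cur[seq_len(length(cur) - w)]
          zk <- path_key(z)
          if (!exists(zk, envir = seen, inherits = FALSE)) {
            assign(zk, list(parent = ck, w = w), envir = seen)
            n_states <- n_states + 1L
            if (identical(z, ref)) { goal_key <- zk; break }
            nxt[[length(nxt) + 1L]] <- z
          }
        }
        if (!is.null(goal_key)) break
      }
      frontier <- nxt
    }
    if (is.null(goal_key)) {
      # state-cap overflow: decide consistency greedily, flag approximate
      if (n_states >= state_cap) return(greedy())
      return(fail)
    }
    # Reconstruct the peel chain goal -> start, i.e. cycles in forward order.
    widths <- integer(0)
    states <- list()
    k <- goal_key
    repeat {
      nd <- get(k, envir = seen, inherits = FALSE)
      if (is.na(nd$parent)) break
      widths <- c(widths, nd$w)
      states[[length(states) + 1L]] <- k
      k <- nd$parent
    }
    # widths[1] is the last peel (first cycle when replayed forward).
    cur <- ref
    ev <- vector("list", length(widths))
    for (i in seq_along(widths)) {
      w <- widths[i]
      last <- cur[length(cur)]
      ev[[i]] <- data.frame(cycle = i, fold_index = abs(last),
                            dir = if (last > 0L) "tt" else "hh",
                            appended = w, stringsAsFactors = FALSE)
      cur <- c(cur, rc_path(cur[(length(cur) - w + 1L):length(cur)]))
    }
    stopifnot(identical(cur, p))
    return(list(cycles = length(widths), events = do.call(rbind, ev),
                approximate = FALSE, consistent = TRUE))
  }

  # Long paths: greedy longest-peel, approximate cycle count.
  greedy()
}

#' Test whether a path obeys the fusion-breakage grammar
#'
#' @inheritParams derive_history
#' @return TRUE when some peel sequence reduces `p` to the reference run.
#' @export
is_bfb_path <- function(p, bfs_limit = 64L) {
  is_bfb_path_fast(p)
}

# Depth-first peeling with a dead-state memo: decides generability without
# searching for a minimal history.
is_bfb_path_fast <- function(p) {
  p <- as.integer(p)
  if (length(p) == 0L) return(FALSE)
  n <- max(abs(p))
  ref <- seq_len(n)
  if (length(p) < n || !identical(p[seq_len(n)], ref)) return(FALSE)
  dead <- new.env(parent = emptyenv())
  dfs <- function(cur) {
    if (identical(cur, ref)) return(TRUE)
    k <- path_key(cur)
    if (exists(k, envir = dead, inherits = FALSE)) return(FALSE)
    for (w in rev(peel_widths(cur))) {       # longest peel first
      if (dfs(cur[seq_len(length(cur) - w)])) return(TRUE)
    }
    assign(k, TRUE, envir = dead)
    FALSE
  }
  dfs(p)
}

#' Enumerate all BFB paths up to a length bound
#'
#' Exhaustive forward closure of the fusion-breakage grammar: from the
#' reference run `1..n`, repeatedly append the reverse complement of every
#' suffix, keeping paths of at most `max_len` oriented segments. Used as the
#' independent oracle against the solver and the history search. Guard rails
#' keep the enumeration desk-sized.
#'
#' @param n segment count (n <= 5).
#' @param max_len maximum path length in oriented segments (<= 14).
#' @param max_cycles optional bound on the number of cycles.
#' @return List with `paths` (list of integer vectors, including the
#'   reference) and `cycles` (integer vector, minimal cycle count at first
#'   discovery -- BFS order makes it minimal).
#' @export
enumerate_bfb_paths <- function(n, max_len = 12L, max_cycles = Inf) {
  stopifnot(n >= 1L, n <= 5L, max_len <= 14L)
  ref <- seq_len(n)
  if (length(ref) > max_len) stop("max_len smaller than the reference path")
  seen <- new.env(parent = emptyenv())
  assign(path_key(ref), TRUE, envir = seen)
  paths <- list(ref)
  cycles <- 0L
  frontier <- list(ref)
  depth <- 0L
  while (length(frontier) > 0L && depth < max_cycles) {
    depth <- depth + 1L
    nxt <- list()
    for (cur in frontier) {
      L <- length(cur)
      for (w in seq_len(min(L, max_len - L))) {
        np <- c(cur, rc_path(cur[(L - w + 1L):L]))
        k <- path_key(np)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          paths[[length(paths) + 1L]] <- np
          cycles <- c(cycles, depth)
          nxt[[length(nxt) + 1L]] <- np
        }
      }
    }
    frontier <- nxt
  }
  list(paths = paths, cycles = cycles)
}

#' Human-readable rendering of an oriented segment path
#'
#' @param p integer vector of signed segment indices.
#' @param labels optional character vector of segment labels (default
#'   `H1..Hn`).
#' @return A single string such as `"H1 H2 H3 -H3 -H2 H2 H3"`.
#' @export
render_path <- function(p, labels = NULL) {
  if (length(p) == 0L) return("")
  n <- max(abs(p))
  if (is.null(labels)) labels <- paste0("H", seq_len(n))
  paste(ifelse(p > 0, labels[abs(p)], paste0("-", labels[abs(p)])),
        collapse = " ")
}
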