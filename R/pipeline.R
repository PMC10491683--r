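# End-to-end resolution: junctions + CN profile -> solved configuration ->
# composed, revised local genomic map.

# Fold-back spec extracted from a junction table resolved against a layout.
# Imperfect folds (different segments) are canonicalized onto the endpoint
# of the longer retained arm (higher index for tt, lower for hh) and the
# observed segment CNs are compensated for the segments the imperfect fold
# skipped, so the perfect-path ILP sees a BFB-consistent profile.
fold_spec_from_junctions <- function(junctions, segment_cn) {
  folds <- list(); fmap <- list()
  adj <- segment_cn
  fbi <- junctions[grepl("^FBI", junctions$jtype), , drop = FALSE]
  for (r in seq_len(nrow(fbi))) {
    i <- fbi$seg_a[r]; j <- fbi$seg_b[r]
    if (is.na(i) || is.na(j)) stop("fold-back junction not resolved to segments")
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    dir <- if (fbi$jtype[r] == "FBI-tt") "tt" else "hh"
    canon <- if (dir == "tt") j else i
    copies <- fbi$observed_cn[r]
    if (is.na(copies) || copies < 1) copies <- 1
    copies <- as.integer(round(copies))
    if (i != j) {
      span <- if (dir == "tt") (i + 1L):j else i:(j - 1L)
      adj[span] <- adj[span] + copies
      fmap[[length(fmap) + 1L]] <-
        data.frame(i = i, j = j, dir = dir, copies = copies)
    }
    folds[[length(folds) + 1L]] <-
      data.frame(index = canon, observed_cn = fbi$observed_cn[r],
                 virtual = FALSE)
  }
  fold_df <- if (length(folds)) {
    agg <- do.call(rbind, folds)
    # merge multiple junctions canonicalized onto one index
    out <- stats::aggregate(observed_cn ~ index, data = agg, FUN = sum,
                            na.action = stats::na.pass)
    out$virtual <- FALSE
    out
  } else {
    fold_table()
  }
  list(folds = fold_df,
       fold_map = if (length(fmap)) do.call(rbind, fmap) else NULL,
       adjusted_cn = adj)
}

# Intra-chromosomal DEL/DUP junctions as stage-2 edits, with the CN
# compensation that removes their effect from the profile handed to the
# perfect-BFB ILP.
edits_from_junctions <- function(junctions, segment_cn) {
  edits <- list()
  adj <- segment_cn
  intra <- junctions[junctions$jtype %in% c("DEL-ht", "DUP-th"), , drop = FALSE]
  for (r in seq_len(nrow(intra))) {
    i <- intra$seg_a[r]; j <- intra$seg_b[r]
    if (is.na(i) || is.na(j)) next
    copies <- intra$observed_cn[r]
    if (is.na(copies) || copies < 1) copies <- 1
    copies <- as.integer(round(copies))
    if (intra$jtype[r] == "DEL-ht") {
      if (j >= i + 2L) {
        adj[(i + 1L):(j - 1L)] <- adj[(i + 1L):(j - 1L)] + copies
        edits[[length(edits) + 1L]] <- list(type = "DEL", i = i, j = j)
      }
    } else {
      # DUP-th: head at lower segment i, tail at higher j; run i..j repeated
      adj[i:j] <- pmax(0, adj[i:j] - copies)
      edits[[length(edits) + 1L]] <- list(type = "DUP", i = i, j = j)
    }
  }
  list(edits = edits, adjusted_cn = adj)
}

# does a core path realize every required (direction, index) fold?
folds_covered <- function(core, req_mat) {
  fa <- fold_adjacencies(core)
  for (d in c("tt", "hh")) {
    for (i in which(req_mat[d, ])) {
      if (!any(fa$index == i & fa$dir == d)) return(FALSE)
    }
  }
  TRUE
}

default_options <- function(options = list()) {
  utils::modifyList(list(
    time_limit = 10, order_limit = 4L, solution_limit = 6L,
    compose_budget = 1500L,
    virtual_budget = 3L, virtual_penalty = 2, snap_tol = 50,
    fold_usage = TRUE, parent_constraints = TRUE,
    penalize_unobserved = TRUE, match_tol = 50
  ), options)
}

# Greedy virtual fold-back augmentation: candidate folds sit at segment
# boundaries adjacent to CN steps (largest step first); each accepted
# candidate must strictly improve the penalized objective.
augment_virtual_fbis <- function(catalog, profile, options, linkage = NULL,
                                 budget = 3L) {
  solve_now <- function(prof) {
    prog <- assemble_program(catalog, prof, options)
    if (!is.null(linkage)) prog <- add_linkage_constraints(prog, linkage)
    solve_configuration(prog, options)
  }
  base <- solve_now(profile)
  if (budget <= 0L || (base$status == "optimal" && base$objective == 0)) {
    return(list(config = base, profile = profile, virtual = integer(0)))
  }
  cn <- profile$segment_cn
  n <- length(cn)
  steps <- data.frame(index = integer(0), size = numeric(0))
  for (i in seq_len(n - 1L)) {
    d <- cn[i] - cn[i + 1L]
    if (is.na(d) || d == 0) next
    idx <- if (d > 0) i else i + 1L
    steps <- rbind(steps, data.frame(index = idx, size = abs(d)))
  }
  steps <- steps[!steps$index %in% profile$folds$index, , drop = FALSE]
  steps <- steps[order(-steps$size), , drop = FALSE]
  best <- base; best_prof <- profile
  accepted <- integer(0)
  for (idx in unique(steps$index)) {
    if (length(accepted) >= budget) break
    cand_prof <- best_prof
    cand_prof$folds <- rbind(cand_prof$folds,
                             data.frame(index = idx, observed_cn = NA_real_,
                                        virtual = TRUE))
    cand <- solve_now(cand_prof)
    better <- cand$status %in% c("optimal", "incumbent") &&
      (!best$status %in% c("optimal", "incumbent") ||
         cand$objective < best$objective - 1e-9)
    if (better) {
      best <- cand; best_prof <- cand_prof
      accepted <- c(accepted, idx)
      if (best$objective <= 1e-9) break
    }
  }
  list(config = best, profile = best_prof, virtual = accepted)
}

#' Resolve one layout: fit entity CNs and compose the local genomic map
#'
#' The single-layout workhorse: extracts fold-backs (canonicalizing
#' imperfect ones and compensating the CN profile), fits entity copy
#' numbers by ILP, optionally augments with virtual fold-backs, composes a
#' path along topological orders of the BFB DAG (enumerating alternate
#' optimal configurations when composition fails), then restores imperfect
#' folds and applies DEL/DUP/INS edits.
#'
#' @param layout reference layout (one contig, or a virtual contig).
#' @param segment_cn observed segment CNs (length = nrow(layout)).
#' @param junctions junction table resolved against `layout` (seg_a/seg_b
#'   filled; see [resolve_junction_segments()]).
#' @param linkage optional oriented-adjacency evidence (data.frame
#'   seg_a/or_a/seg_b/or_b).
#' @param edits additional stage-2 edits (see [apply_intra_edits()]).
#' @param options list of thresholds; see Details of [bfb_solve()].
#' @return A `BfbResult` list: `status` ("resolved" or "unresolved"),
#'   `path` (a `BfbPath` with history and flags; flags carry `core`, the
#'   pre-edit composed path, and `virtual_folds`), `config`
#'   (`CnConfiguration`), `history` (fusion events of the core), and
#'   `objective`.
#' @export
resolve_profile <- function(layout, segment_cn, junctions = NULL,
                            linkage = NULL, edits = list(),
                            options = list()) {
  options <- default_options(options)
  n <- nrow(layout)
  if (length(segment_cn) != n) stop("segment_cn length must match layout")
  if (is.null(junctions)) junctions <- empty_junction_table()
  if (nrow(junctions) > 0L && anyNA(c(junctions$seg_a, junctions$seg_b))) {
    lays <- stats::setNames(list(layout), layout$contig[1L])
    junctions <- resolve_junction_segments(junctions, lays,
                                           snap_tol = options$snap_tol)
  }

  fs <- fold_spec_from_junctions(junctions, segment_cn)
  es <- edits_from_junctions(junctions, fs$adjusted_cn)
  profile <- list(segment_cn = es$adjusted_cn, folds = fs$folds)
  catalog <- enumerate_entities(n)

  aug <- augment_virtual_fbis(catalog, profile, options, linkage,
                              budget = options$virtual_budget)
  config <- aug$config
  if (!config$status %in% c("optimal", "incumbent")) {
    return(structure(list(status = "unresolved", path = NULL, config = config,
                          history = NULL, objective = NA_real_),
                     class = "BfbResult"))
  }

  prog_base <- assemble_program(catalog, aug$profile, options)
  if (!is.null(linkage)) prog_base <- add_linkage_constraints(prog_base, linkage)
  # direction-aware fold requirements for composition: every detected FBI
  # junction (canonical index + direction) must appear in the core path
  fbi_rows <- junctions[grepl("^FBI", junctions$jtype), , drop = FALSE]
  req_mat <- matrix(FALSE, 2L, n, dimnames = list(c("tt", "hh"), NULL))
  caps_mat <- matrix(0, 2L, n, dimnames = list(c("tt", "hh"), NULL))
  for (r in seq_len(nrow(fbi_rows))) {
    dir <- if (fbi_rows$jtype[r] == "FBI-tt") "tt" else "hh"
    i <- fbi_rows$seg_a[r]; j <- fbi_rows$seg_b[r]
    canon <- if (dir == "tt") max(i, j) else min(i, j)
    req_mat[dir, canon] <- TRUE
    v <- fbi_rows$observed_cn[r]
    caps_mat[dir, canon] <- caps_mat[dir, canon] +
      if (is.na(v)) Inf else round(v)
  }
  caps_mat[, aug$virtual] <- Inf
  core <- NULL
  tried <- 0L
  while (tried < options$solution_limit) {
    tried <- tried + 1L
    dag <- tryCatch(build_dag(config), error = function(e) NULL)
    if (!is.null(dag)) {
      for (ord in topological_orders(dag, options$order_limit)) {
        core <- tryCatch(compose_path(dag, ord,
                                      budget = options$compose_budget),
                         error = function(e) NULL)
        if (!is.null(core) && !folds_covered(core, req_mat)) core <- NULL
        if (!is.null(core)) break
      }
    }
    if (is.null(core)) {
      # fold-guided forward search for a path with this configuration's
      # segment aggregates, folds only at detected/virtual sites
      target <- as.integer(round(config$seg_agg))
      core <- search_bfb_path(target, required = req_mat,
                              caps = caps_mat, strict = TRUE)
      if (is.null(core)) {
        core <- search_bfb_path(target, required = req_mat, strict = FALSE)
      }
    }
    if (!is.null(core)) break
    prog_base <- add_no_good_cut(prog_base, config$cn)
    config <- solve_configuration(prog_base, options)
    if (!config$status %in% c("optimal", "incumbent")) break
  }
  if (is.null(core)) {
    return(structure(list(status = "unresolved", path = NULL, config = config,
                          history = NULL, objective = config$objective),
                     class = "BfbResult"))
  }

  hist <- derive_history(core)
  # fold-backs realized by the path but absent from the caller output are
  # inferred ("virtual") junctions completing the BFB structure
  fa_core <- fold_adjacencies(core)
  inferred <- if (nrow(fa_core) == 0L) integer(0) else {
    unique(fa_core$index[!mapply(function(i, d) caps_mat[d, i] > 0,
                                 fa_core$index, fa_core$dir)])
  }
  path_vec <- restore_imperfect_folds(core, fs$fold_map)
  x <- bfb_path(path_vec, layout,
                history = c(
                  lapply(seq_len(max(0L, hist$cycles)), function(k) {
                    ev <- hist$events[k, , drop = FALSE]
                    list(stage = 1L, op = "fusion",
                         detail = list(fold = ev$fold_index, dir = ev$dir))
                  })),
                flags = list(core = core,
                             virtual_folds = sort(union(aug$virtual, inferred)),
                             approximate_history = hist$approximate))
  all_edits <- c(es$edits, edits)
  if (length(all_edits)) x <- apply_intra_edits(x, all_edits)
  structure(list(status = "resolved", path = x, config = config,
                 history = hist, objective = config$objective),
            class = "BfbResult")
}

#' @export
print.BfbResult <- function(x, ...) {
  cat("BfbResult:", x$status)
  if (!is.null(x$objective) && !is.na(x$objective)) {
    cat(" (objective ", x$objective, ")", sep = "")
  }
  cat("\n")
  if (!is.null(x$path)) print(x$path)
  invisible(x)
}

# Split a candidate's junctions by role for the multi-contig modes.
split_candidate_junctions <- function(junctions) {
  list(fbi = junctions[grepl("^FBI", junctions$jtype), , drop = FALSE],
       intra = junctions[junctions$jtype %in% c("DEL-ht", "DUP-th"), , drop = FALSE],
       trx = junctions[grepl("^TRX", junctions$jtype), , drop = FALSE],
       vit = junctions[junctions$jtype == "VIT", , drop = FALSE])
}

# Donor insertions: a contig without fold-backs attached to one host contig
# by exactly two cross-contig junctions is spliced into the host path.
# Returns the candidate edits (either junction may be the upstream side).
donor_insertion_candidates <- function(jpair, layouts, host) {
  flip <- function(j) {
    if (j$contig_a == host) j else {
      data.frame(contig_a = j$contig_b, pos_a = j$pos_b, end_a = j$end_b,
                 contig_b = j$contig_a, pos_b = j$pos_a, end_b = j$end_a,
                 jtype = j$jtype, support = j$support,
                 observed_cn = j$observed_cn, seg_a = j$seg_b, seg_b = j$seg_a,
                 stringsAsFactors = FALSE)
    }
  }
  ja <- flip(jpair[1L, ]); jb <- flip(jpair[2L, ])
  donor_ct <- ja$contig_b
  build <- function(j1, j2) {
    d1 <- j1$seg_b; d2 <- j2$seg_b
    donor_run <- if (j1$end_b == "head" && j2$end_b == "tail" && d2 >= d1) {
      d1:d2
    } else if (j1$end_b == "tail" && j2$end_b == "head" && d2 <= d1) {
      -(d1:d2)
    } else {
      return(NULL)
    }
    after <- if (j1$end_a == "tail") j1$seg_a else -j1$seg_a
    before <- if (j2$end_a == "head") j2$seg_a else -j2$seg_a
    list(type = "INS", after = after, before = before,
         donor_layout = layouts[[donor_ct]], donor = donor_run)
  }
  Filter(Negate(is.null), list(build(ja, jb), build(jb, ja)))
}

# The host-side flanks of a donor insertion must be adjacent in the host
# path (the donor was spliced into that adjacency): expose them as linkage
# evidence for the host solve when unambiguous.
donor_implied_linkage <- function(candidates) {
  if (length(candidates) == 0L) return(NULL)
  adj <- unique(do.call(rbind, lapply(candidates, function(ed) {
    data.frame(seg_a = abs(ed$after), or_a = if (ed$after > 0) "+" else "-",
               seg_b = abs(ed$before), or_b = if (ed$before > 0) "+" else "-",
               stringsAsFactors = FALSE)
  })))
  if (nrow(adj) != 1L) return(NULL)   # ambiguous splice orientation
  u <- if (adj$or_a == "+") adj$seg_a else -adj$seg_a
  v <- if (adj$or_b == "+") adj$seg_b else -adj$seg_b
  if (!adjacency_kind(u, v) %in% c("fold-tt", "fold-hh")) return(NULL)
  adj
}

try_donor_insertion <- function(path, jpair, layouts, host) {
  for (ed in donor_insertion_candidates(jpair, layouts, host)) {
    out <- tryCatch(apply_intra_edits(path, list(ed)), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("donor insertion junctions do not match any adjacency of the host path")
}

#' Resolve a BFB candidate across one or more contigs
#'
#' Orchestrates the full reconstruction for a candidate SV group:
#' fold-backs and intra-chromosomal SVs are resolved per contig; contigs
#' without fold-backs that attach to a host by two junctions are spliced in
#' as insertions; remaining translocations either concatenate per-contig
#' BFB paths (mode `"bfb-to-trx"`) or fuse the layouts into a virtual
#' contig first (mode `"trx-to-bfb"`, forced for virus integration chains).
#'
#' @param layouts named list of per-contig layouts.
#' @param segment_cn named list of observed segment CN vectors per contig.
#' @param junctions junction table (segments resolved or resolvable).
#' @param linkage optional linkage evidence for the (single or fused) BFB
#'   layout.
#' @param mode `"bfb-to-trx"` (default for translocations) or
#'   `"trx-to-bfb"`.
#' @param options list: `time_limit` (s, per ILP solve, default 60),
#'   `order_limit` / `solution_limit` (composition fallbacks),
#'   `virtual_budget` (default 3) and `virtual_penalty` (default 2),
#'   `snap_tol` and `match_tol` (bp, default 50).
#' @return A `BfbResult` (see [resolve_profile()]).
#' @export
bfb_solve <- function(layouts, segment_cn, junctions, linkage = NULL,
                      mode = c("bfb-to-trx", "trx-to-bfb"),
                      options = list()) {
  mode <- match.arg(mode)
  options <- default_options(options)
  if (inherits(layouts, "data.frame")) layouts <- list(layouts)
  if (is.null(names(layouts)) || any(names(layouts) == "")) {
    names(layouts) <- vapply(layouts, function(l) l$contig[1L], character(1))
  }
  if (!is.list(segment_cn)) segment_cn <- stats::setNames(list(segment_cn),
                                                          names(layouts))
  junctions <- resolve_junction_segments(junctions, layouts,
                                         snap_tol = options$snap_tol)
  parts <- split_candidate_junctions(junctions)
  if (nrow(parts$vit) > 0L) mode <- "trx-to-bfb"

  fbi_contig <- unique(c(parts$fbi$contig_a, parts$fbi$contig_b))
  cross <- rbind(parts$trx, parts$vit)

  if (mode == "trx-to-bfb" && nrow(cross) > 0L) {
    chain_cts <- unique(c(cross$contig_a, cross$contig_b))
    # donor-insertion case: a donor contig attached by two junctions whose
    # host adjacency is interior to the BFB path is spliced post-hoc instead
    per_ct <- table(c(cross$contig_a, cross$contig_b))
    donors <- setdiff(names(per_ct)[per_ct == 2L], fbi_contig)
    chain <- cross[!(cross$contig_a %in% donors | cross$contig_b %in% donors), ,
                   drop = FALSE]
    if (nrow(chain) > 0L) {
      ends_tab <- table(c(chain$contig_a, chain$contig_b))
      ends <- names(ends_tab)[ends_tab == 1L]
      # the fused reference must read centromere -> unstable end: prefer
      # starting at a host (human) contig; try both orientations and keep
      # the better reconstruction
      human_ends <- ends[vapply(ends, function(ct) {
        all(layouts[[ct]]$origin == "human")
      }, logical(1))]
      starts <- unique(c(intersect(human_ends, fbi_contig), human_ends, ends))
      best <- NULL
      for (start_ct in starts) {
        ordered <- order_junction_chain(chain, start_ct)
        fused <- build_virtual_contig(ordered$layout_list(layouts),
                                      ordered$chain)
        cn <- vapply(seq_len(nrow(fused)), function(g) {
          segment_cn[[fused$src_contig[g]]][fused$src_index[g]]
        }, numeric(1))
        jv <- remap_junctions_to_virtual(parts$fbi, fused)
        res <- resolve_profile(fused, cn, jv, linkage = linkage,
                               options = options)
        if (res$status == "resolved") {
          res <- apply_donor_insertions(res, cross, donors, layouts, fused)
          return(res)
        }
        if (is.null(best)) best <- res
      }
      return(best)
    }
  }

  # per-contig resolution (bfb-to-trx, or a single contig)
  donors <- setdiff(names(layouts), fbi_contig)
  donor_link <- list()
  for (ct in donors) {
    dj <- cross[cross$contig_a == ct | cross$contig_b == ct, , drop = FALSE]
    if (nrow(dj) != 2L) next
    host <- setdiff(unique(c(dj$contig_a, dj$contig_b)), ct)
    dl <- donor_implied_linkage(donor_insertion_candidates(dj, layouts, host))
    if (!is.null(dl)) donor_link[[host]] <- rbind(donor_link[[host]], dl)
  }
  host_results <- list()
  for (ct in intersect(names(layouts), fbi_contig)) {
    jct <- junctions[junctions$contig_a == ct & junctions$contig_b == ct, ,
                     drop = FALSE]
    lk <- rbind(if (is.list(linkage) && !is.data.frame(linkage)) {
      linkage[[ct]]
    } else if (length(intersect(names(layouts), fbi_contig)) == 1L) {
      linkage
    }, donor_link[[ct]])
    host_results[[ct]] <- resolve_profile(layouts[[ct]], segment_cn[[ct]],
                                          jct, linkage = lk,
                                          options = options)
    if (host_results[[ct]]$status != "resolved") return(host_results[[ct]])
  }
  if (length(host_results) == 0L) stop("candidate contains no fold-back junction")

  # splice donor insertions
  for (ct in donors) {
    dj <- cross[cross$contig_a == ct | cross$contig_b == ct, , drop = FALSE]
    if (nrow(dj) == 0L) next
    if (nrow(dj) != 2L) stop("donor contig ", ct, " needs exactly two junctions")
    host <- setdiff(unique(c(dj$contig_a, dj$contig_b)), ct)
    host_results[[host]]$path <-
      try_donor_insertion(host_results[[host]]$path, dj, layouts, host)
    cross <- cross[!(cross$contig_a == ct | cross$contig_b == ct), ,
                   drop = FALSE]
  }

  if (length(host_results) == 1L && nrow(cross) == 0L) {
    return(host_results[[1L]])
  }

  joined <- concat_translocations(lapply(host_results, function(r) r$path),
                                  cross)
  first <- host_results[[1L]]
  structure(list(status = "resolved", path = joined,
                 config = lapply(host_results, function(r) r$config),
                 history = lapply(host_results, function(r) r$history),
                 objective = sum(vapply(host_results,
                                        function(r) r$objective, numeric(1)))),
            class = "BfbResult")
}

# Order cross-contig junctions into a simple chain starting at the BFB
# contig; returns the chain rows plus a layout accessor.
order_junction_chain <- function(chain, start_contig) {
  remaining <- chain
  ordered <- chain[0, ]
  cur <- start_contig
  cts <- c(start_contig)
  while (nrow(remaining) > 0L) {
    hit <- which(remaining$contig_a == cur | remaining$contig_b == cur)
    if (length(hit) == 0L) break
    j <- remaining[hit[1L], ]
    if (j$contig_b == cur) {
      j <- data.frame(contig_a = j$contig_b, pos_a = j$pos_b, end_a = j$end_b,
                      contig_b = j$contig_a, pos_b = j$pos_a, end_b = j$end_a,
                      jtype = j$jtype, support = j$support,
                      observed_cn = j$observed_cn,
                      seg_a = j$seg_b, seg_b = j$seg_a,
                      stringsAsFactors = FALSE)
    }
    ordered <- rbind(ordered, j)
    remaining <- remaining[-hit[1L], , drop = FALSE]
    cur <- j$contig_b
    cts <- c(cts, cur)
  }
  if (nrow(remaining) > 0L) stop("cross-contig junctions do not form a simple chain")
  list(chain = ordered,
       layout_list = function(layouts) layouts[cts])
}

# express fold-back junctions in virtual-contig segment indices
remap_junctions_to_virtual <- function(fbi, fused) {
  if (nrow(fbi) == 0L) return(fbi)
  remap <- function(ct, seg, end) {
    hit <- which(fused$src_contig == ct & fused$src_index == seg)
    if (length(hit) == 0L) return(list(seg = NA_integer_, end = end))
    g <- fused$index[hit[1L]]
    if (fused$src_strand[hit[1L]] < 0L) {
      end <- if (end == "head") "tail" else "head"
    }
    list(seg = g, end = end)
  }
  for (r in seq_len(nrow(fbi))) {
    a <- remap(fbi$contig_a[r], fbi$seg_a[r], fbi$end_a[r])
    b <- remap(fbi$contig_b[r], fbi$seg_b[r], fbi$end_b[r])
    fbi$seg_a[r] <- a$seg; fbi$end_a[r] <- a$end
    fbi$seg_b[r] <- b$seg; fbi$end_b[r] <- b$end
    fbi$contig_a[r] <- "virtual"; fbi$contig_b[r] <- "virtual"
    # direction label follows the (possibly flipped) ends
    if (a$end == "head" && b$end == "head") fbi$jtype[r] <- "FBI-hh"
    if (a$end == "tail" && b$end == "tail") fbi$jtype[r] <- "FBI-tt"
  }
  fbi <- fbi[!is.na(fbi$seg_a) & !is.na(fbi$seg_b), , drop = FALSE]
  fbi
}

apply_donor_insertions <- function(res, cross, donors, layouts, fused) {
  if (res$status != "resolved" || length(donors) == 0L) return(res)
  for (ct in donors) {
    dj <- cross[cross$contig_a == ct | cross$contig_b == ct, , drop = FALSE]
    if (nrow(dj) != 2L) next
    host <- setdiff(unique(c(dj$contig_a, dj$contig_b)), ct)
    # host segments must be translated to virtual indices
    dj2 <- dj
    for (r in seq_len(nrow(dj2))) {
      for (side in c("a", "b")) {
        ctf <- dj2[[paste0("contig_", side)]][r]
        if (ctf == ct) next
        hit <- which(fused$src_contig == ctf &
                       fused$src_index == dj2[[paste0("seg_", side)]][r])
        if (length(hit)) dj2[[paste0("seg_", side)]][r] <- fused$index[hit[1L]]
        dj2[[paste0("contig_", side)]][r] <- "virtual"
      }
    }
    res$path <- try_donor_insertion(res$path, dj2, layouts, "virtual")
  }
  res
}
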