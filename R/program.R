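# Assembly of the copy-number fitting integer linear program.
#
# Objective: minimize sum(eps_i) + sum(xi_i) (+ flat penalties for virtual
# fold-backs), where eps_i bounds the disparity between observed and
# estimated segment CN (mono-chains contribute their CN, loops twice their
# CN) and xi_i the fold-junction disparity under exact run-start fold
# accounting (see add_profile_block). Default constraints: the reference
# path m(1,n) is used at least once; every used entity except the root has
# a used parent; every detected fold-back junction must carry estimated
# CN >= 1.

new_program <- function() {
  p <- new.env(parent = emptyenv())
  p$nv <- 0L
  p$obj <- numeric(0); p$obj2 <- numeric(0); p$obj3 <- numeric(0)
  p$lb <- numeric(0); p$ub <- numeric(0)
  p$vtype <- character(0); p$vname <- character(0)
  p$ri <- list(); p$rx <- list()
  p$rlb <- numeric(0); p$rub <- numeric(0)
  p$meta <- list()
  class(p) <- "BfbProgram"
  p
}

add_var <- function(p, name, lb = 0, ub = Inf, type = "C",
                    obj = 0, obj2 = 0, obj3 = 0) {
  p$nv <- p$nv + 1L
  p$obj[p$nv] <- obj; p$obj2[p$nv] <- obj2; p$obj3[p$nv] <- obj3
  p$lb[p$nv] <- lb; p$ub[p$nv] <- ub
  p$vtype[p$nv] <- type; p$vname[p$nv] <- name
  p$nv
}

add_row <- function(p, idx, coef, lb = -Inf, ub = Inf) {
  k <- length(p$ri) + 1L
  p$ri[[k]] <- as.integer(idx)
  p$rx[[k]] <- as.numeric(coef)
  p$rlb[k] <- lb; p$rub[k] <- ub
  invisible(k)
}

# Add one clone block (variables + rows) for a profile over `catalog`.
# Returns the block's variable maps. `prefix` distinguishes subclones.
add_profile_block <- function(p, catalog, profile, options = list(),
                              prefix = "") {
  n <- catalog$n
  ent <- catalog$entities
  seg_cn <- profile$segment_cn
  stopifnot(length(seg_cn) == n)
  folds <- profile$folds
  if (is.null(folds)) folds <- fold_table()
  if (any(folds$index < 1L | folds$index > n)) {
    stop("fold-back index outside the layout")
  }

  big_m <- options$big_m
  if (is.null(big_m)) {
    big_m <- max(sum(seg_cn, na.rm = TRUE), 2 * max(seg_cn, 0, na.rm = TRUE),
                 1) + 1
  }
  virt_pen <- options$virtual_penalty %||% 2
  use_parent <- options$parent_constraints %||% TRUE
  use_fold <- options$fold_usage %||% TRUE
  penalize_unobserved <- options$penalize_unobserved %||% TRUE
  root_id <- entity_id(catalog, "m", 1L, n)

  # entity copy numbers (integer) with secondary objectives: total copies,
  # then shorter entities cost more (prefer longer). Upper bounds follow
  # the observed CN over the entity's span (plus slack for residuals):
  # loose bounds make the MILP needlessly hard.
  ub_slack <- options$entity_ub_slack %||% 3
  xv <- integer(nrow(ent))
  for (k in seq_len(nrow(ent))) {
    span_cn <- seg_cn[ent$a[k]:ent$b[k]]
    cap <- if (all(is.na(span_cn))) big_m else {
      m0 <- min(span_cn, na.rm = TRUE)
      if (ent$kind[k] == "l") floor(m0 / 2) + ub_slack else m0 + ub_slack
    }
    xv[ent$id[k]] <- add_var(
      p, sprintf("%sx_%s_%d_%d", prefix, ent$kind[k], ent$a[k], ent$b[k]),
      lb = if (ent$id[k] == root_id) 1 else 0, ub = min(cap, big_m),
      type = "I", obj2 = 1, obj3 = n - ent$len[k] + 1)
  }
  xub <- rep(big_m, nrow(ent))
  xub[ent$id] <- p$ub[xv[ent$id]]
  # usage indicators for non-root entities
  yv <- rep(NA_integer_, nrow(ent))
  for (k in seq_len(nrow(ent))) {
    id <- ent$id[k]
    if (id == root_id) next
    yv[id] <- add_var(p, sprintf("%sy_%d", prefix, id), ub = 1, type = "I")
    add_row(p, c(xv[id], yv[id]), c(1, -xub[id]), ub = 0)  # x <= ub(x) y
    add_row(p, c(yv[id], xv[id]), c(1, -1), ub = 0)        # y <= x
    if (use_parent) {
      par <- entity_parents(catalog, id)
      add_row(p, c(xv[par], yv[id]), c(rep(1, length(par)), -1), lb = 0)
    }
  }

  # segment disparity rows
  ev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (is.na(seg_cn[i])) next
    ev[i] <- add_var(p, sprintf("%seps_%d", prefix, i), obj = 1)
    mi <- entities_containing(catalog, i, "m")
    li <- entities_containing(catalog, i, "l")
    idx <- c(xv[mi], xv[li], ev[i])
    cf_lo <- c(rep(1, length(mi)), rep(2, length(li)), 1)
    cf_hi <- c(rep(1, length(mi)), rep(2, length(li)), -1)
    add_row(p, idx, cf_lo, lb = seg_cn[i])   # agg + eps >= c
    add_row(p, idx, cf_hi, ub = seg_cn[i])   # agg - eps <= c
  }

  # Exact fold accounting. Every fold adjacency of a composed core path is
  # owned by the run that starts at it: a loop copy owns one fold at each
  # endpoint (two at i when a == b); a mono-chain copy owns at most one
  # fold, at its run start (head endpoint a when placed forward, tail
  # endpoint b when reverse-complemented), and exactly one mono run -- the
  # path start -- owns none. Variables fa/fb count fold-owning copies per
  # mono and side.
  mono_ids <- ent$id[ent$kind == "m"]
  fav <- rep(NA_integer_, nrow(ent)); fbv <- rep(NA_integer_, nrow(ent))
  for (id in mono_ids) {
    fav[id] <- add_var(p, sprintf("%sfa_%d", prefix, id), ub = xub[id],
                       type = "I")
    fbv[id] <- add_var(p, sprintf("%sfb_%d", prefix, id), ub = xub[id],
                       type = "I")
    add_row(p, c(fav[id], fbv[id], xv[id]), c(1, 1, -1), ub = 0)
  }
  # at most all mono runs except the path start begin at a fold (the rest
  # may be joined by junctions outside the core model, e.g. dropped calls)
  add_row(p, c(fav[mono_ids], fbv[mono_ids], xv[mono_ids]),
          c(rep(1, 2L * length(mono_ids)), rep(-1, length(mono_ids))),
          ub = -1)
  # linear expression of the estimated fold CN at index i
  fold_agg_terms <- function(i) {
    e <- catalog$entities
    la <- e$id[e$kind == "l" & e$a == i]
    lb_ <- e$id[e$kind == "l" & e$b == i]
    ma <- e$id[e$kind == "m" & e$a == i]
    mb <- e$id[e$kind == "m" & e$b == i]
    idx <- c(xv[la], xv[lb_], fav[ma], fbv[mb])
    cf <- rep(1, length(idx))   # l(i,i) appears via both la and lb_: coeff 2
    list(idx = idx, cf = cf)
  }

  # fold disparity rows, usage constraints, virtual candidates
  fold_target <- rep(0, n)
  fold_has_row <- rep(penalize_unobserved, n)
  fold_required <- rep(FALSE, n)
  fold_virtual <- rep(FALSE, n)
  for (r in seq_len(nrow(folds))) {
    i <- folds$index[r]
    if (isTRUE(folds$virtual[r])) {
      fold_virtual[i] <- TRUE
      fold_has_row[i] <- FALSE
    } else {
      fold_required[i] <- use_fold
      if (is.na(folds$observed_cn[r])) {
        fold_has_row[i] <- FALSE
      } else {
        fold_target[i] <- folds$observed_cn[r]
        fold_has_row[i] <- TRUE
      }
    }
  }

  xiv <- rep(NA_integer_, n)
  zv <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    at <- fold_agg_terms(i)
    if (fold_has_row[i]) {
      xiv[i] <- add_var(p, sprintf("%sxi_%d", prefix, i), obj = 1)
      add_row(p, c(at$idx, xiv[i]), c(at$cf, 1), lb = fold_target[i])
      add_row(p, c(at$idx, xiv[i]), c(at$cf, -1), ub = fold_target[i])
    }
    if (fold_virtual[i]) {
      zv[i] <- add_var(p, sprintf("%sz_%d", prefix, i), ub = 1, type = "I",
                       obj = virt_pen)
      add_row(p, c(at$idx, zv[i]), c(at$cf, -big_m), ub = 0)  # agg <= M z
    }
    if (fold_required[i]) {
      add_row(p, at$idx, at$cf, lb = 1)      # detected fold must be used
    }
  }

  list(n = n, xv = xv, yv = yv, ev = ev, xiv = xiv, zv = zv,
       fav = fav, fbv = fbv,
       root_id = root_id, big_m = big_m,
       fold_target = fold_target, fold_required = fold_required,
       fold_virtual = fold_virtual)
}

#' Empty fold-back observation table
#'
#' @param index segment indices carrying a fold-back junction.
#' @param observed_cn observed junction CN (NA drops the disparity row).
#' @param virtual logical; virtual candidates carry a flat penalty instead
#'   of a disparity row and are optional.
#' @return data.frame with columns index, observed_cn, virtual.
#' @export
fold_table <- function(index = integer(0), observed_cn = NA_real_,
                       virtual = FALSE) {
  if (length(index) == 0L) {
    return(data.frame(index = integer(0), observed_cn = numeric(0),
                      virtual = logical(0)))
  }
  data.frame(index = as.integer(index),
             observed_cn = rep_len(as.numeric(observed_cn), length(index)),
             virtual = rep_len(virtual, length(index)))
}

#' Assemble the CN-fitting program for one profile
#'
#' @param catalog entity catalog from [enumerate_entities()].
#' @param profile list with `segment_cn` (numeric, length n, NA = no
#'   disparity row) and `folds` (see [fold_table()]).
#' @param options list: `big_m`, `virtual_penalty` (default 2),
#'   `parent_constraints`, `fold_usage`, `penalize_unobserved` (all default
#'   TRUE), `time_limit` (seconds, default 60).
#' @return A `BfbProgram` ready for [solve_configuration()].
#' @export
assemble_program <- function(catalog, profile, options = list()) {
  p <- new_program()
  blk <- add_profile_block(p, catalog, profile, options)
  p$meta <- list(catalog = catalog, blocks = list(blk), options = options,
                 linkage_status = NULL)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Append read-linkage constraints to a program
#'
#' Each observed oriented adjacency must be realizable by the configuration:
#' reference adjacencies are always realizable (the root covers them);
#' fold-back adjacencies at segment i require a loop with that endpoint or
#' two mono-chain copies sharing it; anything else is flagged unsatisfiable
#' and dropped with a warning.
#'
#' @param program a `BfbProgram` with exactly one profile block.
#' @param linkage data.frame with columns `seg_a`, `or_a` ("+"/"-"),
#'   `seg_b`, `or_b` (oriented adjacency: a then b along the path).
#' @return The program, with `meta$linkage_status` recording per-adjacency
#'   dispositions ("constrained", "vacuous", "dropped").
#' @export
add_linkage_constraints <- function(program, linkage) {
  blk <- program$meta$blocks[[1L]]
  catalog <- program$meta$catalog
  n <- catalog$n
  status <- character(nrow(linkage))
  for (r in seq_len(nrow(linkage))) {
    i <- linkage$seg_a[r]; j <- linkage$seg_b[r]
    oi <- linkage$or_a[r]; oj <- linkage$or_b[r]
    if (i < 1L || i > n || j < 1L || j > n) {
      stop("linkage adjacency references an unknown segment")
    }
    u <- if (oi == "+") i else -i
    v <- if (oj == "+") j else -j
    kind <- adjacency_kind(u, v)
    if (kind == "ref") {
      status[r] <- "vacuous"
      next
    }
    if (kind == "other") {
      warning(sprintf("linkage adjacency (%s%d,%s%d) realizable by no entity; dropped",
                      oi, i, oj, j))
      status[r] <- "dropped"
      next
    }
    # fold-tt at i is realized by loops with b == i or reverse-placed mono
    # runs starting at -i (fb); fold-hh at i by loops with a == i or
    # forward mono runs starting at +i (fa)
    side <- if (kind == "fold-tt") "b" else "a"
    e <- catalog$entities
    li <- e$id[e$kind == "l" & e[[side]] == abs(u)]
    mi <- e$id[e$kind == "m" & e[[side]] == abs(u)]
    fv <- if (side == "b") blk$fbv[mi] else blk$fav[mi]
    add_row(program, c(blk$xv[li], fv),
            rep(1, length(li) + length(fv)), lb = 1)
    status[r] <- "constrained"
  }
  program$meta$linkage_status <- status
  program
}

#' Jointly fit entity CNs for several subclones
#'
#' One program couples per-subclone copies of the CN-fitting model: for each
#' designated clone pair (default: all pairs) and each entity, the absolute
#' CN difference enters the objective with weight `coupling_weight`, pulling
#' subclones toward shared entities while their own disparities are
#' minimized.
#'
#' @param catalog shared entity catalog (all subclones use one layout).
#' @param profiles named list of profiles (see [assemble_program()]), one
#'   per subclone.
#' @param coupling_weight penalty per unit of entity-CN difference
#'   (default 1; 0 decouples the subclones).
#' @param pairs optional 2-column matrix of clone-name pairs to couple.
#' @param options solver options (see [assemble_program()]).
#' @return Named list of `CnConfiguration`s, one per subclone.
#' @export
joint_solve_subclones <- function(catalog, profiles, coupling_weight = 1,
                                  pairs = NULL, options = list()) {
  stopifnot(length(profiles) >= 1L)
  if (is.null(names(profiles))) {
    names(profiles) <- paste0("clone", seq_along(profiles))
  }
  for (pr in profiles) {
    if (length(pr$segment_cn) != catalog$n) {
      stop("subclone profile does not match the shared layout")
    }
  }
  p <- new_program()
  blocks <- list()
  for (nm in names(profiles)) {
    blocks[[nm]] <- add_profile_block(p, catalog, profiles[[nm]], options,
                                      prefix = paste0(nm, "."))
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(names(profiles), 2L))
    if (length(profiles) < 2L) pairs <- matrix(character(0), 0L, 2L)
  }
  if (coupling_weight > 0 && nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      bu <- blocks[[pairs[r, 1L]]]; bv <- blocks[[pairs[r, 2L]]]
      for (id in catalog$entities$id) {
        d <- add_var(p, sprintf("d_%d_%d", r, id), obj = coupling_weight)
        add_row(p, c(d, bu$xv[id], bv$xv[id]), c(1, -1, 1), lb = 0)
        add_row(p, c(d, bu$xv[id], bv$xv[id]), c(1, 1, -1), lb = 0)
      }
    }
  }
  p$meta <- list(catalog = catalog, blocks = blocks, options = options)
  sol <- worker_request(list(problems = list(program_payload(
    p, options$time_limit %||% 60))))$solutions[[1L]]
  out <- lapply(blocks, function(blk) extract_block(p, blk, sol))
  names(out) <- names(profiles)
  out
}
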