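# MILP solving via a persistent HiGHS worker (scipy.optimize.milp).
#
# The worker is a long-lived python process speaking one JSON object per
# line; thousands of desk-scale programs solve in seconds without paying
# interpreter start-up per call. Falls back to one-shot invocation if the
# worker cannot be kept alive.

.bfb <- new.env(parent = emptyenv())

python_binary <- function() {
  env <- Sys.getenv("BFBMAP_PYTHON", "")
  if (nzchar(env)) return(env)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter found on PATH (required for the MILP backend)")
}

worker_script <- function() {
  s <- system.file("python", "milp_solve.py", package = "bfbmap")
  if (!nzchar(s)) {
    # during in-source development
    s <- file.path("inst", "python", "milp_solve.py")
  }
  normalizePath(s, mustWork = TRUE)
}

milp_worker <- function() {
  w <- .bfb$worker
  if (!is.null(w) && w$is_alive()) return(w)
  w <- processx::process$new(python_binary(), worker_script(),
                             stdin = "|", stdout = "|", stderr = "|")
  # handshake
  w$write_input('{"ping": 1}\n')
  line <- worker_read_line(w, timeout = 60)
  if (is.null(line)) {
    err <- paste(w$read_error_lines(), collapse = "\n")
    w$kill()
    stop("MILP worker failed to start: ", err)
  }
  .bfb$worker <- w
  w
}

worker_read_line <- function(w, timeout = 600) {
  chunks <- list(.bfb$stdout_buf %||% "")
  deadline <- Sys.time() + timeout
  repeat {
    buf <- paste(unlist(chunks), collapse = "")
    nl <- regexpr("\n", buf, fixed = TRUE)
    if (nl > 0L) {
      .bfb$stdout_buf <- substring(buf, nl + 1L)
      return(substring(buf, 1L, nl - 1L))
    }
    chunks <- list(buf)
    if (!w$is_alive() || Sys.time() > deadline) return(NULL)
    w$poll_io(200)
    try(w$read_error(), silent = TRUE)     # keep stderr drained
    chunks[[length(chunks) + 1L]] <- w$read_output()
  }
}

# write_input only accepts up to the pipe buffer; loop until drained
worker_write_all <- function(w, text) {
  pending <- charToRaw(enc2utf8(text))
  deadline <- Sys.time() + 600
  while (length(pending) > 0L) {
    if (!w$is_alive() || Sys.time() > deadline) {
      stop("worker died while receiving input")
    }
    pending <- w$write_input(pending)
    if (length(pending) > 0L) w$poll_io(50)
  }
}

worker_request <- function(payload, timeout = 600) {
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  tryCatch({
    w <- milp_worker()
    worker_write_all(w, paste0(json, "\n"))
    line <- worker_read_line(w, timeout)
    if (is.null(line)) stop("worker timed out or died")
    jsonlite::fromJSON(line, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }, error = function(e) {
    # one-shot fallback
    if (!is.null(.bfb$worker)) {
      try(.bfb$worker$kill(), silent = TRUE)
      .bfb$worker <- NULL
    }
    fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
    writeLines(json, fin)
    st <- system2(python_binary(), c(worker_script(), fin, fout))
    if (st != 0L || !file.exists(fout)) {
      stop("MILP backend failed: ", conditionMessage(e))
    }
    jsonlite::fromJSON(fout, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  })
}

program_payload <- function(p, time_limit = NULL, lex = TRUE) {
  cap <- function(v) { v[v == Inf] <- 1e30; v[v == -Inf] <- -1e30; v }
  rows <- rep(seq_along(p$ri), lengths(p$ri))
  out <- list(obj = p$obj,
              lb = cap(p$lb), ub = cap(p$ub), vtype = p$vtype,
              ai = rows, aj = unlist(p$ri), ax = unlist(p$rx),
              rlb = cap(p$rlb), rub = cap(p$rub),
              time_limit = time_limit)
  if (lex) {
    out$obj2 <- p$obj2
    out$obj3 <- p$obj3
  }
  out
}

#' Solve a batch of CN-fitting programs
#'
#' @param programs list of `BfbProgram`s.
#' @param options list; `time_limit` in seconds per program (default 60).
#' @return List of `CnConfiguration`s (see [solve_configuration()]).
#' @export
solve_programs <- function(programs, options = list()) {
  tl <- options$time_limit %||% 60
  payload <- list(problems = lapply(programs, program_payload,
                                    time_limit = tl,
                                    lex = options$lex %||% TRUE))
  ans <- worker_request(payload, timeout = max(600, tl * length(programs)))
  Map(function(prog, sol) extract_configuration(prog, sol),
      programs, ans$solutions)
}

#' Solve one CN-fitting program
#'
#' @param program a `BfbProgram` from [assemble_program()].
#' @param options list; `time_limit` seconds (default 60).
#' @return A `CnConfiguration`: list with `status` ("optimal", "incumbent",
#'   "infeasible", "failed"), `objective`, `cn` (integer per entity id),
#'   `epsilon`, `xi`, `virtual_used` (segment indices of activated virtual
#'   fold-backs), `seg_agg` and `fold_agg` (estimated CN aggregates), and
#'   the `catalog`.
#' @export
solve_configuration <- function(program, options = list()) {
  solve_programs(list(program), options)[[1L]]
}

extract_configuration <- function(program, sol) {
  blk <- program$meta$blocks[[1L]]
  out <- extract_block(program, blk, sol)
  out$linkage_status <- program$meta$linkage_status
  out
}

extract_block <- function(program, blk, sol) {
  catalog <- program$meta$catalog
  if (is.null(sol$x)) {
    return(structure(list(status = sol$status, objective = NA_real_,
                          cn = NULL, epsilon = NULL, xi = NULL,
                          virtual_used = integer(0), seg_agg = NULL,
                          fold_agg = NULL, catalog = catalog),
                     class = "CnConfiguration"))
  }
  x <- as.numeric(sol$x)
  cn <- as.integer(round(x[blk$xv]))
  names(cn) <- catalog$entities$id
  eps <- ifelse(is.na(blk$ev), NA_real_, x[ifelse(is.na(blk$ev), 1L, blk$ev)])
  xi <- ifelse(is.na(blk$xiv), NA_real_, x[ifelse(is.na(blk$xiv), 1L, blk$xiv)])
  virt <- which(!is.na(blk$zv) & round(x[ifelse(is.na(blk$zv), 1L, blk$zv)]) == 1)
  geti <- function(v) ifelse(is.na(v), 0L, as.integer(round(x[ifelse(is.na(v), 1L, v)])))
  fa <- geti(blk$fav); fb <- geti(blk$fbv)
  structure(list(status = sol$status, objective = as.numeric(sol$objective),
                 cn = cn, epsilon = eps, xi = xi,
                 virtual_used = as.integer(virt),
                 fold_start_a = fa, fold_start_b = fb,
                 seg_agg = config_segment_aggregate(catalog, cn),
                 fold_agg = config_fold_aggregate(catalog, cn, fa, fb),
                 catalog = catalog),
            class = "CnConfiguration")
}

#' Estimated segment CNs of a configuration
#'
#' Mono-chains containing segment i contribute their CN, loops twice theirs.
#'
#' @param catalog entity catalog.
#' @param cn integer vector of entity CNs indexed by entity id.
#' @return Numeric vector of length n.
#' @export
config_segment_aggregate <- function(catalog, cn) {
  n <- catalog$n
  e <- catalog$entities
  vapply(seq_len(n), function(i) {
    inside <- e$a <= i & e$b >= i
    sum(cn[e$id[inside & e$kind == "m"]]) +
      2 * sum(cn[e$id[inside & e$kind == "l"]])
  }, numeric(1))
}

#' Estimated fold-junction CNs of a configuration
#'
#' Exact run-start accounting: a loop copy realizes one fold at each
#' endpoint (two at i when a == b); a mono-chain copy placed with its run
#' start at a fold realizes one fold there (`fa`/`fb` count such copies per
#' side).
#'
#' @inheritParams config_segment_aggregate
#' @param fa,fb integer vectors indexed by entity id: fold-owning mono
#'   copies at the a (head) and b (tail) endpoint.
#' @return Numeric vector of length n.
#' @export
config_fold_aggregate <- function(catalog, cn, fa = NULL, fb = NULL) {
  n <- catalog$n
  e <- catalog$entities
  if (is.null(fa)) fa <- rep(0L, nrow(e))
  if (is.null(fb)) fb <- rep(0L, nrow(e))
  vapply(seq_len(n), function(i) {
    sum(cn[e$id[e$kind == "l" & e$a == i]]) +
      sum(cn[e$id[e$kind == "l" & e$b == i]]) +
      sum(fa[e$id[e$kind == "m" & e$a == i]]) +
      sum(fb[e$id[e$kind == "m" & e$b == i]])
  }, numeric(1))
}

# Exclude one specific entity-CN assignment from future solves (no-good
# cut). Disjunctive form with indicator binaries: at least one entity must
# deviate up (x_e >= cn_e + 1) or down (x_e <= cn_e - 1).
add_no_good_cut <- function(program, cn) {
  blk <- program$meta$blocks[[1L]]
  M <- blk$big_m + max(cn)
  tag <- length(program$ri)
  sel <- integer(0)
  for (id in seq_along(cn)) {
    xe <- blk$xv[id]
    u <- add_var(program, sprintf("ngu_%d_%d", tag, id), ub = 1, type = "I")
    add_row(program, c(xe, u), c(1, -(cn[id] + 1) - M), lb = -M)  # u=1 -> x >= cn+1
    sel <- c(sel, u)
    if (cn[id] >= 1) {
      v <- add_var(program, sprintf("ngv_%d_%d", tag, id), ub = 1, type = "I")
      add_row(program, c(xe, v), c(1, M), ub = cn[id] - 1 + M)    # v=1 -> x <= cn-1
      sel <- c(sel, v)
    }
  }
  add_row(program, sel, rep(1, length(sel)), lb = 1)
  program
}

release_worker <- function() {
  if (!is.null(.bfb$worker)) {
    try(.bfb$worker$kill(), silent = TRUE)
    .bfb$worker <- NULL
  }
}

.onUnload <- function(libpath) {
  release_worker()
}
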