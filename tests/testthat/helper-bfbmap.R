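# Shared fixtures, all generated in code.

# a CnConfiguration from named entity CNs, e.g. cfg(3, m_1_3 = 1, l_2_3 = 1)
make_config <- function(n, ...) {
  ids_cn <- list(...)
  catal <- enumerate_entities(n)
  cn <- stats::setNames(rep(0L, nrow(catal$entities)), catal$entities$id)
  for (nm in names(ids_cn)) {
    parts <- strsplit(nm, "_")[[1]]
    cn[entity_id(catal, parts[1], as.integer(parts[2]),
                 as.integer(parts[3]))] <- ids_cn[[nm]]
  }
  structure(list(cn = cn, catalog = catal), class = "CnConfiguration")
}

# perfect fold-back junction at a segment boundary of a layout
fold_junction <- function(layout, index, dir = c("tt", "hh"),
                          observed_cn = NA_real_) {
  dir <- match.arg(dir)
  pos <- if (dir == "tt") layout$end[index] else layout$start[index]
  end <- if (dir == "tt") "tail" else "head"
  junction_row(breakpoint(layout$contig[1], pos, end),
               breakpoint(layout$contig[1], pos, end),
               observed_cn = observed_cn)
}

# full noise-free round trip of a simulated single-contig path
round_trip <- function(path_vec, n = max(abs(path_vec)), options = list()) {
  truth <- bfb_path(path_vec, uniform_layout(n))
  obs <- derive_observables(truth)
  res <- resolve_profile(truth$layout, obs$segments$observed_cn,
                         obs$junctions, options = options)
  list(truth = truth, obs = obs, res = res,
       report = if (res$status == "resolved") {
         evaluate_reconstruction(res$path, truth)
       })
}
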