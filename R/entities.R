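# Mono-chain / loop catalog over a layout of n segments.
#
# A mono-chain m(a,b) is the run s_a..s_b (forward or reverse complement); a
# loop l(a,b) is a run concatenated with its own reverse complement. Both are
# indexed by 1 <= a <= b <= n, giving n(n+1)/2 of each. Entities are the
# vertices of the BFB DAG; e(a1,b1) is a child of e(a2,b2) iff they share an
# endpoint and b1-a1 < b2-a2.

#' Enumerate all entities of a layout
#'
#' @param n segment count (>= 1).
#' @return An `EntityCatalog`: list with `n`, `K` (= n(n+1)/2) and
#'   `entities`, a data.frame with columns `id`, `kind` ("m" or "l"), `a`,
#'   `b`, `len` (= b - a + 1). Mono-chains occupy ids 1..K, loops K+1..2K.
#' @examples
#' enumerate_entities(3)$entities  # 6 mono-chains + 6 loops
#' @export
enumerate_entities <- function(n) {
  if (!is.numeric(n) || n < 1L) stop("segment count must be >= 1")
  n <- as.integer(n)
  ab <- do.call(rbind, lapply(seq_len(n), function(a) {
    data.frame(a = a, b = a:n)
  }))
  K <- nrow(ab)
  ent <- rbind(
    data.frame(kind = "m", ab, stringsAsFactors = FALSE),
    data.frame(kind = "l", ab, stringsAsFactors = FALSE)
  )
  ent$id <- seq_len(2L * K)
  ent$len <- ent$b - ent$a + 1L
  structure(list(n = n, K = K,
                 entities = ent[, c("id", "kind", "a", "b", "len")]),
            class = "EntityCatalog")
}

#' Look up an entity id
#'
#' @param catalog an [enumerate_entities()] catalog.
#' @param kind `"m"` or `"l"`.
#' @param a,b segment endpoints, a <= b.
#' @return The entity id.
#' @export
entity_id <- function(catalog, kind, a, b) {
  e <- catalog$entities
  id <- e$id[e$kind == kind & e$a == a & e$b == b]
  if (length(id) != 1L) stop(sprintf("no entity %s(%d,%d)", kind, a, b))
  id
}

#' Child relation between two entities
#'
#' `e1` is a child of `e2` iff they share an endpoint (a1 == a2 or b1 == b2)
#' and e1 is strictly shorter (b1 - a1 < b2 - a2). One extension keeps the
#' DAG connected for degenerate spans: a loop is also a child of the
#' equal-length mono-chain over the same segments (inserting l(a,b) into
#' m(a,b) is a valid fusion), e.g. m(1,1) -> l(1,1) on a single segment.
#'
#' @param e1,e2 one-row entity records (columns kind, a, b).
#' @return Logical.
#' @export
is_child <- function(e1, e2) {
  shared <- e1$a == e2$a || e1$b == e2$b
  if (!shared) return(FALSE)
  if ((e1$b - e1$a) < (e2$b - e2$a)) return(TRUE)
  e1$b - e1$a == e2$b - e2$a && e1$kind == "l" && e2$kind == "m" &&
    e1$a == e2$a && e1$b == e2$b
}

# ids of entities containing segment i (M_i for monos, L_i for loops)
entities_containing <- function(catalog, i, kind) {
  e <- catalog$entities
  e$id[e$kind == kind & e$a <= i & e$b >= i]
}

# ids of parents of entity id e: shared endpoint and strictly longer, plus
# the same-span mono-chain when e is a loop (see is_child)
entity_parents <- function(catalog, id) {
  e <- catalog$entities
  me <- e[e$id == id, ]
  out <- e$id[(e$a == me$a | e$b == me$b) & e$len > me$len]
  if (me$kind == "l") {
    out <- c(out, e$id[e$kind == "m" & e$a == me$a & e$b == me$b])
  }
  out
}
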