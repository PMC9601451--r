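# Gene-set over-representation analysis: hypergeometric upper-tail test
# per set with Benjamini-Hochberg correction across sets.

#' Over-representation test of a query gene list against gene sets
#'
#' For each set, the hypergeometric probability of drawing at least the
#' observed overlap when sampling the query from the universe:
#' `P(X >= k)` with `X ~ Hypergeom(N, K, n)`. This equals the one-sided
#' Fisher exact test on the 2x2 overlap table. Benjamini-Hochberg
#' q-values are computed across sets. The `ease` mode subtracts one from
#' the overlap in the tail (a conservative variant used by some
#' annotation servers).
#'
#' @param query Character vector of query gene symbols (uppercased).
#' @param gene_sets A `gene_set_collection` (see [read_gmt()]).
#' @param universe Explicit gene universe; default is the union of all
#'   set genes (plus the collection's own universe when present). Query
#'   genes outside the universe are dropped with a warning.
#' @param ease Use the EASE-style `k - 1` tail.
#' @return Data.frame sorted by p: `set`, `k_overlap`, `n_query`,
#'   `K_set`, `N_universe`, `p`, `q`, `genes` (comma-separated overlap).
#' @export
ora_test <- function(query, gene_sets, universe = NULL, ease = FALSE) {
  query <- unique(toupper(query))
  if (length(query) == 0) stopf("empty query gene list")
  if (is.null(universe))
    universe <- gene_sets$universe %||%
      unique(toupper(unlist(gene_sets$sets, use.names = FALSE)))
  universe <- unique(toupper(universe))
  drop <- setdiff(query, universe)
  if (length(drop)) {
    warnf("%d query gene(s) outside the universe dropped: %s",
          length(drop), paste(utils::head(drop, 5), collapse = ", "))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) stopf("no query genes left within the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets$sets), function(nm) {
    set_genes <- intersect(toupper(gene_sets$sets[[nm]]), universe)
    K <- length(set_genes)
    hits <- intersect(query, set_genes)
    k <- length(hits)
    k_tail <- if (ease) max(k - 1, 0) else k
    p <- if (k_tail == 0) 1 else
      stats::phyper(k_tail - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k_overlap = k, n_query = n, K_set = K,
               N_universe = N, p = p,
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set),
             c("set", "k_overlap", "n_query", "K_set", "N_universe",
               "p", "q", "genes")]
  rownames(out) <- NULL
  out
}
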