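#' Hypergeometric over-representation test
#'
#' Upper-tail probability of drawing at least `k` set genes when drawing
#' `n` query genes from a universe of `M` genes of which `K` belong to the
#' set: `p = sum_{k'>=k} C(K,k') C(M-K, n-k') / C(M,n)`, evaluated in log
#' space by the hypergeometric distribution function.
#'
#' @param query_genes Character vector of query gene IDs (subset of
#'   universe).
#' @param gene_set Character vector of set gene IDs (intersected with the
#'   universe).
#' @param universe Character vector of background gene IDs.
#' @return List with `p_value`, `overlap` (gene IDs), `k`, `K`, `n`, `M`.
#' @export
ora_hypergeom <- function(query_genes, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query_genes <- unique(query_genes)
  if (length(query_genes) == 0) stop("empty query")
  if (!all(query_genes %in% universe)) {
    stop("query genes must be a subset of the universe")
  }
  set_u <- intersect(unique(gene_set), universe)
  overlap <- intersect(query_genes, set_u)
  k <- length(overlap)
  K <- length(set_u)
  n <- length(query_genes)
  M <- length(universe)
  p <- if (k == 0) 1 else {
    exp(stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE,
                      log.p = TRUE))
  }
  list(p_value = min(p, 1), overlap = sort(overlap),
       k = k, K = K, n = n, M = M)
}

#' Over-representation analysis of a query against a gene-set collection
#'
#' One hypergeometric test per set with at least one universe gene
#' (sets with none are omitted with a warning), BH adjustment across sets,
#' sorted by q, then p, then set name.
#'
#' @param query_genes Query gene IDs (subset of universe).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene IDs (conventionally the genes tested in
#'   the relevant DE contrast).
#' @param alpha Significance threshold annotated in the result
#'   (default 0.05).
#' @return data.frame with columns `set`, `k`, `K`, `n`, `M`, `p_value`,
#'   `q_value`, `significant`, `overlap_genes` (comma-separated).
#' @export
enrich_collection <- function(query_genes, collection, universe,
                              alpha = 0.05) {
  keep <- vapply(collection, function(s) {
    length(intersect(s, universe)) > 0
  }, TRUE)
  if (any(!keep)) {
    warning(sum(!keep), " set(s) with no universe genes omitted")
  }
  collection <- collection[keep]
  if (length(collection) == 0) {
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), M = integer(), p_value = double(),
                      q_value = double(), significant = logical(),
                      overlap_genes = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(collection), function(nm) {
    r <- ora_hypergeom(query_genes, collection[[nm]], universe)
    data.frame(set = nm, k = r$k, K = r$K, n = r$n, M = r$M,
               p_value = r$p_value, q_value = NA_real_,
               significant = NA,
               overlap_genes = paste(r$overlap, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < alpha
  out <- out[order(out$q_value, out$p_value, out$set, method = "radix"), ]
  rownames(out) <- NULL
  out
}
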