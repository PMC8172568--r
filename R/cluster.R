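#' PCA embedding of cells over high-variance genes
#'
#' Restricts the normalized matrix to the high-variance genes, centers and
#' scales each gene to unit variance (standardized values clipped at
#' `+/- 10`), and computes an exact singular value decomposition of the
#' cells x genes matrix, equivalent to an eigendecomposition of the gene
#' covariance. Sign convention: within each component the largest-magnitude
#' gene loading is positive.
#'
#' @param norm Genes x cells normalized matrix.
#' @param hvg_list Character vector of gene IDs to embed over.
#' @param n_pcs Number of components (default 30).
#' @return List of class `embedding` with `coords` (cells x n_pcs),
#'   `loadings` (genes x n_pcs) and `explained_variance` (one eigenvalue per
#'   component, decreasing).
#' @export
pca_embed <- function(norm, hvg_list, n_pcs = 30) {
  hvg_list <- intersect(hvg_list, rownames(norm))
  if (length(hvg_list) < 2) stop("need at least 2 HVGs present in matrix")
  x <- t(as.matrix(norm[hvg_list, , drop = FALSE]))  # cells x genes
  n_cells <- nrow(x)
  if (n_pcs > min(length(hvg_list), n_cells) - 1) {
    stop("n_pcs exceeds min(n_hvg, n_cells) - 1")
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (all(sdv == 0)) stop("degenerate input: all genes constant")
  sdv[sdv == 0] <- 1
  x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  x[x > 10] <- 10
  x[x < -10] <- -10
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  eig <- sv$d^2 / (n_cells - 1)
  coords <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  loadings <- sv$v
  for (j in seq_len(n_pcs)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- colnames(norm)
  colnames(coords) <- paste0("PC", seq_len(n_pcs))
  rownames(loadings) <- hvg_list
  colnames(loadings) <- colnames(coords)
  structure(list(coords = coords, loadings = loadings,
                 explained_variance = eig[seq_len(n_pcs)]),
            class = "embedding")
}

#' Shared-nearest-neighbor graph with Jaccard weights
#'
#' Finds the `k` nearest neighbors of each cell by Euclidean distance in PC
#' space (a cell is its own first neighbor, the usual convention), weights
#' each cell pair by the Jaccard overlap of their neighbor sets, and prunes
#' weights below `prune` to zero.
#'
#' @param embedding An `embedding` object or a cells x dims matrix.
#' @param k Neighborhood size (default 20).
#' @param prune Jaccard pruning cutoff (default 1/15).
#' @return An undirected weighted `igraph` graph over the cells.
#' @export
build_snn <- function(embedding, k = 20, prune = 1 / 15) {
  coords <- if (inherits(embedding, "embedding")) embedding$coords
            else as.matrix(embedding)
  n <- nrow(coords)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(coords))
  # neighbor incidence (self included); ties resolved by cell order
  nn <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn[i, order(d[i, ])[seq_len(k)]] <- 1
  }
  nn <- methods::as(nn, "CsparseMatrix")
  shared <- Matrix::tcrossprod(nn)            # |A intersect B|
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)            # |A n B| / |A u B|
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- rownames(coords)
  g
}

#' Modularity clustering of the SNN graph
#'
#' Multi-level (Louvain) greedy modularity optimization with a
#' resolution-scaled null model; deterministic given the seed.
#'
#' @param graph Weighted undirected `igraph` graph.
#' @param resolution Resolution parameter (default 1.4).
#' @param seed Integer seed fixing the node sweep order.
#' @return Object of class `cluster_labels`: integer vector of 0-based
#'   cluster IDs named by cell, ordered so that cluster 0 is the largest;
#'   attributes `resolution` and `modularity`.
#' @export
cluster_modularity <- function(graph, resolution = 1.4, seed = 1) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  if (igraph::ecount(graph) == 0) {
    warning("graph has no edges: every cell is its own cluster")
    memb <- seq_len(igraph::vcount(graph))
    mod <- NA_real_
  } else {
    cl <- with_seed(seed, igraph::cluster_louvain(
      graph, weights = igraph::E(graph)$weight, resolution = resolution))
    memb <- igraph::membership(cl)
    mod <- igraph::modularity(graph, memb,
                              weights = igraph::E(graph)$weight,
                              resolution = resolution)
  }
  # relabel contiguously from 0, largest cluster first, ties by old ID
  tab <- table(memb)
  new_ids <- stats::setNames(seq_along(tab) - 1L,
                             names(sort(-tab)))
  labels <- unname(new_ids[as.character(memb)])
  names(labels) <- igraph::V(graph)$name
  structure(labels, class = "cluster_labels",
            resolution = resolution, modularity = mod)
}

#' Marker-based cluster cell-type assignment with ambiguity exclusion
#'
#' Z-scores each marker gene across all cells, averages within marker sets
#' per cell and then per cluster, assigns each cluster the argmax set when
#' its score exceeds `z_threshold`, and flags the cluster "high" for every
#' set exceeding the threshold. Clusters high for two or more sets (e.g.
#' endothelial/pericyte doublet contamination) are excluded, as are
#' clusters with no marker signal.
#'
#' @param norm Genes x cells normalized matrix.
#' @param labels `cluster_labels` (0-based per-cell cluster IDs).
#' @param marker_sets Named list of marker gene vectors (non-overlapping).
#' @param z_threshold Score cutoff for "high expression" (default 0.5).
#' @return data.frame with one row per cluster: `cluster`, `assigned_type`
#'   (NA if excluded), `excluded`, `reason`, and one score column per set.
#' @export
assign_cell_types <- function(norm, labels, marker_sets, z_threshold = 0.5) {
  all_markers <- unlist(marker_sets, use.names = FALSE)
  if (anyDuplicated(all_markers)) stop("marker sets must be non-overlapping")
  scores_by_set <- lapply(names(marker_sets), function(nm) {
    genes <- marker_sets[[nm]]
    present <- intersect(genes, rownames(norm))
    if (length(present) == 0) {
      stop("all markers of set '", nm, "' absent from matrix")
    }
    if (length(present) < length(genes)) {
      warning(length(genes) - length(present), " marker(s) of set '", nm,
              "' absent from matrix; dropped")
    }
    x <- as.matrix(norm[present, , drop = FALSE])
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    sdv[sdv == 0] <- 1
    z <- (x - mu) / sdv
    colMeans(z)                         # per-cell mean marker z-score
  })
  names(scores_by_set) <- names(marker_sets)
  clusters <- sort(unique(as.integer(labels)))
  score_mat <- vapply(scores_by_set, function(s) {
    vapply(clusters, function(cl) mean(s[labels == cl]), 0)
  }, numeric(length(clusters)))
  score_mat <- matrix(score_mat, nrow = length(clusters),
                      dimnames = list(clusters, names(marker_sets)))
  res <- data.frame(cluster = clusters, assigned_type = NA_character_,
                    excluded = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(clusters)) {
    high <- which(score_mat[i, ] > z_threshold)
    if (length(high) == 0) {
      res$excluded[i] <- TRUE
      res$reason[i] <- "no marker signal"
    } else if (length(high) >= 2) {
      res$excluded[i] <- TRUE
      res$reason[i] <- paste0("high for multiple marker sets: ",
                              paste(names(marker_sets)[high],
                                    collapse = ", "))
    } else {
      res$assigned_type[i] <- names(marker_sets)[
        which.max(score_mat[i, ])]
    }
  }
  cbind(res, as.data.frame(score_mat, row.names = NULL))
}
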