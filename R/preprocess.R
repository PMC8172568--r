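#' Per-cell quality-control statistics
#'
#' @param counts Genes x cells count matrix (sparse, with gene rownames).
#' @param mito_prefix Case-insensitive gene-ID prefix identifying
#'   mitochondrial genes (default `"mt-"`, the mouse convention).
#' @return data.frame with one row per cell: `barcode`, `total_umi`,
#'   `n_genes` (detected genes), `mito_fraction`, and `zero_total` flagging
#'   empty cells for unconditional removal.
#' @export
compute_cell_qc <- function(counts, mito_prefix = "mt-") {
  counts <- as_count_matrix(counts)
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  total <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- startsWith(tolower(rownames(counts)), tolower(mito_prefix))
  mito_total <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  frac <- ifelse(total > 0, mito_total / total, NA_real_)
  data.frame(barcode = colnames(counts), total_umi = total,
             n_genes = n_genes, mito_fraction = frac,
             zero_total = total == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quality-control thresholds for cell filtering
#'
#' @param low_pct,high_pct Percentile bounds on total UMI and detected genes
#'   (defaults 5 and 95): cells strictly below the low or strictly above
#'   the high percentile on either statistic are removed.
#' @param mito_max Maximum mitochondrial fraction (default 0.20).
#' @param min_cells_per_gene Minimum number of detecting cells for a gene to
#'   be retained (default 5).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(low_pct = 5, high_pct = 95, mito_max = 0.20,
                          min_cells_per_gene = 5) {
  stopifnot(low_pct >= 0, low_pct < high_pct, high_pct <= 100,
            mito_max > 0, mito_max <= 1, min_cells_per_gene >= 1)
  structure(list(low_pct = low_pct, high_pct = high_pct,
                 mito_max = mito_max,
                 min_cells_per_gene = as.integer(min_cells_per_gene)),
            class = "qc_thresholds")
}

#' Cell filter by joint UMI/gene-count percentiles and mitochondrial cutoff
#'
#' Percentiles are computed over all cells jointly with the linear
#' interpolation convention (quantile type 7). A cell is removed iff its
#' total UMI or detected-gene count is strictly below the low percentile or
#' strictly above the high percentile, or its mitochondrial fraction exceeds
#' `mito_max`. All-zero cells are always removed.
#'
#' @param qc_stats Output of [compute_cell_qc()].
#' @param thresholds A [qc_thresholds()] object.
#' @return Logical vector: TRUE for retained cells.
#' @export
filter_cells <- function(qc_stats, thresholds = qc_thresholds()) {
  if (nrow(qc_stats) < 2) stop("need at least 2 cells to compute percentiles")
  probs <- c(thresholds$low_pct, thresholds$high_pct) / 100
  q_umi <- stats::quantile(qc_stats$total_umi, probs, type = 7, names = FALSE)
  q_gene <- stats::quantile(qc_stats$n_genes, probs, type = 7, names = FALSE)
  out <- qc_stats$total_umi < q_umi[1] | qc_stats$total_umi > q_umi[2] |
    qc_stats$n_genes < q_gene[1] | qc_stats$n_genes > q_gene[2]
  out <- out | (!is.na(qc_stats$mito_fraction) &
                  qc_stats$mito_fraction > thresholds$mito_max)
  out <- out | qc_stats$zero_total
  !out
}

#' Gene filter by minimum number of detecting cells
#'
#' A gene is retained iff it has a nonzero count in at least `min_cells`
#' cells ("fewer than" is strict: detection in exactly `min_cells` cells
#' retains the gene).
#'
#' @param counts Genes x cells count matrix.
#' @param min_cells Minimum number of detecting cells (default 5).
#' @return Logical vector: TRUE for retained genes.
#' @export
filter_genes <- function(counts, min_cells = 5) {
  stopifnot(min_cells >= 1)
  Matrix::rowSums(counts > 0) >= min_cells
}

#' Log counts-per-10k normalization
#'
#' `value = ln(1 + count * scale_factor / cell_total)`. Zero-total cells
#' must be filtered out first.
#'
#' @param counts Genes x cells count matrix.
#' @param scale_factor Library-size target (default 1e4).
#' @return A sparse genes x cells matrix of class `dgCMatrix` with
#'   attributes `method = "log_cp10k"` and `scale_factor`.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  counts <- as_count_matrix(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("zero-total cell(s): filter cells first")
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  norm@x <- log1p(norm@x)
  norm <- methods::as(norm, "CsparseMatrix")
  dimnames(norm) <- dimnames(counts)
  attr(norm, "method") <- "log_cp10k"
  attr(norm, "scale_factor") <- scale_factor
  norm
}

#' Pearson-residual normalization under a negative binomial model
#'
#' Per gene, fits an NB regression of counts on log10(cell total) (Poisson
#' working model for the mean), pools the dispersion across genes of similar
#' mean by bin-median smoothing, and returns residuals
#' `(y - mu) / sqrt(mu + mu^2/theta)` clipped to `+/- sqrt(n_cells)`.
#' Genes detected in fewer than 10 cells fall back to the pooled (global
#' median) dispersion.
#'
#' @param counts Genes x cells count matrix (filtered).
#' @param n_bins Number of gene-mean bins for dispersion pooling.
#' @return Dense genes x cells matrix of residuals, attribute
#'   `method = "pearson_residual"`.
#' @export
pearson_residual_normalize <- function(counts, n_bins = 20) {
  counts <- as_count_matrix(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("zero-total cell(s): filter cells first")
  x <- as.matrix(counts)
  n_cells <- ncol(x)
  lt <- log10(totals)
  design <- cbind(1, lt - mean(lt))

  mu <- matrix(0, nrow(x), n_cells, dimnames = dimnames(x))
  theta_raw <- rep(NA_real_, nrow(x))
  n_det <- Matrix::rowSums(counts > 0)
  for (g in seq_len(nrow(x))) {
    y <- x[g, ]
    fit <- suppressWarnings(
      stats::glm.fit(design, y, family = stats::poisson()))
    mu_g <- fit$fitted.values
    mu[g, ] <- mu_g
    # method-of-moments dispersion from Pearson-type excess variance
    excess <- sum((y - mu_g)^2 - mu_g)
    denom <- sum(mu_g^2)
    if (denom > 0 && excess > 0) theta_raw[g] <- denom / excess
  }
  gmean <- rowMeans(x)
  bins <- cut(rank(gmean, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  global_med <- stats::median(theta_raw, na.rm = TRUE)
  if (!is.finite(global_med)) global_med <- 100
  theta <- vapply(seq_len(nrow(x)), function(g) {
    if (n_det[g] < 10) return(global_med)
    tb <- stats::median(theta_raw[bins == bins[g]], na.rm = TRUE)
    if (is.finite(tb)) tb else global_med
  }, 0)

  res <- (x - mu) / sqrt(mu + mu^2 / theta)
  res[!is.finite(res)] <- 0
  clip <- sqrt(n_cells)
  res[res > clip] <- clip
  res[res < -clip] <- -clip
  attr(res, "method") <- "pearson_residual"
  res
}

#' Variance-stabilized high-variance gene selection
#'
#' Fits a loess trend (span 0.3) of log10 variance on log10 mean over genes
#' with positive variance, standardizes each gene's counts by the
#' trend-predicted standard deviation with values clipped at
#' `sqrt(n_cells)`, and scores genes by the variance of the clipped
#' standardized counts. Returns the top `n_hvg` gene IDs; ties are broken by
#' gene ID.
#'
#' @param counts Genes x cells count matrix (filtered).
#' @param n_hvg Number of genes to select (default 3000).
#' @param loess_span Span of the mean-variance trend fit.
#' @return Character vector of selected gene IDs, with the full score table
#'   in attribute `"scores"` (gene, mean, variance, standardized_variance).
#' @export
select_hvg <- function(counts, n_hvg = 3000, loess_span = 0.3) {
  counts <- as_count_matrix(counts)
  n_cells <- ncol(counts)
  gmean <- Matrix::rowSums(counts) / n_cells
  gsq <- Matrix::rowSums(counts^2)
  gvar <- (gsq - n_cells * gmean^2) / (n_cells - 1)

  std_var <- rep(0, nrow(counts))
  pos <- gvar > 0 & gmean > 0
  if (any(pos)) {
    # trend of log-variance on log-mean; with too few variable genes to
    # support a local fit, each gene is standardized by its own variance
    sd_pred <- if (sum(pos) >= 10) {
      fit <- stats::loess(log10(gvar[pos]) ~ log10(gmean[pos]),
                          span = loess_span, degree = 2,
                          family = "gaussian")
      sqrt(10^fit$fitted)
    } else {
      sqrt(gvar[pos])
    }
    clip <- sqrt(n_cells)
    idx <- which(pos)
    dense <- as.matrix(counts[idx, , drop = FALSE])
    for (ii in seq_along(idx)) {
      g <- idx[ii]
      z <- (dense[ii, ] - gmean[g]) / sd_pred[ii]
      z[z > clip] <- clip
      z[z < -clip] <- -clip
      std_var[g] <- sum((z - mean(z))^2) / (n_cells - 1)
    }
  }
  ids <- rownames(counts)
  ord <- order(-std_var, ids)
  if (n_hvg > nrow(counts)) {
    warning("fewer genes (", nrow(counts), ") than n_hvg = ", n_hvg,
            "; returning all")
    n_hvg <- nrow(counts)
  }
  sel <- ids[ord][seq_len(n_hvg)]
  attr(sel, "scores") <- data.frame(
    gene = ids, mean = gmean, variance = gvar,
    standardized_variance = std_var,
    row.names = NULL, stringsAsFactors = FALSE)
  sel
}
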