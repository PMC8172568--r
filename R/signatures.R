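#' Gene-signature module score with expression-binned control genes
#'
#' The binned-control scheme: every gene's mean normalized expression over
#' all cells is computed, genes are partitioned into `nbins` equal-size bins
#' by that average (ties broken by gene ID), and for each signature gene
#' `nctrl` control genes are drawn uniformly without replacement from its
#' bin (with replacement when the bin is smaller than `nctrl`; signature
#' genes are excluded from the control pool so the score responds linearly
#' to shifts of the signature). The score of a cell is the mean expression
#' of the signature genes minus the mean expression of the pooled
#' (deduplicated) control draw.
#'
#' @param norm Genes x cells normalized matrix.
#' @param signature Character vector of signature gene IDs.
#' @param nbins Number of expression bins (default 24).
#' @param nctrl Control genes drawn per signature gene (default 100).
#' @param seed Seed for the control draw.
#' @return Numeric per-cell score vector named by barcode, with attributes
#'   `signature_genes` (those present), `control_genes`, `nbins`, `nctrl`,
#'   `seed`.
#' @export
module_score <- function(norm, signature, nbins = 24, nctrl = 100,
                         seed = 1) {
  stopifnot(nbins >= 2)
  present <- intersect(signature, rownames(norm))
  if (length(present) == 0) stop("no signature gene present in matrix")
  if (length(present) < length(signature)) {
    warning(length(signature) - length(present),
            " signature gene(s) missing from matrix; dropped")
  }
  gmean <- Matrix::rowSums(norm) / ncol(norm)
  ids <- rownames(norm)
  ord <- order(gmean, ids)
  bin_of <- integer(length(ids))
  # equal-size bins over the expression-sorted gene order
  bin_sizes <- rep(length(ids) %/% nbins, nbins) +
    c(rep(1L, length(ids) %% nbins), rep(0L, nbins - length(ids) %% nbins))
  bin_of[ord] <- rep(seq_len(nbins), times = bin_sizes)

  controls <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      bin_genes <- ids[bin_of == bin_of[ids == g]]
      # signature genes are not their own controls
      pool <- setdiff(bin_genes, present)
      if (length(pool) == 0) pool <- bin_genes
      if (length(pool) >= nctrl) {
        sample(pool, nctrl)
      } else {
        sample(pool, nctrl, replace = TRUE)
      }
    }))
  })
  controls <- unique(controls)
  sig_mean <- Matrix::colSums(norm[present, , drop = FALSE]) /
    length(present)
  ctrl_mean <- Matrix::colSums(norm[controls, , drop = FALSE]) /
    length(controls)
  score <- sig_mean - ctrl_mean
  names(score) <- colnames(norm)
  attr(score, "signature_genes") <- present
  attr(score, "control_genes") <- controls
  attr(score, "nbins") <- nbins
  attr(score, "nctrl") <- nctrl
  attr(score, "seed") <- seed
  score
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `k - 1` degrees of freedom. When every observation is tied, H is defined
#' as 0 with p = 1.
#'
#' @param scores Numeric vector.
#' @param groups Group labels (coerced to factor).
#' @return List with `H`, `df`, `p_value`, `group_medians`, `n`.
#' @export
kruskal_wallis <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  med <- tapply(scores, groups, stats::median)
  if (length(unique(scores)) == 1) {
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1,
                group_medians = med, n = length(scores)))
  }
  kt <- stats::kruskal.test(scores, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, group_medians = med, n = length(scores))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Rank-based z statistics
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sumT/(12(N-1))) *
#' (1/n_i + 1/n_j))` with tie correction `sumT = sum(t^3 - t)` over tie
#' groups, and two-sided normal p-values. Unadjusted by default; Holm
#' adjustment optional.
#'
#' @param scores Numeric vector.
#' @param groups Group labels.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with one row per unordered pair: `group_i`,
#'   `group_j`, `mean_rank_diff`, `z`, `p_value`.
#' @export
dunn_posthoc <- function(scores, groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  N <- length(scores)
  r <- rank(scores)
  rbar <- tapply(r, groups, mean)
  ns <- table(groups)
  ties <- table(scores)
  sum_t <- sum(ties^3 - ties)
  v <- N * (N + 1) / 12 - sum_t / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    gi <- pairs[1, j]; gj <- pairs[2, j]
    diff <- rbar[[gi]] - rbar[[gj]]
    se <- sqrt(v * (1 / ns[[gi]] + 1 / ns[[gj]]))
    z <- if (se > 0) diff / se else 0
    data.frame(group_i = gi, group_j = gj, mean_rank_diff = diff,
               z = z, p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (adjust == "holm") {
    out$p_value <- stats::p.adjust(out$p_value, method = "holm")
  }
  rownames(out) <- NULL
  out
}

#' Score a signature and compare groups
#'
#' Convenience wrapper: module score over the cells of one cell type,
#' Kruskal-Wallis omnibus test across groups, and Dunn's post hoc pairwise
#' comparisons.
#'
#' @param norm Genes x cells normalized matrix.
#' @param metadata Cell metadata with `barcode`, `group`, `cell_type`.
#' @param signature Signature gene IDs.
#' @param cell_type Cell type whose cells are scored (NA = all cells).
#' @inheritParams module_score
#' @return List with `scores` (data.frame barcode, group, score),
#'   `kruskal` and `dunn`.
#' @export
score_and_compare <- function(norm, metadata, signature, cell_type = NA,
                              nbins = 24, nctrl = 100, seed = 1) {
  idx <- match(colnames(norm), metadata$barcode)
  if (anyNA(idx)) stop("metadata does not cover all matrix columns")
  meta <- metadata[idx, ]
  keep <- if (is.na(cell_type)) rep(TRUE, ncol(norm))
          else meta$cell_type == cell_type
  if (!any(keep)) stop("no cells of type ", cell_type)
  sub <- norm[, keep, drop = FALSE]
  sc <- module_score(sub, signature, nbins = nbins, nctrl = nctrl,
                     seed = seed)
  grp <- droplevels(factor(meta$group[keep]))
  list(scores = data.frame(barcode = colnames(sub),
                           group = as.character(grp), score = as.numeric(sc),
                           row.names = NULL, stringsAsFactors = FALSE),
       kruskal = kruskal_wallis(as.numeric(sc), grp),
       dunn = dunn_posthoc(as.numeric(sc), grp))
}
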