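#' Union of significant genes across two contrasts
#'
#' Genes with FDR-adjusted q below `alpha` in either the aging or the
#' treatment DEG table. Genes significant in one table but untested in the
#' other (no lnFC available) are excluded with a warning rather than
#' imputed, since an imputed zero would fabricate a direction.
#'
#' @param deg_age,deg_treat DEG tables from [run_de_contrast()].
#' @param alpha Significance threshold on q (default 0.05).
#' @return Character vector of gene IDs (sorted).
#' @export
union_significant <- function(deg_age, deg_treat, alpha = 0.05) {
  sig_a <- deg_age$gene[!is.na(deg_age$q_value) & deg_age$q_value < alpha]
  sig_t <- deg_treat$gene[!is.na(deg_treat$q_value) &
                            deg_treat$q_value < alpha]
  u <- union(sig_a, sig_t)
  tested_both <- intersect(deg_age$gene, deg_treat$gene)
  dropped <- setdiff(u, tested_both)
  if (length(dropped)) {
    warning(length(dropped),
            " significant gene(s) untested in the other contrast; excluded")
    u <- intersect(u, tested_both)
  }
  if (length(u) == 0) stop("empty union of significant genes")
  sort(u)
}

#' Reversal statistics over a gene list
#'
#' For each gene, the reversed flag is `sign(lnFC_age) * sign(lnFC_treat)
#' < 0` (an exactly-zero lnFC carries no direction and counts as not
#' reversed). Summaries: the proportion reversed, and the unweighted OLS
#' regression of treatment lnFC (y) on aging lnFC (x) with intercept, with
#' r-squared and the two-sided t-test p-value of the slope.
#'
#' @param deg_age,deg_treat DEG tables.
#' @param genes Gene IDs over which to compute (e.g. from
#'   [union_significant()]).
#' @return Object of class `reversal_result`: list with `n_union`,
#'   `prop_reversed`, `slope`, `intercept`, `r2`, `p_slope` and the
#'   gene-level data.frame `gene_table`.
#' @export
reversal_statistics <- function(deg_age, deg_treat, genes) {
  ia <- match(genes, deg_age$gene)
  it <- match(genes, deg_treat$gene)
  if (anyNA(ia) || anyNA(it)) {
    stop("lnFC not available in both tables for every gene")
  }
  x <- deg_age$lnFC[ia]
  y <- deg_treat$lnFC[it]
  reversed <- sign(x) * sign(y) < 0
  n <- length(genes)
  prop <- mean(reversed)
  slope <- intercept <- r2 <- p_slope <- NA_real_
  if (n >= 3 && stats::var(x) > 0) {
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
    fitted <- intercept + slope * x
    rss <- sum((y - fitted)^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
    if (n > 2) {
      se <- sqrt(rss / (n - 2) / sxx)
      p_slope <- if (se > 0) {
        2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
      } else 0
    }
  }
  structure(list(n_union = n, prop_reversed = prop, slope = slope,
                 intercept = intercept, r2 = r2, p_slope = p_slope,
                 gene_table = data.frame(gene = genes, lnFC_age = x,
                                         lnFC_treat = y, reversed = reversed,
                                         row.names = NULL,
                                         stringsAsFactors = FALSE)),
            class = "reversal_result")
}

#' @export
print.reversal_result <- function(x, ...) {
  cat("Reversal of aging signature by treatment\n")
  cat(sprintf("  union of significant genes: %d\n", x$n_union))
  cat(sprintf("  proportion reversed:        %.3f\n", x$prop_reversed))
  cat(sprintf("  slope (treat ~ age lnFC):   %.4f (r2 = %.3f, p = %.3g)\n",
              x$slope, x$r2, x$p_slope))
  invisible(x)
}

#' Top reversed genes by fold-change rank in both contrasts
#'
#' Ranks significant genes of each contrast by `|lnFC|` descending (ties by
#' gene ID) and keeps genes ranked within `rank_limit` in both tables with
#' opposite lnFC signs.
#'
#' @param deg_age,deg_treat DEG tables.
#' @param rank_limit Rank cutoff (default 500).
#' @param alpha Significance threshold defining the ranking universe
#'   (default 0.05); set to `NULL` to rank over all tested genes.
#' @return Character vector of gene IDs (sorted).
#' @export
select_top_reversed <- function(deg_age, deg_treat, rank_limit = 500,
                                alpha = 0.05) {
  universe <- function(tab) {
    if (is.null(alpha)) {
      tab[!is.na(tab$p_value), ]
    } else {
      tab[!is.na(tab$q_value) & tab$q_value < alpha, ]
    }
  }
  ua <- universe(deg_age)
  ut <- universe(deg_treat)
  if (nrow(ua) == 0 || nrow(ut) == 0) return(character())
  ra <- rank_abs_desc(ua$lnFC, ua$gene)
  rt <- rank_abs_desc(ut$lnFC, ut$gene)
  top_a <- ua[ra <= rank_limit, c("gene", "lnFC")]
  top_t <- ut[rt <= rank_limit, c("gene", "lnFC")]
  common <- intersect(top_a$gene, top_t$gene)
  if (length(common) == 0) return(character())
  fa <- top_a$lnFC[match(common, top_a$gene)]
  ft <- top_t$lnFC[match(common, top_t$gene)]
  sort(common[sign(fa) * sign(ft) < 0])
}

#' Pairwise consistency of differential expression across subtypes
#'
#' For each unordered pair of subtypes, takes the union of their
#' significant genes in the given contrast and regresses one subtype's lnFC
#' on the other's (both directed slopes are kept; r2 and p are symmetric).
#'
#' @param deg_tables Named list of DEG tables, one per subtype.
#' @param alpha Significance threshold (default 0.05).
#' @return data.frame with one row per unordered pair: `subtype_1`,
#'   `subtype_2`, `n_union`, `slope_12` (lnFC of 1 regressed on 2),
#'   `slope_21`, `r2`, `p`.
#' @export
pairwise_consistency <- function(deg_tables, alpha = 0.05) {
  if (length(deg_tables) < 2) stop("need at least 2 subtypes")
  nms <- names(deg_tables)
  pairs <- utils::combn(nms, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    n1 <- pairs[1, j]; n2 <- pairs[2, j]
    t1 <- deg_tables[[n1]]; t2 <- deg_tables[[n2]]
    out <- data.frame(subtype_1 = n1, subtype_2 = n2, n_union = 0L,
                      slope_12 = NA_real_, slope_21 = NA_real_,
                      r2 = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    u <- tryCatch(suppressWarnings(union_significant(t1, t2, alpha)),
                  error = function(e) character())
    if (length(u) < 3) {
      warning("pair ", n1, "/", n2, ": empty or tiny union; NA entry")
      return(out)
    }
    x1 <- t1$lnFC[match(u, t1$gene)]
    x2 <- t2$lnFC[match(u, t2$gene)]
    r12 <- reversal_statistics(t1[match(u, t1$gene), ],
                               t2[match(u, t2$gene), ], u)
    out$n_union <- length(u)
    # slope_12: lnFC of subtype 1 regressed on subtype 2 and vice versa
    out$slope_21 <- r12$slope       # y = subtype2 on x = subtype1
    out$slope_12 <- if (stats::var(x2) > 0) {
      sum((x2 - mean(x2)) * (x1 - mean(x1))) / sum((x2 - mean(x2))^2)
    } else NA_real_
    out$r2 <- r12$r2
    out$p <- r12$p_slope
    out
  })
  do.call(rbind, rows)
}

#' Replication of top reversed genes in an independent contrast
#'
#' Looks up the top reversed genes in a replicate DEG table (e.g. treated
#' vs vehicle in an independent dataset) and reports, per gene, the
#' replicate lnFC against the original aging lnFC, plus the fraction of
#' genes with opposite signs (an exactly-zero replicate lnFC is not
#' reversed).
#'
#' @param top_reversed_genes Gene IDs from [select_top_reversed()].
#' @param deg_replicate Replicate DEG table.
#' @param deg_age Aging DEG table from the original dataset.
#' @return List with `table` (gene, lnFC_age, lnFC_replicate,
#'   opposite_sign) and `sign_agreement` (fraction opposite).
#' @export
replication_check <- function(top_reversed_genes, deg_replicate, deg_age) {
  common <- intersect(top_reversed_genes, deg_replicate$gene)
  common <- intersect(common, deg_age$gene)
  if (length(common) == 0) {
    stop("replicate table covers none of the top reversed genes")
  }
  fa <- deg_age$lnFC[match(common, deg_age$gene)]
  fr <- deg_replicate$lnFC[match(common, deg_replicate$gene)]
  opp <- sign(fa) * sign(fr) < 0
  list(table = data.frame(gene = common, lnFC_age = fa,
                          lnFC_replicate = fr, opposite_sign = opp,
                          row.names = NULL, stringsAsFactors = FALSE),
       sign_agreement = mean(opp))
}
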