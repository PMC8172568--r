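#' Natural-log fold change between two cell groups
#'
#' The Seurat v3 convention on log-normalized values:
#' `lnFC = ln(mean(expm1(y_A)) + 1) - ln(mean(expm1(y_B)) + 1)`, i.e. fold
#' change of back-transformed mean normalized expression with pseudocount 1.
#'
#' @param norm Genes x cells log-normalized (`log_cp10k`) matrix.
#' @param cells_A,cells_B Column indices or barcodes of the two groups
#'   (A relative to B).
#' @return Named numeric vector of per-gene lnFC.
#' @export
compute_lnfc <- function(norm, cells_A, cells_B) {
  a <- norm[, cells_A, drop = FALSE]
  b <- norm[, cells_B, drop = FALSE]
  if (ncol(a) == 0 || ncol(b) == 0) stop("both groups must be non-empty")
  mean_back <- function(m) {
    e <- m
    e@x <- expm1(e@x)
    Matrix::rowSums(e) / ncol(m)
  }
  if (!methods::is(a, "sparseMatrix")) {
    a <- methods::as(a, "CsparseMatrix")
    b <- methods::as(b, "CsparseMatrix")
  }
  log(mean_back(a) + 1) - log(mean_back(b) + 1)
}

# Binomial log-likelihood at the MLE for a saturated-by-group fit,
# with the 0*log(0) = 0 convention.
binom_ll <- function(d, n) {
  p <- d / n
  t1 <- ifelse(d > 0, d * log(p), 0)
  t2 <- ifelse(n - d > 0, (n - d) * log(1 - p), 0)
  t1 + t2
}

# Gaussian ML log-likelihood given residual sum of squares over n points.
gauss_ll <- function(rss, n) {
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

#' Fit the two-part hurdle model for one gene
#'
#' Detection part: logistic regression of `1{y > 0}` on the design by
#' maximum likelihood (a ridge penalty of 1e-8 is applied when complete
#' separation is detected). Continuous part: ordinary least squares of `y`
#' on the design over detected cells with Gaussian ML variance. The total
#' log-likelihood is the sum of the parts.
#'
#' @param y Per-cell normalized expression values.
#' @param design Covariate matrix (including intercept).
#' @return List with `disc_coef`, `cont_coef`, `sigma2`, `loglik`,
#'   `loglik_disc`, `loglik_cont`, and flags `cont_testable`,
#'   `disc_saturated`, `separation`.
#' @export
fit_hurdle <- function(y, design) {
  design <- as.matrix(design)
  n <- length(y)
  z <- as.numeric(y > 0)
  n_det <- sum(z)

  # --- detection part ---
  disc_saturated <- n_det == 0 || n_det == n
  separation <- FALSE
  if (disc_saturated) {
    # likelihood supremum is 0 (all probabilities at the boundary)
    disc_coef <- rep(NA_real_, ncol(design))
    ll_disc <- 0
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(design, z, family = stats::binomial()))
    p_hat <- fit$fitted.values
    eps <- 1e-10
    if (!fit$converged || any(p_hat < eps | p_hat > 1 - eps)) {
      separation <- TRUE
      ridge <- logistic_ridge(design, z, lambda = 1e-8)
      disc_coef <- ridge$coef
      p_hat <- ridge$p
    } else {
      disc_coef <- fit$coefficients
    }
    ph <- pmin(pmax(p_hat, 1e-300), 1 - 1e-16)
    ll_disc <- sum(z * log(ph) + (1 - z) * log(1 - ph))
  }

  # --- continuous part (detected cells only) ---
  cont_testable <- FALSE
  cont_coef <- rep(NA_real_, ncol(design))
  sigma2 <- NA_real_
  ll_cont <- 0
  if (n_det >= 3) {
    xd <- design[z > 0, , drop = FALSE]
    yd <- y[z > 0]
    if (qr(xd)$rank == ncol(xd)) {
      fit <- stats::lm.fit(xd, yd)
      rss <- sum(fit$residuals^2)
      if (rss > 0) {
        cont_testable <- TRUE
        cont_coef <- fit$coefficients
        sigma2 <- rss / n_det
        ll_cont <- gauss_ll(rss, n_det)
      }
    }
  }
  list(disc_coef = disc_coef, cont_coef = cont_coef, sigma2 = sigma2,
       loglik = ll_disc + ll_cont, loglik_disc = ll_disc,
       loglik_cont = ll_cont, cont_testable = cont_testable,
       disc_saturated = disc_saturated, separation = separation)
}

# Ridge-penalized logistic regression by IRLS; used under separation.
logistic_ridge <- function(x, z, lambda = 1e-8, max_iter = 100) {
  beta <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-12)
    grad <- drop(crossprod(x, z - p)) - lambda * beta
    hess <- crossprod(x * w, x) + diag(lambda, ncol(x))
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- drop(x %*% beta)
  list(coef = beta, p = 1 / (1 + exp(-eta)))
}

#' Hurdle likelihood-ratio test for a group effect
#'
#' Compares the full model (group + covariates) with the reduced model
#' (covariates only):
#' `chi2 = 2 * (ll_full - ll_reduced)` summed over the two parts; `df` is
#' the number of dropped coefficients across testable parts (2 when the
#' group term is testable in both parts, 1 when one part is untestable);
#' the p-value is the chi-square upper tail.
#'
#' @param y Per-cell values.
#' @param group_indicator 0/1 vector (1 = group A).
#' @param covariates Optional matrix of nuisance covariates.
#' @return List with `chi2`, `df`, `p_value` and the two fitted models.
#' @export
hurdle_lrt <- function(y, group_indicator, covariates = NULL) {
  group_indicator <- as.numeric(group_indicator)
  if (length(unique(group_indicator)) != 2) {
    stop("both groups must have at least one cell")
  }
  base <- cbind(intercept = rep(1, length(y)), covariates)
  full <- cbind(base, group = group_indicator)
  f_full <- fit_hurdle(y, full)
  f_red <- fit_hurdle(y, base)

  z <- y > 0
  det_testable <- any(z) && !all(z)
  cont_testable <- f_full$cont_testable && f_red$cont_testable
  df <- as.integer(det_testable) + as.integer(cont_testable)
  if (df == 0) {
    return(list(chi2 = NA_real_, df = 0L, p_value = NA_real_,
                full = f_full, reduced = f_red))
  }
  chi2 <- 0
  if (det_testable) {
    chi2 <- chi2 + 2 * (f_full$loglik_disc - f_red$loglik_disc)
  }
  if (cont_testable) {
    chi2 <- chi2 + 2 * (f_full$loglik_cont - f_red$loglik_cont)
  }
  chi2 <- max(chi2, 0)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       full = f_full, reduced = f_red)
}

#' Benjamini-Hochberg FDR adjustment with NA passthrough
#'
#' NAs (untestable genes) are passed through unchanged and do not count
#' toward the number of tests.
#'
#' @param p Vector of p-values, possibly with NAs.
#' @return Vector of q-values of the same length.
#' @export
bh_adjust <- function(p) {
  q <- p
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Contrast specification for differential expression
#'
#' @param cell_type Cell-type label to test within.
#' @param group_A,group_B Group labels (A relative to the reference B).
#' @param use_cdr Include the centered cellular detection rate (fraction of
#'   genes detected per cell) as a nuisance covariate (default FALSE).
#' @param min_detection_fraction Prefilter: a gene must be detected in at
#'   least this fraction of cells in at least one group (default 0.1).
#' @param min_abs_lnfc_prefilter Prefilter on `|lnFC|` (default 0).
#' @return Object of class `contrast_spec`.
#' @export
contrast_spec <- function(cell_type, group_A, group_B, use_cdr = FALSE,
                          min_detection_fraction = 0.1,
                          min_abs_lnfc_prefilter = 0) {
  stopifnot(group_A != group_B,
            min_detection_fraction >= 0, min_detection_fraction <= 1)
  structure(list(cell_type = cell_type, group_A = group_A,
                 group_B = group_B, use_cdr = use_cdr,
                 min_detection_fraction = min_detection_fraction,
                 min_abs_lnfc_prefilter = min_abs_lnfc_prefilter),
            class = "contrast_spec")
}

#' Run a hurdle differential-expression contrast
#'
#' Prefilters genes by detection fraction and optionally by `|lnFC|`, runs
#' the hurdle likelihood-ratio test per gene, and adjusts p-values by
#' Benjamini-Hochberg over the tested genes. When no covariates are
#' requested the group-design likelihoods have closed forms and are
#' computed vectorized over genes.
#'
#' @param norm Genes x cells `log_cp10k` matrix.
#' @param metadata data.frame with `barcode`, `group`, `cell_type` columns
#'   matching the matrix columns.
#' @param spec A [contrast_spec()].
#' @return A `DEG table` data.frame: `gene`, `lnFC`, `p_value`, `q_value`,
#'   `pct_A`, `pct_B`, `chi2`, `df`, sorted by q, then `|lnFC|` descending,
#'   then gene ID. Attribute `"contrast"` records the spec.
#' @export
run_de_contrast <- function(norm, metadata, spec) {
  stopifnot(inherits(spec, "contrast_spec"))
  idx <- match(colnames(norm), metadata$barcode)
  if (anyNA(idx)) stop("metadata does not cover all matrix columns")
  meta <- metadata[idx, ]
  in_type <- if (is.null(meta$cell_type) || is.na(spec$cell_type)) {
    rep(TRUE, ncol(norm))
  } else {
    meta$cell_type == spec$cell_type
  }
  cells_A <- which(in_type & meta$group == spec$group_A)
  cells_B <- which(in_type & meta$group == spec$group_B)
  if (length(cells_A) == 0 || length(cells_B) == 0) {
    stop("empty group in contrast: ", spec$group_A, " vs ", spec$group_B,
         " in ", spec$cell_type)
  }
  a <- norm[, cells_A, drop = FALSE]
  b <- norm[, cells_B, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  dA <- Matrix::rowSums(a > 0)
  dB <- Matrix::rowSums(b > 0)
  pct_A <- dA / nA
  pct_B <- dB / nB
  lnfc <- compute_lnfc(norm, cells_A, cells_B)

  keep <- pmax(pct_A, pct_B) >= spec$min_detection_fraction &
    abs(lnfc) >= spec$min_abs_lnfc_prefilter
  if (!any(keep)) {
    warning("no genes pass the prefilters; empty DEG table")
    empty <- data.frame(gene = character(), lnFC = double(),
                        p_value = double(), q_value = double(),
                        pct_A = double(), pct_B = double(),
                        chi2 = double(), df = integer(),
                        stringsAsFactors = FALSE)
    attr(empty, "contrast") <- spec
    return(empty)
  }
  genes <- rownames(norm)[keep]

  if (!spec$use_cdr) {
    st <- hurdle_lrt_grouped(a[keep, , drop = FALSE],
                             b[keep, , drop = FALSE])
  } else {
    cdr <- Matrix::colSums(norm[, c(cells_A, cells_B), drop = FALSE] > 0) /
      nrow(norm)
    cdr <- cdr - mean(cdr)
    grp <- rep(c(1, 0), c(nA, nB))
    ab <- as.matrix(norm[keep, c(cells_A, cells_B), drop = FALSE])
    st <- list(chi2 = rep(NA_real_, length(genes)),
               df = rep(0L, length(genes)),
               p_value = rep(NA_real_, length(genes)))
    for (g in seq_along(genes)) {
      r <- hurdle_lrt(ab[g, ], grp, covariates = cbind(cdr = cdr))
      st$chi2[g] <- r$chi2; st$df[g] <- r$df; st$p_value[g] <- r$p_value
    }
  }
  res <- data.frame(gene = genes, lnFC = lnfc[keep],
                    p_value = st$p_value, q_value = bh_adjust(st$p_value),
                    pct_A = pct_A[keep], pct_B = pct_B[keep],
                    chi2 = st$chi2, df = st$df,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$q_value, -abs(res$lnFC), res$gene,
                   method = "radix"), ]
  rownames(res) <- NULL
  attr(res, "contrast") <- spec
  res
}

# Closed-form vectorized hurdle LRT for the intercept + group design.
# For a two-level factor both parts saturate at group-wise MLEs:
# detection rates per group, and group means with pooled ML variance.
hurdle_lrt_grouped <- function(a, b) {
  nA <- ncol(a); nB <- ncol(b); n <- nA + nB
  dA <- Matrix::rowSums(a > 0)
  dB <- Matrix::rowSums(b > 0)
  d <- dA + dB
  ll_det_full <- binom_ll(dA, nA) + binom_ll(dB, nB)
  ll_det_red <- binom_ll(d, n)
  det_testable <- d > 0 & d < n
  chi2_det <- 2 * (ll_det_full - ll_det_red)

  sA <- Matrix::rowSums(a); sA2 <- Matrix::rowSums(a^2)
  sB <- Matrix::rowSums(b); sB2 <- Matrix::rowSums(b^2)
  rss_grp <- function(s, s2, k) ifelse(k > 0, s2 - s^2 / k, 0)
  rss_full <- rss_grp(sA, sA2, dA) + rss_grp(sB, sB2, dB)
  rss_full <- pmax(rss_full, 0)
  rss_red <- pmax((sA2 + sB2) - (sA + sB)^2 / pmax(d, 1), 0)
  cont_testable <- d >= 3 & dA >= 1 & dB >= 1 & rss_full > 1e-300
  chi2_cont <- ifelse(cont_testable, d * log(rss_red / rss_full), 0)

  df <- as.integer(det_testable) + as.integer(cont_testable)
  chi2 <- pmax(ifelse(det_testable, chi2_det, 0) +
                 ifelse(cont_testable, chi2_cont, 0), 0)
  p <- ifelse(df > 0, stats::pchisq(chi2, df, lower.tail = FALSE),
              NA_real_)
  chi2[df == 0] <- NA_real_
  list(chi2 = chi2, df = df, p_value = p)
}
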