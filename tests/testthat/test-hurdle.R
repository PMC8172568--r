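test_that("lnFC follows the back-transformed-mean convention", {
  # A: one cell at ln 2 (back-transformed 1), B: one cell at 0
  norm <- make_counts(matrix(0, 1, 2))
  norm[1, 1] <- log(2)
  expect_equal(unname(compute_lnfc(norm, 1, 2)), log(2), tolerance = 1e-12)
  # identical groups: lnFC 0 for every gene
  set.seed(2)
  m <- methods::as(matrix(abs(rnorm(40)), 4, 10,
                          dimnames = list(paste0("g", 1:4),
                                          paste0("c", 1:10))),
                   "CsparseMatrix")
  expect_equal(unname(compute_lnfc(m, 1:5, 1:5)), rep(0, 4))
  # swapping the groups negates lnFC exactly
  f1 <- compute_lnfc(m, 1:5, 6:10)
  f2 <- compute_lnfc(m, 6:10, 1:5)
  expect_equal(f1, -f2, tolerance = 1e-12)
})

test_that("hurdle fit has the intercept-only closed form", {
  y <- c(0, 0, 0, 1.2, 2.0, 3.1)
  fit <- fit_hurdle(y, matrix(1, 6, 1))
  rate <- 3 / 6
  expect_equal(unname(fit$disc_coef[1]), log(rate / (1 - rate)),
               tolerance = 1e-6)
  expect_equal(unname(fit$cont_coef[1]), mean(c(1.2, 2.0, 3.1)),
               tolerance = 1e-10)
  # no zeros: detection part saturated and flagged
  fit2 <- fit_hurdle(c(1, 2, 3, 4), matrix(1, 4, 1))
  expect_true(fit2$disc_saturated)
  expect_equal(fit2$loglik_disc, 0)
  # fewer than 3 detected cells: continuous part undefined
  fit3 <- fit_hurdle(c(0, 0, 0, 0, 1.5, 2.5), matrix(1, 6, 1))
  expect_false(fit3$cont_testable)
})

test_that("hurdle log-likelihood matches brute-force maximization", {
  set.seed(101)
  for (i in 1:10) {
    n <- 40
    grp <- rep(c(0, 1), each = n / 2)
    design <- cbind(1, grp)
    y <- ifelse(runif(n) < 0.6, abs(rnorm(n, 1.5 + 0.5 * grp, 0.7)), 0)
    if (sum(y > 0) < 6 || all(y > 0)) next
    fit <- fit_hurdle(y, design)
    oracle <- brute_force_hurdle_ll(y, design)
    expect_lt(abs(fit$loglik - oracle), 1e-6)
  }
})

test_that("the likelihood-ratio test behaves at its boundaries", {
  # identical data in both groups: chi2 ~ 0, p ~ 1
  y <- rep(c(0, 1.5, 2.5, 0, 3), 2)
  grp <- rep(c(1, 0), each = 5)
  r <- hurdle_lrt(y, grp)
  expect_lt(r$chi2, 1e-8)
  expect_gt(r$p_value, 0.999)
  # chi2 is invariant to relabeling the groups
  set.seed(7)
  y2 <- ifelse(runif(30) < 0.5, abs(rnorm(30, 2)), 0)
  g2 <- rep(c(1, 0), 15)
  r1 <- hurdle_lrt(y2, g2)
  r2 <- hurdle_lrt(y2, 1 - g2)
  expect_equal(r1$chi2, r2$chi2, tolerance = 1e-8)
  expect_gte(r1$chi2, 0)
  # spec'd mixed instance matches the numerical oracle
  y3 <- c(0, 1.0, 2.0, 0, 0, 3.0)
  g3 <- c(1, 1, 1, 0, 0, 0)
  r3 <- hurdle_lrt(y3, g3)
  ll_full <- brute_force_hurdle_ll(y3, cbind(1, g3))
  ll_red <- brute_force_hurdle_ll(y3, cbind(rep(1, 6)))
  expect_equal(r3$chi2, 2 * (ll_full - ll_red), tolerance = 1e-5)
  expect_error(hurdle_lrt(y3, rep(1, 6)), "both groups")
})

test_that("degrees of freedom reflect which parts are testable", {
  # both parts testable: df 2
  y <- c(0, 1, 2, 3, 0, 0, 1, 5)
  g <- rep(c(1, 0), each = 4)
  expect_equal(hurdle_lrt(y, g)$df, 2L)
  # no zeros: only the continuous part contributes
  y2 <- c(1, 2, 3, 4, 2, 3, 4, 5)
  expect_equal(hurdle_lrt(y2, g)$df, 1L)
  # one group never detected: continuous group effect untestable, df 1
  y3 <- c(1, 2, 3, 4, 0, 0, 0, 0)
  expect_equal(hurdle_lrt(y3, g)$df, 1L)
})

test_that("Benjamini-Hochberg adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  # NAs pass through and do not count toward m
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_adjust(c(0.01, 0.04)))
  # direct formula min_{j>=i} m p_(j) / j on a random instance
  set.seed(3)
  p <- runif(50)
  m <- length(p)
  ord <- order(p)
  direct <- numeric(m)
  direct[ord] <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  expect_equal(bh_adjust(p), pmin(direct, 1), tolerance = 1e-12)
  # q is monotone in the p-value rank
  q2 <- bh_adjust(p)
  expect_true(all(diff(q2[order(p)]) >= -1e-12))
})

test_that("the vectorized group path equals the per-gene hurdle fits", {
  cfg <- tiny_config(n_genes = 120, seed = 55)
  sim <- simulate_dataset(cfg)
  keep <- filter_genes(sim$counts, 5)
  norm <- lognormalize(sim$counts[keep, ])
  meta <- sim$metadata
  de <- run_de_contrast(norm, meta, contrast_spec("ct1", "aged", "young"))
  cells_A <- meta$barcode[meta$group == "aged"]
  cells_B <- meta$barcode[meta$group == "young"]
  grp <- rep(c(1, 0), c(length(cells_A), length(cells_B)))
  sub <- as.matrix(norm[, c(cells_A, cells_B)])
  for (g in sample(de$gene, 15)) {
    r <- hurdle_lrt(sub[g, ], grp)
    row <- de[de$gene == g, ]
    if (row$df > 0) {
      expect_equal(row$chi2, r$chi2, tolerance = 1e-6)
      expect_equal(row$df, r$df)
      expect_equal(row$p_value, r$p_value, tolerance = 1e-6)
    }
  }
})

test_that("planted effects are recovered with the right sign", {
  cfg <- tiny_config(n_genes = 1000, cells_per_sample_per_type = 40,
                     f_de = 0.1, seed = 66)
  sim <- simulate_dataset(cfg)
  keep <- filter_genes(sim$counts, 5)
  norm <- lognormalize(sim$counts[keep, ])
  de <- run_de_contrast(norm, sim$metadata,
                        contrast_spec("ct1", "aged", "young"))
  truthtab <- planted_effect_table(sim$truth, "ct1")
  delta <- truthtab$delta[match(de$gene, truthtab$gene)]
  sig <- !is.na(de$q_value) & de$q_value < 0.05 & delta != 0
  expect_gte(mean(sign(de$lnFC[sig]) == sign(delta[sig])), 0.95)
  # estimated lnFC correlates strongly with the planted effects
  tested <- !is.na(de$p_value) & delta != 0
  expect_gte(stats::cor(de$lnFC[tested], delta[tested]), 0.8)
})

test_that("degenerate prefilters give an empty table with a warning", {
  # sparse toy data: no gene is detected in every cell of either group
  m <- make_counts(rbind(c(1, 0, 0, 2, 3, 0), c(0, 3, 2, 0, 1, 4),
                         c(2, 1, 0, 2, 0, 0)))
  meta <- data.frame(barcode = colnames(m), sample = "s1",
                     group = rep(c("aged", "young"), 3),
                     cell_type = "ct1", stringsAsFactors = FALSE)
  norm <- lognormalize(m)
  expect_warning(
    de <- run_de_contrast(norm, meta,
                          contrast_spec("ct1", "aged", "young",
                                        min_detection_fraction = 1.0)),
    "no genes pass")
  expect_equal(nrow(de), 0)
})

test_that("the CDR covariate path agrees with the general fitter", {
  cfg <- tiny_config(n_genes = 60, seed = 88)
  sim <- simulate_dataset(cfg)
  keep <- filter_genes(sim$counts, 5)
  norm <- lognormalize(sim$counts[keep, ])
  de <- run_de_contrast(norm, sim$metadata,
                        contrast_spec("ct1", "aged", "young",
                                      use_cdr = TRUE))
  expect_true(all(de$df[!is.na(de$p_value)] >= 1))
  expect_true(all(de$chi2[!is.na(de$chi2)] >= 0))
})
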