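test_that("the union rule keeps genes significant in either contrast", {
  deg_a <- make_deg(c("g1", "g2", "g3"), c(1, 0.5, 0.2),
                    q = c(0.01, 0.2, 0.9))
  deg_t <- make_deg(c("g1", "g2", "g3"), c(-0.5, -0.3, 0.1),
                    q = c(0.3, 0.04, 0.8))
  expect_equal(union_significant(deg_a, deg_t), c("g1", "g2"))
  # alpha = 1 gives all tested genes
  expect_equal(union_significant(deg_a, deg_t, alpha = 1.0),
               c("g1", "g2", "g3"))
  # no significant gene anywhere: explicit error
  none_a <- make_deg("g1", 1, q = 0.9)
  none_t <- make_deg("g1", 1, q = 0.9)
  expect_error(union_significant(none_a, none_t), "empty union")
  # significant gene untested in the other table is dropped with warning
  only_a <- make_deg(c("g1", "g2"), c(1, 1), q = c(0.01, 0.01))
  only_t <- make_deg("g1", -1, q = 0.3)
  expect_warning(u <- union_significant(only_a, only_t), "untested")
  expect_equal(u, "g1")
})

test_that("reversal statistics reproduce hand-computed OLS values", {
  x <- c(1, -1, 0.5, -2)
  y <- c(-0.5, 0.4, 0.2, 1.0)
  deg_a <- make_deg(paste0("g", 1:4), x)
  deg_t <- make_deg(paste0("g", 1:4), y)
  r <- reversal_statistics(deg_a, deg_t, paste0("g", 1:4))
  expect_equal(r$prop_reversed, 0.75)
  expect_equal(r$slope, -2.3875 / 5.6875, tolerance = 1e-12)
  expect_equal(r$n_union, 4L)
  expect_equal(nrow(r$gene_table), r$n_union)
})

test_that("reversal statistics hit their exact limits", {
  x <- c(0.5, -1, 2, -0.2)
  g <- paste0("g", 1:4)
  # perfect reversal
  r1 <- reversal_statistics(make_deg(g, x), make_deg(g, -x), g)
  expect_equal(r1$prop_reversed, 1)
  expect_equal(r1$slope, -1, tolerance = 1e-12)
  expect_equal(r1$r2, 1, tolerance = 1e-12)
  # perfect concordance
  r2 <- reversal_statistics(make_deg(g, x), make_deg(g, x), g)
  expect_equal(r2$prop_reversed, 0)
  expect_equal(r2$slope, 1, tolerance = 1e-12)
  # an exactly-zero lnFC carries no direction
  r3 <- reversal_statistics(make_deg(g, c(0, 1, -1, 2)),
                            make_deg(g, c(1, 0, 1, -2)), g)
  expect_equal(r3$prop_reversed, 0.5)   # only g3, g4 count as reversed? no:
  # g1: sign 0 * 1 -> not reversed; g2: 1 * 0 -> not; g3: -1 * 1 -> reversed;
  # g4: 2 * -2 -> reversed
  # fewer than 3 genes: proportion still returned, regression NA
  r4 <- reversal_statistics(make_deg(g[1:2], c(1, -1)),
                            make_deg(g[1:2], c(-1, 1)), g[1:2])
  expect_equal(r4$prop_reversed, 1)
  expect_true(is.na(r4$slope))
  # missing lnFC is an error
  expect_error(reversal_statistics(make_deg("g1", 1), make_deg("g2", 1),
                                   "g1"),
               "not available")
})

test_that("reversal statistics are antisymmetric under lnFC negation", {
  set.seed(14)
  g <- paste0("g", 1:30)
  x <- rnorm(30); y <- rnorm(30)
  r <- reversal_statistics(make_deg(g, x), make_deg(g, y), g)
  rn <- reversal_statistics(make_deg(g, x), make_deg(g, -y), g)
  expect_equal(rn$slope, -r$slope, tolerance = 1e-12)
  expect_equal(rn$gene_table$reversed[x != 0 & y != 0],
               !r$gene_table$reversed[x != 0 & y != 0])
})

test_that("top reversed selection ranks within both contrasts", {
  deg_a <- make_deg(c("g1", "g2", "g3"), c(1.0, 0.9, -0.2))
  deg_t <- make_deg(c("g1", "g2", "g3"), c(-0.8, 0.5, 0.1))
  expect_equal(select_top_reversed(deg_a, deg_t, rank_limit = 2), "g1")
  # rank_limit >= n reduces to all opposite-sign significant genes
  expect_equal(select_top_reversed(deg_a, deg_t, rank_limit = 10),
               c("g1", "g3"))
  # all concordant: empty selection
  conc <- make_deg(c("g1", "g2"), c(1, 2))
  expect_equal(select_top_reversed(conc, conc, 10), character())
  # selection is always a subset of the significant union
  set.seed(15)
  g <- paste0("g", 1:40)
  da <- make_deg(g, rnorm(40), q = runif(40, 0, 0.1))
  dt <- make_deg(g, rnorm(40), q = runif(40, 0, 0.1))
  sel <- select_top_reversed(da, dt, rank_limit = 1e6)
  expect_true(all(sel %in% union_significant(da, dt)))
})

test_that("pairwise consistency is exact for identical tables", {
  g <- paste0("g", 1:20)
  set.seed(16)
  tab <- make_deg(g, rnorm(20), q = 0.01)
  res <- pairwise_consistency(list(s1 = tab, s2 = tab))
  expect_equal(res$slope_12, 1, tolerance = 1e-12)
  expect_equal(res$slope_21, 1, tolerance = 1e-12)
  expect_equal(res$r2, 1, tolerance = 1e-12)
  # a subtype with no tested genes at all yields an NA row with a warning
  none <- make_deg(character(0), numeric(0))
  expect_warning(res2 <- pairwise_consistency(list(s1 = tab, s2 = none)),
                 "tiny union|untested|empty")
  expect_true(is.na(res2$r2))
  expect_error(pairwise_consistency(list(s1 = tab)), "at least 2")
})

test_that("subtypes sharing planted effects have positive pairwise slopes", {
  # two pseudo-subtypes from random halves of one cell type: identical
  # planted delta, independent sampling noise
  cfg <- tiny_config(n_genes = 1000, cells_per_sample_per_type = 60,
                     seed = 19)
  sim <- simulate_dataset(cfg)
  keep <- filter_genes(sim$counts, 5)
  norm <- lognormalize(sim$counts[keep, ])
  meta <- sim$metadata
  meta$cell_type <- ifelse(seq_len(nrow(meta)) %% 2 == 0, "s1", "s2")
  deg <- lapply(c("s1", "s2"), function(ct) {
    run_de_contrast(norm, meta, contrast_spec(ct, "aged", "young"))
  })
  names(deg) <- c("s1", "s2")
  res <- pairwise_consistency(deg)
  expect_gt(res$slope_12, 0)
  expect_gt(res$slope_21, 0)
  expect_gt(res$r2, 0.3)
})

test_that("replication checks count opposite signs conservatively", {
  g <- paste0("g", 1:6)
  deg_a <- make_deg(g, c(1, -1, 2, -2, 0.5, -0.5))
  deg_t <- make_deg(g, -c(1, -1, 2, -2, 0.5, -0.5))
  top <- select_top_reversed(deg_a, deg_t, rank_limit = 10)
  # replicate identical to the treatment table: full agreement
  rep1 <- replication_check(top, deg_t, deg_a)
  expect_equal(rep1$sign_agreement, 1)
  # all-zero replicate lnFC: zero is not reversed
  rep0 <- replication_check(top, make_deg(g, rep(0, 6)), deg_a)
  expect_equal(rep0$sign_agreement, 0)
  expect_error(replication_check(top, make_deg("other", 1), deg_a),
               "covers none")
})

test_that("vehicle-controlled replicates reproduce the reversal signs", {
  cfg <- tiny_config(n_genes = 1000, cells_per_sample_per_type = 40,
                     rho = 0.8, p_rev = 0.9,
                     groups = c("young", "aged", "treated", "vehicle"),
                     seed = 23)
  sim <- simulate_dataset(cfg)
  keep <- filter_genes(sim$counts, 5)
  norm <- lognormalize(sim$counts[keep, ])
  meta <- sim$metadata
  deg_age <- run_de_contrast(norm, meta, contrast_spec("ct1", "aged", "young"))
  deg_trt <- run_de_contrast(norm, meta, contrast_spec("ct1", "treated", "aged"))
  deg_veh <- run_de_contrast(norm, meta,
                             contrast_spec("ct1", "treated", "vehicle"))
  top <- select_top_reversed(deg_age, deg_trt, rank_limit = 500)
  expect_gt(length(top), 10)
  rep_res <- replication_check(top, deg_veh, deg_age)
  expect_gte(rep_res$sign_agreement, 0.8)
})
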