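test_that("module scores vanish when signature and controls are identical", {
  # every gene identical across genes: controls equal signature exactly
  m <- matrix(rep(c(1, 2, 3, 4), each = 8), 8, 4, byrow = TRUE)
  dimnames(m) <- list(sprintf("g%02d", 1:8), sprintf("c%02d", 1:4))
  norm <- methods::as(m, "CsparseMatrix")
  sc <- module_score(norm, c("g01", "g03"), nbins = 2, nctrl = 3, seed = 1)
  expect_equal(unname(as.numeric(sc)), rep(0, 4), tolerance = 1e-12)
})

test_that("module scores are hand-computable with homogeneous bins", {
  # two bins of genes with constant within-bin values: any control draw
  # yields the same hand-derivable score
  low <- matrix(1, 5, 4)    # bin 1: value 1 in every cell
  high <- matrix(3, 5, 4)   # bin 2: value 3 in every cell
  m <- rbind(low, high)
  dimnames(m) <- list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:4))
  norm <- methods::as(m, "CsparseMatrix")
  # signature: one low gene and one high gene -> mean 2; controls: one
  # draw from each bin -> pooled mean 2; score 0
  sc <- module_score(norm, c("g01", "g06"), nbins = 2, nctrl = 1, seed = 1)
  expect_equal(unname(as.numeric(sc)), rep(0, 4), tolerance = 1e-12)
  # signature entirely in the high bin: score 3 - 3 = 0; shift the
  # signature genes by +c in two cells and the score moves by exactly +c
  m2 <- m
  m2[6, 1:2] <- m2[6, 1:2] + 0.7
  norm2 <- methods::as(m2, "CsparseMatrix")
  sc2 <- module_score(norm2, "g06", nbins = 2, nctrl = 1, seed = 1)
  base2 <- module_score(norm, "g06", nbins = 2, nctrl = 1, seed = 1)
  expect_equal(as.numeric(sc2 - base2), c(0.7, 0.7, 0, 0),
               tolerance = 1e-6)
})

test_that("module scoring is deterministic under the seed and warns on
          missing genes", {
  sim <- simulate_dataset(tiny_config(seed = 6))
  norm <- lognormalize(sim$counts[filter_genes(sim$counts, 5), ])
  sig <- head(rownames(norm), 5)
  s1 <- module_score(norm, sig, seed = 10)
  s2 <- module_score(norm, sig, seed = 10)
  expect_identical(as.numeric(s1), as.numeric(s2))
  s3 <- module_score(norm, sig, seed = 11)
  expect_false(identical(attr(s1, "control_genes"),
                         attr(s3, "control_genes")))
  expect_warning(module_score(norm, c(sig, "absent-gene"), seed = 1),
                 "missing from matrix")
  expect_error(module_score(norm, "absent-gene", seed = 1),
               "no signature gene")
})

test_that("module score is invariant to a global constant shift", {
  sim <- simulate_dataset(tiny_config(seed = 13))
  norm <- as.matrix(lognormalize(sim$counts[filter_genes(sim$counts, 5), ]))
  sig <- rownames(norm)[10:14]
  s1 <- module_score(methods::as(norm, "CsparseMatrix"), sig, seed = 4)
  # adding a constant to every gene in every cell shifts signature and
  # control means equally (bin ranks are also preserved)
  s2 <- module_score(methods::as(norm + 1, "CsparseMatrix"), sig, seed = 4)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-10)
})

test_that("Kruskal-Wallis matches the hand-computed H", {
  r <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(r$H, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  # all observations tied: H defined as 0 with p = 1
  r0 <- kruskal_wallis(rep(1, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(r0$H, 0)
  expect_equal(r0$p_value, 1)
  expect_error(kruskal_wallis(1:3, factor(c("a", "a", "a"),
                                          levels = c("a", "b"))),
               "at least 2 groups|empty group")
})

test_that("Kruskal-Wallis p-values are calibrated under the null", {
  set.seed(20)
  hits <- mean(replicate(1000, {
    kruskal_wallis(rnorm(30), rep(c("a", "b"), 15))$p_value < 0.05
  }))
  expect_gt(hits, 0.03)
  expect_lt(hits, 0.07)
})

test_that("Dunn post hoc z statistics match the hand computation", {
  d <- dunn_posthoc(1:9, rep(c("a", "b", "c"), each = 3))
  z13 <- d$z[d$group_i == "a" & d$group_j == "c"]
  expect_equal(z13, -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(nrow(d), 3)    # C(3, 2) pairs
  # identical groups: z = 0, p = 1
  d0 <- dunn_posthoc(rep(c(1, 2), 6), rep(c("a", "b"), each = 6))
  expect_equal(d0$z, 0)
  expect_equal(d0$p_value, 1)
  # antisymmetry: swapping the factor order flips the sign
  drev <- dunn_posthoc(1:9, factor(rep(c("a", "b", "c"), each = 3),
                                   levels = c("c", "b", "a")))
  zrev <- drev$z[drev$group_i == "c" & drev$group_j == "a"]
  expect_equal(zrev, -z13, tolerance = 1e-12)
  # Holm adjustment never decreases p
  dh <- dunn_posthoc(1:9, rep(c("a", "b", "c"), each = 3), adjust = "holm")
  expect_true(all(dh$p_value >= d$p_value - 1e-12))
})

test_that("rank tests agree with an exact permutation oracle at tiny n", {
  x <- c(1.2, 3.4, 0.5, 2.2, 5.1, 4.4, 2.9, 0.1)
  g <- rep(c("a", "b"), each = 4)
  obs <- kruskal_wallis(x, g)$H
  # enumerate all C(8,4) group assignments
  combos <- utils::combn(8, 4)
  perm_h <- apply(combos, 2, function(idx) {
    gg <- rep("b", 8); gg[idx] <- "a"
    kruskal_wallis(x, gg)$H
  })
  p_perm <- mean(perm_h >= obs - 1e-12)
  p_chi2 <- kruskal_wallis(x, g)$p_value
  expect_lt(abs(p_perm - p_chi2), 0.1)
})

test_that("planted signature shifts order the group medians", {
  cfg <- tiny_config(n_genes = 800, cells_per_sample_per_type = 40,
                     rho = 0.8, signature_size = 40,
                     signature_shift_ln = 0.5, seed = 25)
  sim <- simulate_dataset(cfg)
  keep <- filter_genes(sim$counts, 5)
  norm <- lognormalize(sim$counts[keep, ])
  sig <- intersect(sim$truth$gene_ids[sim$truth$is_signature],
                   rownames(norm))
  res <- score_and_compare(norm, sim$metadata, sig, cell_type = "ct1",
                           seed = 2)
  med <- res$kruskal$group_medians
  expect_gt(med[["aged"]], med[["treated"]])
  expect_gt(med[["treated"]], med[["young"]])
  expect_lt(res$kruskal$p_value, 0.05)
  expect_equal(nrow(res$dunn), 3)
})
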