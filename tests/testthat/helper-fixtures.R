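# Shared fixtures: small simulation configurations and utilities.

# Minimal single-cell-type configuration for fast unit tests.
tiny_config <- function(...) {
  defaults <- list(n_genes = 300, n_cell_types = 1,
                   cells_per_sample_per_type = 20, samples_per_group = 3,
                   f_de = 0.1, f_treat_only = 0, marker_genes_per_type = 5,
                   n_mito_genes = 5, signature_size = 10,
                   f_high_mito_cells = 0.02, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# A dense labeled count matrix from explicit values (genes x cells).
make_counts <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  methods::as(m, "CsparseMatrix")
}

# A DEG-table-shaped data.frame from parallel vectors.
make_deg <- function(gene, lnFC, q = 0.01, p = q) {
  n <- length(gene)
  data.frame(gene = gene, lnFC = lnFC, p_value = rep_len(p, n),
             q_value = rep_len(q, n), pct_A = rep_len(0.5, n),
             pct_B = rep_len(0.5, n), chi2 = rep_len(1, n),
             df = rep_len(2L, n), stringsAsFactors = FALSE)
}

# Adjusted Rand index between two labelings (for cluster recovery checks).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Joint hurdle negative log-likelihood for brute-force numerical
# maximization: an oracle independent of the package's fitting code.
hurdle_negll <- function(par, y, design) {
  p <- ncol(design)
  bd <- par[seq_len(p)]
  bc <- par[p + seq_len(p)]
  log_s2 <- par[2 * p + 1]
  eta <- drop(design %*% bd)
  pr <- 1 / (1 + exp(-eta))
  pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
  z <- y > 0
  ll_disc <- sum(log(pr[z])) + sum(log(1 - pr[!z]))
  mu <- drop(design %*% bc)[z]
  s2 <- exp(log_s2)
  ll_cont <- sum(stats::dnorm(y[z], mu, sqrt(s2), log = TRUE))
  -(ll_disc + ll_cont)
}

brute_force_hurdle_ll <- function(y, design) {
  p <- ncol(design)
  best <- Inf
  for (start_scale in c(0, 0.5)) {
    start <- c(rep(start_scale, p), rep(start_scale, p), 0)
    fit <- tryCatch(
      stats::optim(start, hurdle_negll, y = y, design = design,
                   method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best) best <- fit$value
  }
  -best
}
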