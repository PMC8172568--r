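#' Configuration for the planted-reversal single-cell simulator
#'
#' Builds a validated configuration for [simulate_dataset()]. The generator
#' emulates a multi-group (young / aged / treated, optionally vehicle),
#' multi-cell-type UMI count experiment in which a subset of genes changes
#' with age in each affected cell type and the treatment shifts a tunable
#' fraction of those genes back toward the young state by a tunable multiple
#' `rho` of the aging effect.
#'
#' Counts are negative binomial with per-gene dispersion and log-normal
#' library sizes; cell types carry boosted marker genes; a fraction of cells
#' has inflated mitochondrial content (QC failures); one designated cell
#' type carries a disease-associated signature that is up-shifted with age
#' and partially reversed by treatment.
#'
#' @param n_genes Number of genes.
#' @param n_cell_types Number of cell types.
#' @param cells_per_sample_per_type Cells per animal per cell type.
#' @param samples_per_group Animals per group (default 3, three mice per
#'   group).
#' @param groups Ordered group labels; must contain `young`, `aged` and
#'   `treated` for reversal experiments; `vehicle` (vehicle-treated aged) is
#'   optional.
#' @param f_de Fraction of genes with an aging effect per affected cell type.
#' @param de_effect_mean,de_effect_sd Mean and sd of the aging effect
#'   magnitude `|delta|` (natural-log scale, normal truncated at 0); the
#'   sign is a fair coin.
#' @param rho Reversal coefficient in `[0, 1.5]`: reversed genes receive a
#'   treatment effect `tau = -rho * delta`. Scalar or one value per cell
#'   type.
#' @param p_rev Fraction of aging-DE genes that are reversed (others get
#'   `tau = 0`).
#' @param f_treat_only Fraction of genes with treatment-only effects
#'   (`delta = 0`, `tau` drawn from the aging-effect family).
#' @param theta_meanlog,theta_sdlog Log-normal parameters of the NB size
#'   (dispersion) parameter.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size parameters.
#' @param marker_genes_per_type Marker genes per cell type.
#' @param marker_boost_ln Natural-log elevation of marker genes in their
#'   own cell type.
#' @param n_mito_genes Number of mitochondrial genes (IDs prefixed `mt-`).
#' @param f_high_mito_cells Fraction of cells with inflated mitochondrial
#'   fraction (expected fraction 0.35, above the 0.20 QC cutoff).
#' @param signature_size Number of genes in the planted disease signature.
#' @param signature_shift_ln Aging up-shift of signature genes (natural log)
#'   in the designated cell type; treatment moves them by `-rho` times this.
#' @param signature_cell_type Index of the cell type carrying the signature.
#' @param sample_noise_sd Per-sample per-gene log-normal jitter sd
#'   (animal-to-animal variation).
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_cell_types = 2,
                              cells_per_sample_per_type = 60,
                              samples_per_group = 3,
                              groups = c("young", "aged", "treated"),
                              f_de = 0.1,
                              de_effect_mean = 0.8,
                              de_effect_sd = 0.25,
                              rho = 0.8,
                              p_rev = 0.9,
                              f_treat_only = 0.05,
                              theta_meanlog = log(2),
                              theta_sdlog = 0.5,
                              libsize_meanlog = log(4000),
                              libsize_sdlog = 0.35,
                              marker_genes_per_type = 25,
                              marker_boost_ln = log(5),
                              n_mito_genes = 10,
                              f_high_mito_cells = 0.02,
                              signature_size = 50,
                              signature_shift_ln = 0.5,
                              signature_cell_type = 1,
                              sample_noise_sd = 0.05,
                              seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cell_types = as.integer(n_cell_types),
              cells_per_sample_per_type = as.integer(cells_per_sample_per_type),
              samples_per_group = as.integer(samples_per_group),
              groups = as.character(groups),
              f_de = f_de, de_effect_mean = de_effect_mean,
              de_effect_sd = de_effect_sd,
              rho = rep_len(rho, n_cell_types),
              p_rev = p_rev, f_treat_only = f_treat_only,
              theta_meanlog = theta_meanlog, theta_sdlog = theta_sdlog,
              libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
              marker_genes_per_type = as.integer(marker_genes_per_type),
              marker_boost_ln = marker_boost_ln,
              n_mito_genes = as.integer(n_mito_genes),
              f_high_mito_cells = f_high_mito_cells,
              signature_size = as.integer(signature_size),
              signature_shift_ln = signature_shift_ln,
              signature_cell_type = as.integer(signature_cell_type),
              sample_noise_sd = sample_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L || cfg$n_cell_types < 1L ||
      cfg$cells_per_sample_per_type < 1L || cfg$samples_per_group < 1L) {
    stop("invalid config: zero genes or zero cells")
  }
  fracs <- c(cfg$f_de, cfg$p_rev, cfg$f_treat_only, cfg$f_high_mito_cells)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (any(cfg$rho < 0 | cfg$rho > 1.5)) stop("rho must lie in [0, 1.5]")
  if (!all(c("young", "aged", "treated") %in% cfg$groups)) {
    stop("groups must contain young, aged and treated")
  }
  if (!all(cfg$groups %in% c("young", "aged", "treated", "vehicle"))) {
    stop("unknown group label")
  }
  if (cfg$signature_cell_type < 1L ||
      cfg$signature_cell_type > cfg$n_cell_types) {
    stop("signature_cell_type out of range")
  }
  n_special <- cfg$n_mito_genes +
    cfg$marker_genes_per_type * cfg$n_cell_types + cfg$signature_size
  if (n_special >= cfg$n_genes) {
    stop("n_genes too small for the requested marker/mito/signature genes")
  }
  invisible(cfg)
}

# Gene-level ground truth: baselines, dispersions, flags and per-cell-type
# effect matrices delta (aged vs young) and tau (treated vs aged).
draw_truth <- function(config, seed = config$seed) {
  with_seed(seed, {
    ng <- config$n_genes
    nk <- config$n_cell_types
    gene_ids <- sprintf("gene%05d", seq_len(ng))
    if (config$n_mito_genes > 0) {
      gene_ids[seq_len(config$n_mito_genes)] <-
        sprintf("mt-gene%03d", seq_len(config$n_mito_genes))
    }
    is_mito <- startsWith(gene_ids, "mt-")
    m <- stats::rnorm(ng, mean = 0, sd = 1)
    theta <- stats::rlnorm(ng, config$theta_meanlog, config$theta_sdlog)

    cell_types <- sprintf("ct%d", seq_len(nk))
    is_marker <- matrix(FALSE, ng, nk, dimnames = list(gene_ids, cell_types))
    avail <- which(!is_mito)
    for (k in seq_len(nk)) {
      pick <- sample(avail, config$marker_genes_per_type)
      is_marker[pick, k] <- TRUE
      avail <- setdiff(avail, pick)
    }
    is_signature <- rep(FALSE, ng)
    if (config$signature_size > 0) {
      pick <- sample(avail, config$signature_size)
      is_signature[pick] <- TRUE
      avail <- setdiff(avail, pick)
    }

    delta <- matrix(0, ng, nk, dimnames = list(gene_ids, cell_types))
    tau <- matrix(0, ng, nk, dimnames = list(gene_ids, cell_types))
    is_reversed <- matrix(FALSE, ng, nk,
                          dimnames = list(gene_ids, cell_types))
    rtruncnorm0 <- function(n) {
      x <- stats::rnorm(n, config$de_effect_mean, config$de_effect_sd)
      while (any(bad <- x <= 0)) {
        x[bad] <- stats::rnorm(sum(bad), config$de_effect_mean,
                               config$de_effect_sd)
      }
      x
    }
    n_de <- round(config$f_de * ng)
    n_to <- round(config$f_treat_only * ng)
    for (k in seq_len(nk)) {
      pool <- avail
      de <- if (n_de > 0) sample(pool, min(n_de, length(pool))) else integer()
      if (length(de)) {
        sgn <- sample(c(-1, 1), length(de), replace = TRUE)
        delta[de, k] <- sgn * rtruncnorm0(length(de))
        rev <- de[stats::runif(length(de)) < config$p_rev]
        tau[rev, k] <- -config$rho[k] * delta[rev, k]
        is_reversed[rev, k] <- config$rho[k] > 0
      }
      pool <- setdiff(pool, de)
      to <- if (n_to > 0) sample(pool, min(n_to, length(pool))) else integer()
      if (length(to)) {
        sgn <- sample(c(-1, 1), length(to), replace = TRUE)
        tau[to, k] <- sgn * rtruncnorm0(length(to))
      }
    }
    # planted disease signature: up with age, partially reversed by treatment
    if (config$signature_size > 0 && config$signature_shift_ln != 0) {
      k <- config$signature_cell_type
      sig <- which(is_signature)
      delta[sig, k] <- config$signature_shift_ln
      tau[sig, k] <- -config$rho[k] * config$signature_shift_ln
      is_reversed[sig, k] <- config$rho[k] > 0
    }
    structure(list(config = config, gene_ids = gene_ids,
                   cell_types = cell_types, m = m, theta = theta,
                   is_mito = is_mito, is_marker = is_marker,
                   is_signature = is_signature, delta = delta, tau = tau,
                   is_reversed = is_reversed),
              class = "sim_truth")
  })
}

#' Simulate a multi-group, multi-cell-type UMI count dataset
#'
#' Draws counts `NB(mean = L_c * q_gc, size = theta_g)` where the relative
#' expression `q_gc` is proportional to
#' `exp(m_g + marker boost + group effect + sample jitter)`, renormalized
#' within each cell so that library size is independent of group. Aged cells
#' of affected types carry the aging effect `delta`; treated cells carry
#' `delta + tau`; vehicle cells (if present) carry `delta` only. A fraction
#' of cells has mitochondrial relative expression inflated to an expected
#' mitochondrial fraction of 0.35.
#'
#' @param config A [simulation_config()] object.
#' @return A list with `counts` (sparse genes x cells matrix), `metadata`
#'   (data.frame with barcode, sample, group, cell_type, high_mito flag) and
#'   `truth` (a `sim_truth` object).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  truth <- draw_truth(config, config$seed)
  with_seed(stage_seed(config$seed, "cells"), {
    ng <- config$n_genes
    nk <- config$n_cell_types
    groups <- config$groups
    nspg <- config$samples_per_group
    cpst <- config$cells_per_sample_per_type

    samples <- as.vector(outer(seq_len(nspg), groups,
                               function(s, g) paste0(g, "_s", s)))
    sample_group <- rep(groups, each = nspg)
    # animal-level jitter, shared by all cells of one sample
    jitter <- matrix(stats::rnorm(ng * length(samples), 0,
                                  config$sample_noise_sd),
                     ng, length(samples))

    n_cells <- nk * length(groups) * nspg * cpst
    counts <- matrix(0L, ng, n_cells)
    barcode <- character(n_cells)
    meta_sample <- character(n_cells)
    meta_group <- character(n_cells)
    meta_type <- character(n_cells)
    high_mito <- rep(FALSE, n_cells)
    mito_idx <- which(truth$is_mito)

    col <- 0L
    for (k in seq_len(nk)) {
      base_k <- truth$m + config$marker_boost_ln * truth$is_marker[, k]
      for (si in seq_along(samples)) {
        g <- sample_group[si]
        eff <- switch(g,
                      young = 0,
                      aged = truth$delta[, k],
                      vehicle = truth$delta[, k],
                      treated = truth$delta[, k] + truth$tau[, k])
        logq <- base_k + eff + jitter[, si]
        q <- exp(logq)
        flags <- stats::runif(cpst) < config$f_high_mito_cells
        L <- stats::rlnorm(cpst, config$libsize_meanlog, config$libsize_sdlog)
        for (ci in seq_len(cpst)) {
          qc <- q
          if (flags[ci] && length(mito_idx)) {
            # inflate mito share to an expected fraction of 0.35
            s_m <- sum(qc[mito_idx])
            s_o <- sum(qc[-mito_idx])
            if (s_m > 0) {
              qc[mito_idx] <- qc[mito_idx] * (0.35 * s_o) / (0.65 * s_m)
            }
          }
          qc <- qc / sum(qc)
          col <- col + 1L
          counts[, col] <- stats::rnbinom(ng, mu = L[ci] * qc,
                                          size = truth$theta)
          barcode[col] <- sprintf("cell%06d", col)
          meta_sample[col] <- samples[si]
          meta_group[col] <- g
          meta_type[col] <- truth$cell_types[k]
          high_mito[col] <- flags[ci]
        }
      }
    }
    dimnames(counts) <- list(truth$gene_ids, barcode)
    metadata <- data.frame(barcode = barcode, sample = meta_sample,
                           group = factor(meta_group, levels = groups),
                           cell_type = meta_type, high_mito = high_mito,
                           stringsAsFactors = FALSE)
    list(counts = methods::as(counts, "CsparseMatrix"),
         metadata = metadata, truth = truth)
  })
}

#' Ground-truth effect table for one cell type
#'
#' @param truth A `sim_truth` object.
#' @param cell_type Cell-type label present in the truth.
#' @return data.frame with columns `gene`, `delta` (aging lnFC), `tau`
#'   (treatment lnFC relative to aged) and `is_reversed`.
#' @export
planted_effect_table <- function(truth, cell_type) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!cell_type %in% truth$cell_types) {
    stop("unknown cell type: ", cell_type)
  }
  data.frame(gene = truth$gene_ids,
             delta = truth$delta[, cell_type],
             tau = truth$tau[, cell_type],
             is_reversed = truth$is_reversed[, cell_type],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Truth-level expected reversal statistics
#'
#' Computes, at the level of the planted effects and without simulating any
#' counts, the expected reversal summary for one cell type: the OLS slope of
#' the treatment effect `tau` on the aging effect `delta` and the proportion
#' of sign-discordant genes, over genes with `delta != 0` or `tau != 0`.
#' A gene with `tau = 0` (or `delta = 0`) carries no direction and counts as
#' not reversed. Because the planted effects are random, the expectation is
#' estimated by Monte Carlo over fresh truth draws from the same
#' configuration.
#'
#' @param truth A `sim_truth` object.
#' @param cell_type Cell-type label.
#' @param n_mc Number of Monte-Carlo truth draws (1 = use the given truth
#'   only).
#' @param seed Seed for the Monte-Carlo draws.
#' @return List with `expected_slope`, `expected_prop_reversed`, `n_mc`, and
#'   Monte-Carlo standard errors `se_slope`, `se_prop`.
#' @export
expected_reversal <- function(truth, cell_type, n_mc = 100,
                              seed = truth$config$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!cell_type %in% truth$cell_types) {
    stop("unknown cell type: ", cell_type)
  }
  one <- function(tr) {
    d <- tr$delta[, cell_type]
    t_ <- tr$tau[, cell_type]
    keep <- d != 0 | t_ != 0
    if (!any(keep)) stop("no DE genes for cell type ", cell_type)
    d <- d[keep]; t_ <- t_[keep]
    prop <- mean(sign(d) * sign(t_) < 0)
    slope <- if (stats::var(d) > 0) {
      sum((d - mean(d)) * (t_ - mean(t_))) / sum((d - mean(d))^2)
    } else NA_real_
    c(slope = slope, prop = prop)
  }
  if (n_mc <= 1) {
    est <- one(truth)
    return(list(expected_slope = unname(est["slope"]),
                expected_prop_reversed = unname(est["prop"]),
                n_mc = 1L, se_slope = NA_real_, se_prop = NA_real_))
  }
  draws <- vapply(seq_len(n_mc), function(i) {
    one(draw_truth(truth$config, stage_seed(seed, paste0("mc", i))))
  }, c(slope = 0, prop = 0))
  list(expected_slope = mean(draws["slope", ]),
       expected_prop_reversed = mean(draws["prop", ]),
       n_mc = as.integer(n_mc),
       se_slope = stats::sd(draws["slope", ]) / sqrt(n_mc),
       se_prop = stats::sd(draws["prop", ]) / sqrt(n_mc))
}
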