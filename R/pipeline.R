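#' Pipeline configuration
#'
#' Collects the constants of the full analysis. Defaults follow the
#' reference workflow: 3000 high-variance genes, 30 principal components,
#' SNN with k = 20 and Jaccard pruning 1/15, modularity resolution 1.4,
#' significance threshold q < 0.05, top-500 fold-change ranking for the
#' top reversed genes, and 24 bins / 100 controls for module scores.
#'
#' @param simulation A [simulation_config()] for synthetic input, or NULL.
#' @param input Optional list with `matrix`, `genes`, `barcodes`,
#'   `metadata` paths for real input (ignored when `simulation` is given).
#' @param qc A [qc_thresholds()] object.
#' @param n_hvg,n_pcs,snn_k,snn_prune,resolution,alpha,rank_limit,nbins,nctrl
#'   Stage parameters (see module docs).
#' @param marker_gmt,signature_gmt Optional GMT paths; with simulated input
#'   the planted marker and signature sets are used when these are NULL.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param outdir Output directory, or NULL to skip writing.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input = NULL,
                            qc = qc_thresholds(),
                            n_hvg = 3000, n_pcs = 30, snn_k = 20,
                            snn_prune = 1 / 15, resolution = 1.4,
                            alpha = 0.05, rank_limit = 500,
                            nbins = 24, nctrl = 100,
                            marker_gmt = NULL, signature_gmt = NULL,
                            seed = 1, outdir = NULL) {
  if (is.null(simulation) && is.null(input)) {
    stop("either a simulation section or input paths are required")
  }
  structure(list(simulation = simulation, input = input, qc = qc,
                 n_hvg = n_hvg, n_pcs = n_pcs, snn_k = snn_k,
                 snn_prune = snn_prune, resolution = resolution,
                 alpha = alpha, rank_limit = rank_limit, nbins = nbins,
                 nctrl = nctrl, marker_gmt = marker_gmt,
                 signature_gmt = signature_gmt, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `simulation` and `qc` sections mirror [simulation_config()] and
#' [qc_thresholds()]. Unknown keys are an error.
#'
#' @param path Path to a YAML configuration file.
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$simulation)) {
    bad <- setdiff(names(raw$simulation), names(formals(simulation_config)))
    if (length(bad)) {
      stop("unknown simulation key(s): ", paste(bad, collapse = ", "))
    }
    raw$simulation <- do.call(simulation_config, raw$simulation)
  }
  if (!is.null(raw$qc)) {
    bad <- setdiff(names(raw$qc), names(formals(qc_thresholds)))
    if (length(bad)) {
      stop("unknown qc key(s): ", paste(bad, collapse = ", "))
    }
    raw$qc <- do.call(qc_thresholds, raw$qc)
  }
  do.call(pipeline_config, raw)
}

#' Demo configuration: small planted-reversal experiment
#'
#' Two cell types, one with reversal coefficient 0.8 and one non-reversed
#' control, three animals per group, scaled for a fast end-to-end run.
#'
#' @param seed Master seed.
#' @param outdir Optional output directory.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1, outdir = NULL) {
  pipeline_config(
    simulation = simulation_config(
      n_genes = 1500, n_cell_types = 2, cells_per_sample_per_type = 40,
      rho = c(0.8, 0), f_treat_only = 0, signature_cell_type = 1,
      seed = seed),
    n_hvg = 500, n_pcs = 20, snn_k = 15,
    seed = seed, outdir = outdir)
}

#' Run the full reversal analysis pipeline
#'
#' Simulate or load counts, apply gene and cell quality control, normalize,
#' select high-variance genes, embed with PCA, build the SNN graph, cluster
#' by modularity, assign cell types by marker z-scores, run the hurdle
#' differential-expression contrasts per cell type (aged vs young and
#' treated vs aged, plus treated vs vehicle when a vehicle group is
#' present), compute reversal statistics and top reversed genes per cell
#' type, run over-representation analysis of the top reversed genes, score
#' the disease signature in its cell type with Kruskal-Wallis and Dunn
#' comparisons, and assess cross-cell-type consistency. All randomness
#' derives from the master seed; a rerun with the same configuration is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage outputs and a `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("screversal")),
                   seed = config$seed, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  # --- input ---
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_dataset(config$simulation)
    counts <- sim$counts
    metadata <- sim$metadata
    truth <- sim$truth
  } else {
    counts <- read_mtx_bundle(config$input$matrix, config$input$genes,
                              config$input$barcodes)
    metadata <- read_table_typed(config$input$metadata,
                                 schema = c(barcode = "character",
                                            sample = "character",
                                            group = "character"))
  }
  log_stage("input", n_genes = nrow(counts), n_cells = ncol(counts))

  # --- QC: gene filter on the raw matrix, then cell filters ---
  gene_mask <- filter_genes(counts, config$qc$min_cells_per_gene)
  counts <- counts[gene_mask, , drop = FALSE]
  qc <- compute_cell_qc(counts)
  cell_mask <- filter_cells(qc, config$qc)
  counts <- counts[, cell_mask, drop = FALSE]
  metadata <- metadata[match(colnames(counts), metadata$barcode), ]
  log_stage("qc", genes_retained = sum(gene_mask),
            cells_retained = sum(cell_mask))

  # --- normalization and HVG selection ---
  norm <- lognormalize(counts)
  n_hvg <- min(config$n_hvg, nrow(counts))
  hvg <- suppressWarnings(select_hvg(counts, n_hvg = n_hvg))
  log_stage("hvg", n_hvg = length(hvg))

  # --- embedding and clustering ---
  emb <- pca_embed(norm, hvg, n_pcs = config$n_pcs)
  snn <- build_snn(emb, k = config$snn_k, prune = config$snn_prune)
  labels <- cluster_modularity(snn, resolution = config$resolution,
                               seed = stage_seed(config$seed, "cluster"))
  log_stage("cluster", n_clusters = length(unique(labels)),
            modularity = attr(labels, "modularity"))

  # --- cell-type assignment ---
  marker_sets <- if (!is.null(config$marker_gmt)) {
    read_gmt(config$marker_gmt)
  } else if (!is.null(truth)) {
    stats::setNames(lapply(truth$cell_types, function(k) {
      truth$gene_ids[truth$is_marker[, k]]
    }), truth$cell_types)
  } else {
    stop("marker_gmt is required for non-simulated input")
  }
  assignment <- suppressWarnings(
    assign_cell_types(norm, labels, marker_sets))
  type_of_cluster <- stats::setNames(assignment$assigned_type,
                                     assignment$cluster)
  metadata$cell_type <- unname(
    type_of_cluster[as.character(labels[metadata$barcode])])
  analysed <- !is.na(metadata$cell_type)
  log_stage("assign", n_excluded_clusters = sum(assignment$excluded),
            n_cells_analysed = sum(analysed))

  # --- differential expression per cell type ---
  has_vehicle <- "vehicle" %in% metadata$group
  cell_types <- sort(unique(metadata$cell_type[analysed]))
  deg <- list()
  for (ct in cell_types) {
    deg[[ct]] <- list(
      age = run_de_contrast(norm, metadata,
                            contrast_spec(ct, "aged", "young")),
      treat = run_de_contrast(norm, metadata,
                              contrast_spec(ct, "treated", "aged")))
    if (has_vehicle) {
      deg[[ct]]$vehicle <- run_de_contrast(
        norm, metadata, contrast_spec(ct, "treated", "vehicle"))
    }
  }

  # --- reversal statistics, top reversed genes, enrichment ---
  reversal <- list()
  top_reversed <- list()
  enrichment <- list()
  sig_set <- if (!is.null(config$signature_gmt)) {
    read_gmt(config$signature_gmt)[[1]]
  } else if (!is.null(truth)) {
    truth$gene_ids[truth$is_signature]
  } else NULL
  ora_collection <- c(marker_sets,
                      if (!is.null(sig_set)) list(signature = sig_set))
  for (ct in cell_types) {
    u <- tryCatch(
      union_significant(deg[[ct]]$age, deg[[ct]]$treat, config$alpha),
      error = function(e) {
        warning("cell type ", ct, ": ", conditionMessage(e))
        character()
      })
    if (length(u)) {
      reversal[[ct]] <- reversal_statistics(deg[[ct]]$age,
                                            deg[[ct]]$treat, u)
    }
    top_reversed[[ct]] <- select_top_reversed(
      deg[[ct]]$age, deg[[ct]]$treat, config$rank_limit, config$alpha)
    if (length(top_reversed[[ct]]) > 0) {
      universe <- intersect(deg[[ct]]$age$gene, deg[[ct]]$treat$gene)
      enrichment[[ct]] <- suppressWarnings(enrich_collection(
        top_reversed[[ct]], ora_collection, universe, config$alpha))
    }
  }
  log_stage("reversal",
            n_union = vapply(reversal, function(r) r$n_union, 0L),
            prop_reversed = vapply(reversal,
                                   function(r) r$prop_reversed, 0),
            slope = vapply(reversal, function(r) r$slope, 0))

  # --- signature scoring in the designated cell type ---
  signature_result <- NULL
  if (!is.null(sig_set)) {
    sig_ct <- if (!is.null(truth)) {
      truth$cell_types[config$simulation$signature_cell_type]
    } else cell_types[1]
    if (sig_ct %in% cell_types) {
      signature_result <- score_and_compare(
        norm, metadata, sig_set, cell_type = sig_ct,
        nbins = config$nbins, nctrl = config$nctrl,
        seed = stage_seed(config$seed, "score"))
      log_stage("signature", cell_type = sig_ct,
                kruskal_p = signature_result$kruskal$p_value,
                medians = as.list(signature_result$kruskal$group_medians))
    }
  }

  # --- cross-cell-type consistency of the aging contrast ---
  consistency <- NULL
  if (length(cell_types) >= 2) {
    consistency <- suppressWarnings(pairwise_consistency(
      lapply(deg[cell_types], `[[`, "age"), config$alpha))
  }

  result <- list(config = config, counts = counts, metadata = metadata,
                 truth = truth, norm_method = attr(norm, "method"),
                 hvg = hvg, embedding = emb, labels = labels,
                 assignment = assignment, deg = deg, reversal = reversal,
                 top_reversed = top_reversed, enrichment = enrichment,
                 signature = signature_result, consistency = consistency,
                 manifest = manifest)
  if (!is.null(config$outdir)) {
    write_pipeline_outputs(result, config$outdir)
  }
  invisible(result)
}

# Serialize pipeline outputs as TSV/MTX/JSON under outdir.
write_pipeline_outputs <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_mtx_bundle(result$counts, file.path(outdir, "counts"))
  write_table_typed(result$metadata, file.path(outdir, "metadata.tsv"))
  for (ct in names(result$deg)) {
    for (con in names(result$deg[[ct]])) {
      write_table_typed(result$deg[[ct]][[con]],
                        file.path(outdir,
                                  sprintf("deg_%s_%s.tsv", ct, con)))
    }
  }
  rev_summary <- do.call(rbind, lapply(names(result$reversal), function(ct) {
    r <- result$reversal[[ct]]
    data.frame(cell_type = ct, n_union = r$n_union,
               prop_reversed = r$prop_reversed, slope = r$slope,
               intercept = r$intercept, r2 = r$r2, p_slope = r$p_slope,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(rev_summary)) {
    write_table_typed(rev_summary, file.path(outdir, "reversal_summary.tsv"))
    for (ct in names(result$reversal)) {
      write_table_typed(result$reversal[[ct]]$gene_table,
                        file.path(outdir,
                                  sprintf("reversal_genes_%s.tsv", ct)))
    }
  }
  for (ct in names(result$enrichment)) {
    write_table_typed(result$enrichment[[ct]],
                      file.path(outdir, sprintf("enrichment_%s.tsv", ct)))
  }
  if (!is.null(result$signature)) {
    write_table_typed(result$signature$scores,
                      file.path(outdir, "signature_scores.tsv"))
    write_table_typed(result$signature$dunn,
                      file.path(outdir, "signature_dunn.tsv"))
  }
  if (!is.null(result$consistency)) {
    write_table_typed(result$consistency,
                      file.path(outdir, "consistency.tsv"))
  }
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
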