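#' Read a 10x-style MatrixMarket count bundle
#'
#' Reads a sparse genes x cells count matrix from a MatrixMarket coordinate
#' file plus sidecar gene and barcode TSV files (first column used as the
#' label). Entries absent from the file are zero. The file must declare
#' `coordinate integer general`, or `real` with integral values.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param genes_path Path to the gene TSV (one gene per line).
#' @param barcodes_path Path to the barcode TSV (one barcode per line).
#' @return A `dgCMatrix` with gene IDs as rownames and barcodes as colnames.
#' @export
read_mtx_bundle <- function(matrix_path, genes_path, barcodes_path) {
  header <- readLines(matrix_path, n = 1L)
  ok <- grepl("^%%MatrixMarket +matrix +coordinate +(integer|real) +general",
              header)
  if (!ok) {
    stop("not a general coordinate integer/real MatrixMarket file: ", header)
  }
  m <- Matrix::readMM(matrix_path)
  if (any(m@x < 0)) stop("negative entries in count matrix")
  if (any(m@x != round(m@x))) stop("non-integral entries in count matrix")
  genes <- read.delim(genes_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1L]]
  barcodes <- read.delim(barcodes_path, header = FALSE,
                         stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(m)) {
    stop("gene file has ", length(genes), " entries but matrix has ",
         nrow(m), " rows")
  }
  if (length(barcodes) != ncol(m)) {
    stop("barcode file has ", length(barcodes), " entries but matrix has ",
         ncol(m), " columns")
  }
  if (anyDuplicated(genes)) stop("duplicate gene IDs")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write a count matrix as a MatrixMarket bundle
#'
#' Writes `matrix.mtx`, `genes.tsv` and `barcodes.tsv` into `out_dir`.
#' Entries are emitted in deterministic row-major order.
#'
#' @param counts Sparse or dense genes x cells matrix with dimnames.
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_mtx_bundle <- function(counts, out_dir) {
  counts <- as_count_matrix(counts)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             genes = file.path(out_dir, "genes.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"))
  trip <- Matrix::summary(counts)
  ord <- order(trip$i, trip$j)
  con <- file(paths["matrix"], "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(counts), ncol(counts), nrow(trip))), con)
  if (nrow(trip) > 0) {
    writeLines(paste(trip$i[ord], trip$j[ord],
                     format(trip$x[ord], scientific = FALSE, trim = TRUE)),
               con)
  }
  writeLines(rownames(counts), paths["genes"])
  writeLines(colnames(counts), paths["barcodes"])
  invisible(paths)
}

# Validate/coerce a genes x cells count matrix to labeled dgCMatrix.
as_count_matrix <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene rownames and barcode colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene IDs")
  m <- methods::as(methods::as(methods::as(
    counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0)) stop("negative entries in count matrix")
  if (any(m@x != round(m@x))) stop("non-integral entries in count matrix")
  m
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene order is
#' preserved; duplicate genes within a set are dropped with a warning;
#' duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character gene vectors, with per-set descriptions
#'   in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stop("GMT line ", which(bad)[1L], " has fewer than 3 fields")
  }
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name: ", nms[duplicated(nms)][1L])
  }
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes within set '", f[[1L]], "' dropped")
      genes <- genes[!duplicated(genes)]
    }
    genes
  })
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), nms)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character gene vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to set names.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a typed TSV table
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Named character vector mapping required column names to R
#'   types (`"character"`, `"integer"`, `"double"`, `"logical"`). Columns not
#'   named in the schema are read as-is.
#' @return A data.frame with typed columns.
#' @export
read_table_typed <- function(path, schema = NULL) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(schema)) {
    missing_cols <- setdiff(names(schema), names(df))
    if (length(missing_cols)) {
      stop("missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    for (col in names(schema)) {
      v <- df[[col]]
      coerced <- switch(schema[[col]],
        character = as.character(v),
        integer = suppressWarnings(as.integer(v)),
        double = suppressWarnings(as.double(v)),
        logical = as.logical(v),
        stop("unknown schema type: ", schema[[col]]))
      if (schema[[col]] %in% c("integer", "double") &&
          anyNA(coerced) && !anyNA(v)) {
        stop("column '", col, "' cannot be coerced to ", schema[[col]])
      }
      df[[col]] <- coerced
    }
  }
  df
}

#' Write a table as TSV
#'
#' Floating-point columns are serialized with 17 significant digits so that
#' write/read round-trips are value-stable.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table_typed <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
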