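# Cohort container and the delimited-text input/output schema.
# Inputs are three UTF-8 CSV files with mandatory header rows:
#   covariates: sample_id, cov1..covd   (numeric)
#   phenotype:  sample_id, y            (0/1)
#   snps:       sample_id, snp1..snpk   (0/1/2 minor-allele counts)
# Results are written as tab-separated text plus a JSON sidecar with the
# depth report and config echo.

#' Construct a cohort container
#'
#' Standardizes the raw covariates (mean 0, sd 1) and prepends the intercept
#' column; genotypes stay on the 0/1/2 scale.
#'
#' @param Z Raw covariate matrix (n x d).
#' @param y Binary phenotype vector.
#' @param S Genotype matrix (n x k).
#' @param sample_id Optional sample identifiers.
#' @param spec Optional [cohort_spec()] echo.
#' @return A list of class `cohort_data` with elements `Z`, `X`
#'   (standardized design, intercept first), `y`, `S`.
#' @export
new_cohort_data <- function(Z, y, S, sample_id = NULL, spec = NULL) {
  Z <- as.matrix(Z)
  S <- as.matrix(S)
  n <- nrow(Z)
  stopifnot(length(y) == n, nrow(S) == n)
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate cohort: covariate ", which(sds == 0)[1],
         " is constant and cannot be standardized", call. = FALSE)
  }
  X <- cbind(intercept = 1, scale(Z))
  colnames(X) <- c("intercept", colnames(Z))
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  structure(list(Z = Z, X = X, y = as.numeric(y), S = S,
                 sample_id = as.character(sample_id), spec = spec),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("cohort_data: %d samples, %d covariates, %d SNPs, %.1f%% cases\n",
              nrow(x$X), ncol(x$X) - 1L, ncol(x$S), 100 * mean(x$y)))
  invisible(x)
}

read_numeric_table <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop(what, " file ", path, " lacks a sample_id column", call. = FALSE)
  }
  vals <- df[setdiff(names(df), "sample_id")]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad)) {
      stop(sprintf("%s file %s: non-numeric value '%s' at row %d, column '%s'",
                   what, path, vals[[j]][bad[1]], bad[1], names(vals)[j]),
           call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("%s file %s: missing value at row %d, column '%s'",
                   what, path, which(is.na(v))[1], names(vals)[j]),
           call. = FALSE)
    }
    vals[[j]] <- v
  }
  list(sample_id = as.character(df$sample_id),
       values = as.matrix(vals))
}

#' Read a cohort from delimited text
#'
#' Validates sample counts across the three files, phenotype coding and the
#' 0/1/2 genotype range (errors name the offending row and column), then
#' standardizes the covariates and adds the intercept.
#'
#' @param covariates_path,phenotype_path,snp_path CSV paths (see the schema
#'   in the package description).
#' @return A `cohort_data` object.
#' @export
read_cohort <- function(covariates_path, phenotype_path, snp_path) {
  cov <- read_numeric_table(covariates_path, "covariates")
  phe <- read_numeric_table(phenotype_path, "phenotype")
  snp <- read_numeric_table(snp_path, "snps")
  n <- length(cov$sample_id)
  if (length(phe$sample_id) != n || length(snp$sample_id) != n) {
    stop(sprintf(
      "row-count mismatch: %d covariate rows, %d phenotype rows, %d snp rows",
      n, length(phe$sample_id), length(snp$sample_id)), call. = FALSE)
  }
  if (!identical(cov$sample_id, phe$sample_id) ||
      !identical(cov$sample_id, snp$sample_id)) {
    stop("sample_id columns do not agree across the input files",
         call. = FALSE)
  }
  y <- phe$values[, 1]
  if (!all(y %in% c(0, 1))) {
    bad <- which(!y %in% c(0, 1))[1]
    stop(sprintf("phenotype must be 0/1; found %s at row %d", y[bad], bad),
         call. = FALSE)
  }
  S <- snp$values
  bad <- which(!S %in% c(0, 1, 2))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(S)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(S)) + 1L
    stop(sprintf("genotype must be 0/1/2; found %s at row %d, column '%s'",
                 S[i, j], i, colnames(S)[j]), call. = FALSE)
  }
  new_cohort_data(cov$values, y, S, sample_id = cov$sample_id)
}

#' Write a cohort in the input CSV schema
#'
#' Writes `covariates.csv`, `phenotype.csv` and `snps.csv` (raw covariates;
#' [read_cohort()] re-standardizes), plus `spec.json` when the cohort
#' carries a generator spec.
#'
#' @param cohort A `cohort_data`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(m, name) {
    utils::write.csv(
      data.frame(sample_id = cohort$sample_id, m, check.names = FALSE),
      file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  w(cohort$Z, "covariates.csv")
  utils::write.csv(data.frame(sample_id = cohort$sample_id, y = cohort$y),
                   file.path(dir, "phenotype.csv"),
                   row.names = FALSE, quote = FALSE)
  w(cohort$S, "snps.csv")
  if (!is.null(cohort$spec)) {
    jsonlite::write_json(unclass(cohort$spec),
                         file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Write GWAS results as tab-separated text
#'
#' One row per SNP (snp_id, numerator, denominator, beta, err, batch_index)
#' plus, for full pipeline results, a JSON sidecar with the depth report and
#' config echo.
#'
#' @param result A `gwas_result` or a data frame in the result schema.
#' @param path Output TSV path.
#' @param sidecar Optional sidecar path (default: `path` with a `.json`
#'   extension) used when `result` is a `gwas_result`.
#' @return `path`, invisibly.
#' @export
write_gwas_results <- function(result, path,
                               sidecar = paste0(path, ".json")) {
  tab <- if (inherits(result, "gwas_result")) result$table else result
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (inherits(result, "gwas_result")) {
    jsonlite::write_json(
      list(depth = unclass(result$depth),
           config = unclass(result$config),
           params = unclass(result$params),
           batches = result$batches),
      sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a GWAS result table
#'
#' @param path A TSV written by [write_gwas_results()].
#' @return A data frame.
#' @export
read_gwas_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
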