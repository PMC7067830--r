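#' Protein-by-sample matrix with cohort labels
#'
#' Lightweight container used throughout the pipeline: a numeric matrix of
#' protein quantities (rows = proteins, columns = samples) together with the
#' sample-to-cohort assignment. Two scales exist: `"intensity"` (nonnegative
#' raw or TIC-normalized spectral intensities) and `"log2"` (log2-transformed
#' expression). Missing values are `NA`; zeros in intensity data are treated
#' as non-detections and coerced to `NA` at load time.
#'
#' @param values Numeric matrix with unique rownames (protein identifiers)
#'   and unique colnames (sample identifiers).
#' @param cohorts Character or factor vector of cohort labels, either named
#'   by sample identifier or in column order.
#' @param scale `"intensity"` or `"log2"`.
#' @return An object of class `protein_matrix`: a list with elements
#'   `values`, `cohorts` (named factor) and `scale`.
#' @examples
#' m <- matrix(2^rnorm(12, 20), 2, 6,
#'             dimnames = list(c("P1", "P2"), paste0("s", 1:6)))
#' pm <- protein_matrix(m, rep(c("Ctrl", "MI", "MI+CP"), each = 2))
#' dim(pm)
#' @export
protein_matrix <- function(values, cohorts, scale = c("intensity", "log2")) {
  scale <- match.arg(scale)
  stop_if(!is.matrix(values) || !is.numeric(values),
          "'values' must be a numeric matrix")
  stop_if(is.null(rownames(values)) || is.null(colnames(values)),
          "'values' must have protein rownames and sample colnames")
  stop_if(anyDuplicated(rownames(values)) > 0, "duplicate protein identifiers")
  stop_if(anyDuplicated(colnames(values)) > 0, "duplicate sample identifiers")
  if (is.null(names(cohorts))) {
    stop_if(length(cohorts) != ncol(values),
            "'cohorts' length must match the number of samples")
    names(cohorts) <- colnames(values)
  }
  stop_if(!all(colnames(values) %in% names(cohorts)),
          "every sample must map to a cohort")
  cohorts <- factor(as.character(cohorts[colnames(values)]))
  stop_if(anyNA(cohorts), "every sample must map to exactly one cohort")
  if (scale == "intensity") {
    stop_if(any(values < 0, na.rm = TRUE), "intensities must be >= 0")
  } else {
    stop_if(any(!is.finite(values) & !is.na(values)),
            "log2 values must be finite where not missing")
  }
  structure(list(values = values, cohorts = cohorts, scale = scale),
            class = "protein_matrix")
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix (%s scale): %d proteins x %d samples\n",
              x$scale, nrow(x$values), ncol(x$values)))
  cat("cohorts:",
      paste(sprintf("%s (n=%d)", levels(x$cohorts), table(x$cohorts)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a sample-to-cohort map
#'
#' Two-column tab-separated file `sample_id<TAB>cohort`, one row per sample.
#' The mapping is always supplied explicitly, never inferred from sample
#' names.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: cohort labels named by sample identifier.
#' @export
read_cohort_map <- function(path) {
  stop_if(!file.exists(path), "cohort map not found: ", path)
  d <- utils::read.delim(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  stop_if(ncol(d) < 2, "cohort map must have two columns (sample, cohort)")
  stop_if(anyDuplicated(d[[1]]) > 0, "duplicate sample in cohort map")
  stats::setNames(d[[2]], d[[1]])
}

#' Read a protein intensity matrix
#'
#' Supports a plain wide TSV (first column protein identifiers, one column
#' per sample) and the MaxQuant proteinGroups dialect, from which the
#' `LFQ intensity <sample>` columns are extracted and rows flagged `+` in
#' `Reverse` or `Potential contaminant` are dropped. Zero intensities are
#' non-detections and become missing (`NA`).
#'
#' @param path Path to the intensity table.
#' @param cohorts Named cohort vector (see [read_cohort_map()]) or a path to
#'   a cohort-map TSV.
#' @param dialect `"plain_tsv"` or `"maxquant_proteingroups"`.
#' @return A `protein_matrix` on the intensity scale.
#' @export
read_intensity_matrix <- function(path, cohorts,
                                  dialect = c("plain_tsv",
                                              "maxquant_proteingroups")) {
  dialect <- match.arg(dialect)
  stop_if(!file.exists(path), "intensity file not found: ", path)
  if (is.character(cohorts) && length(cohorts) == 1 && file.exists(cohorts))
    cohorts <- read_cohort_map(cohorts)
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (dialect == "plain_tsv") {
    ids <- as.character(d[[1]])
    vals <- as.matrix(d[, -1, drop = FALSE])
  } else {
    id_col <- intersect(c("Protein IDs", "Majority protein IDs", "id"),
                        names(d))
    stop_if(length(id_col) == 0, "no protein identifier column found")
    keep <- rep(TRUE, nrow(d))
    for (flag in c("Reverse", "Potential contaminant")) {
      if (flag %in% names(d))  # empty flag columns read as NA
        keep <- keep & (is.na(d[[flag]]) | d[[flag]] != "+")
    }
    lfq <- grep("^LFQ intensity ", names(d), value = TRUE)
    stop_if(length(lfq) == 0, "no 'LFQ intensity ' columns found")
    d <- d[keep, , drop = FALSE]
    ids <- as.character(d[[id_col[1]]])
    vals <- as.matrix(d[, lfq, drop = FALSE])
    colnames(vals) <- sub("^LFQ intensity ", "", lfq)
  }
  stop_if(anyDuplicated(ids) > 0, "duplicate protein identifiers in ", path)
  storage.mode(vals) <- "double"
  stop_if(any(vals < 0, na.rm = TRUE), "negative intensities in ", path)
  vals[!is.na(vals) & vals == 0] <- NA_real_
  rownames(vals) <- ids
  protein_matrix(vals, cohorts, scale = "intensity")
}

#' Write a protein matrix as wide TSV
#'
#' First column `protein_id`, one column per sample; missing cells are
#' written empty. Round-trips losslessly through
#' [read_intensity_matrix()] for intensity-scale matrices.
#'
#' @param m A `protein_matrix`.
#' @param path Output path.
#' @export
write_protein_matrix <- function(m, path) {
  d <- data.frame(protein_id = rownames(m$values), m$values,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Total-ion-current normalization
#'
#' Scales every sample so its summed intensity equals the grand mean of the
#' per-sample sums, removing loading and instrument-drift differences. The
#' grand-mean target (rather than a fixed constant) preserves the overall
#' scale of the matrix. Missing cells stay missing. Idempotent.
#'
#' @param m A `protein_matrix` on the intensity scale.
#' @return A `protein_matrix` with equal per-sample total intensity.
#' @export
normalize_tic <- function(m) {
  stopifnot(inherits(m, "protein_matrix"))
  stop_if(m$scale != "intensity", "normalize_tic expects intensity scale")
  sums <- colSums(m$values, na.rm = TRUE)
  stop_if(any(sums == 0), "sample with no non-missing values: ",
          paste(colnames(m$values)[sums == 0], collapse = ", "))
  fac <- mean(sums) / sums
  m$values <- sweep(m$values, 2, fac, `*`)
  m
}

#' Log2-transform an intensity matrix
#'
#' @param m A `protein_matrix` on the intensity scale; values must be
#'   positive where not missing.
#' @return A `protein_matrix` on the log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "protein_matrix"))
  stop_if(any(m$values <= 0, na.rm = TRUE),
          "nonpositive intensities cannot be log2-transformed")
  m$values <- log2(m$values)
  m$scale <- "log2"
  m
}

#' Filter proteins by per-cohort detection
#'
#' Retains proteins with at least `min_valid_per_cohort` non-missing values
#' in every cohort; the default of 2 is the minimum for a variance estimate.
#' Dropped identifiers are attached as attribute `"dropped"`.
#'
#' @param m A `protein_matrix`.
#' @param min_valid_per_cohort Minimum non-missing values required per
#'   cohort.
#' @return The filtered `protein_matrix` with attribute `dropped`.
#' @export
filter_by_detection <- function(m, min_valid_per_cohort = 2) {
  stopifnot(inherits(m, "protein_matrix"))
  stop_if(min_valid_per_cohort > min(table(m$cohorts)),
          "min_valid_per_cohort exceeds the smallest cohort size")
  ok <- rep(TRUE, nrow(m$values))
  for (g in levels(m$cohorts)) {
    cols <- m$cohorts == g
    ok <- ok & rowSums(!is.na(m$values[, cols, drop = FALSE])) >=
      min_valid_per_cohort
  }
  dropped <- rownames(m$values)[!ok]
  m$values <- m$values[ok, , drop = FALSE]
  attr(m, "dropped") <- dropped
  m
}

#' Row-wise z-scores
#'
#' Standardizes each protein across its non-missing samples to mean 0 and
#' sample standard deviation 1, as used for heatmap display. Constant rows
#' (zero variance) are emitted as all-zero with a warning.
#'
#' @param m A `protein_matrix` on the log2 scale.
#' @return Numeric matrix of z-scores, same dimnames as `m$values`.
#' @export
zscore_rows <- function(m) {
  stopifnot(inherits(m, "protein_matrix"))
  v <- m$values
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1, stats::sd, na.rm = TRUE)
  const <- !is.na(sdv) & sdv == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) emitted as all-zero")
    sdv[const] <- 1
  }
  z <- (v - mu) / sdv
  z[const, ] <- ifelse(is.na(v[const, , drop = FALSE]), NA_real_, 0)
  z
}
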