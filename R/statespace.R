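#' Squared Euclidean distance between cohort proteome states
#'
#' Sum over a differential-expression universe of the squared difference of
#' cohort mean log2 expression — the squared length of the pairwise log2
#' fold-change vector. Proteins with no usable value in either cohort are
#' skipped and reported in attribute `"skipped"`.
#'
#' @param m A `protein_matrix` on the log2 scale.
#' @param cohort_a,cohort_b Cohort labels.
#' @param de_universe Character vector of protein identifiers to sum over;
#'   conventionally the union of proteins significant in any pairwise
#'   contrast.
#' @return Nonnegative numeric distance with attribute `skipped`.
#' @export
squared_distance <- function(m, cohort_a, cohort_b, de_universe) {
  stopifnot(inherits(m, "protein_matrix"))
  stop_if(length(de_universe) == 0, "empty differential-expression universe")
  lv <- levels(m$cohorts)
  stop_if(!cohort_a %in% lv, "unknown cohort label: ", cohort_a)
  stop_if(!cohort_b %in% lv, "unknown cohort label: ", cohort_b)
  rows <- intersect(de_universe, rownames(m$values))
  va <- m$values[rows, m$cohorts == cohort_a, drop = FALSE]
  vb <- m$values[rows, m$cohorts == cohort_b, drop = FALSE]
  ok <- rowSums(!is.na(va)) >= 1 & rowSums(!is.na(vb)) >= 1
  skipped <- union(setdiff(de_universe, rows), rows[!ok])
  stop_if(sum(ok) == 0, "no usable proteins in the universe")
  diffs <- rowMeans(vb[ok, , drop = FALSE], na.rm = TRUE) -
    rowMeans(va[ok, , drop = FALSE], na.rm = TRUE)
  structure(sum(diffs^2), skipped = skipped)
}

#' Displacement percentages from three cohort distances
#'
#' Given the squared distances control-to-disease, control-to-treated and
#' disease-to-treated, reports the residual displacement — how far the
#' treated cohort still lies from control, as a percentage of the
#' disease-induced displacement — and the returned displacement — how far
#' along the path back toward the pre-disease state the treated cohort has
#' moved, `100 * d_mi_micp / (d_ctrl_micp + d_mi_micp)`. Both are
#' scale-invariant and reported as integers (half-up).
#'
#' @param d_ctrl_mi Squared distance, control vs disease (must be > 0).
#' @param d_ctrl_micp Squared distance, control vs treated.
#' @param d_mi_micp Squared distance, disease vs treated.
#' @return A list with the three distances, `residual_pct` and
#'   `returned_pct`.
#' @export
displacement_summary <- function(d_ctrl_mi, d_ctrl_micp, d_mi_micp) {
  stop_if(any(c(d_ctrl_mi, d_ctrl_micp, d_mi_micp) < 0),
          "distances must be nonnegative")
  stop_if(d_ctrl_mi <= 0, "zero disease displacement")
  residual <- 100 * d_ctrl_micp / d_ctrl_mi
  returned <- if (d_ctrl_micp + d_mi_micp > 0)
    100 * d_mi_micp / (d_ctrl_micp + d_mi_micp) else NA_real_
  list(d_ctrl_mi = d_ctrl_mi, d_ctrl_micp = d_ctrl_micp,
       d_mi_micp = d_mi_micp,
       residual_pct = round_half_up(residual),
       returned_pct = round_half_up(returned))
}

#' PCA of cohort samples over a differential-expression universe
#'
#' Projects samples on the principal components of the protein-centered
#' log2 matrix restricted to the given universe (rows with any missing
#' value are dropped). Component signs are fixed by making each
#' component's largest-magnitude protein loading positive, so results are
#' reproducible across platforms.
#'
#' @param m A `protein_matrix` on the log2 scale with >= 3 samples.
#' @param de_universe Character vector of protein identifiers.
#' @param n_components Number of leading components to report (default 3).
#' @return A list: `coordinates` (data frame `sample`, `cohort`, `PC1..`),
#'   `variance_explained` (fractions, nonincreasing), `n_proteins_used`,
#'   and `degenerate` (TRUE when total variance is zero).
#' @export
pca_cohorts <- function(m, de_universe, n_components = 3) {
  stopifnot(inherits(m, "protein_matrix"))
  stop_if(ncol(m$values) < 3, "need at least 3 samples for cohort PCA")
  stop_if(length(de_universe) == 0, "empty differential-expression universe")
  rows <- intersect(de_universe, rownames(m$values))
  x <- m$values[rows, , drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  stop_if(nrow(x) == 0, "no complete proteins in the universe")
  if (sum(apply(x, 1, stats::var)) == 0) {
    k <- min(n_components, ncol(x))
    coords <- matrix(0, ncol(x), k,
                     dimnames = list(colnames(x), paste0("PC", seq_len(k))))
    return(list(coordinates = data.frame(sample = colnames(x),
                                         cohort = as.character(m$cohorts),
                                         coords, stringsAsFactors = FALSE),
                variance_explained = rep(0, k),
                n_proteins_used = nrow(x), degenerate = TRUE))
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(coordinates = data.frame(sample = colnames(x),
                                cohort = as.character(m$cohorts),
                                coords, stringsAsFactors = FALSE),
       variance_explained = ve,
       n_proteins_used = nrow(x), degenerate = FALSE)
}

#' Default differential-expression universe
#'
#' Union of proteins significant in any of the supplied contrast tables.
#'
#' @param ... Contrast tables with significance calls.
#' @return Character vector of protein identifiers.
#' @export
de_universe <- function(...) {
  tabs <- list(...)
  unique(unlist(lapply(tabs, function(t) t$protein_id[t$significant])))
}
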