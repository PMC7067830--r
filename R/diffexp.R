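#' Significance thresholds for differential expression
#'
#' The pipeline calls a protein differentially expressed in a contrast when
#' it clears both a minimum fold change and a raw p-value cutoff; the
#' defaults are a two-fold change and p < 0.01. No multiple-testing
#' correction is applied across proteins (the reported calls use raw p).
#'
#' @param min_fold_change Minimum linear fold change (> 1); the gate on the
#'   log2 scale is `|log2fc| >= log2(min_fold_change)`, boundary inclusive.
#' @param alpha Raw p-value cutoff, exclusive (`p < alpha`).
#' @return A `de_thresholds` list.
#' @export
de_thresholds <- function(min_fold_change = 2, alpha = 0.01) {
  stop_if(!is.finite(min_fold_change) || min_fold_change <= 1,
          "min_fold_change must be a finite ratio > 1")
  stop_if(!is.finite(alpha) || alpha <= 0 || alpha >= 1,
          "alpha must be in (0, 1)")
  structure(list(min_fold_change = min_fold_change, alpha = alpha),
            class = "de_thresholds")
}

#' Per-protein pairwise cohort contrast
#'
#' For each protein, computes the log2 fold change as the difference of
#' cohort mean log2 expression (comparison minus reference) and a two-sided
#' p-value from a t statistic. The cohort comparisons mirror a per-protein
#' one-factor Gaussian linear model: with `variance_mode = "pooled3"` (the
#' default) the residual variance is pooled across all cohorts present in
#' the matrix, as a one-factor ANOVA fit to all groups would use;
#' `"pairwise"` pools over the two contrasted cohorts only.
#'
#' Proteins with fewer than two non-missing values in either contrasted
#' cohort are untestable: they are reported with `NA` fold change and
#' p-value and are never significant.
#'
#' @param m A `protein_matrix` on the log2 scale.
#' @param cohort_a Reference cohort label.
#' @param cohort_b Comparison cohort label; `log2fc = mean(b) - mean(a)`.
#' @param variance_mode `"pooled3"` or `"pairwise"`.
#' @param thresholds A [de_thresholds()] object used to flag significance.
#' @return A `contrast_table` data frame with columns `protein_id`,
#'   `log2fc`, `p_value`, `significant`, `direction`, `n_a`, `n_b`, and
#'   attributes `contrast` (label `"b_vs_a"`) and `thresholds`.
#' @export
fit_contrast <- function(m, cohort_a, cohort_b,
                         variance_mode = c("pooled3", "pairwise"),
                         thresholds = de_thresholds()) {
  stopifnot(inherits(m, "protein_matrix"))
  stop_if(m$scale != "log2", "fit_contrast expects log2 scale")
  variance_mode <- match.arg(variance_mode)
  lv <- levels(m$cohorts)
  stop_if(!cohort_a %in% lv, "unknown cohort label: ", cohort_a)
  stop_if(!cohort_b %in% lv, "unknown cohort label: ", cohort_b)

  v <- m$values
  group_stats <- function(g) {
    x <- v[, m$cohorts == g, drop = FALSE]
    n <- rowSums(!is.na(x))
    mu <- rowMeans(x, na.rm = TRUE)
    ss <- rowSums((x - mu)^2, na.rm = TRUE)  # within-group sum of squares
    list(n = n, mu = mu, ss = ss)
  }
  sa <- group_stats(cohort_a)
  sb <- group_stats(cohort_b)
  lfc <- sb$mu - sa$mu

  if (variance_mode == "pairwise") {
    ss <- sa$ss + sb$ss
    df <- pmax(sa$n - 1, 0) + pmax(sb$n - 1, 0)
  } else {
    ss <- 0
    df <- 0
    for (g in lv) {
      sg <- if (g == cohort_a) sa else if (g == cohort_b) sb else
        group_stats(g)
      use <- sg$n >= 2  # cohorts with one value contribute nothing
      ss <- ss + ifelse(use, sg$ss, 0)
      df <- df + ifelse(use, sg$n - 1, 0)
    }
  }
  testable <- sa$n >= 2 & sb$n >= 2 & df >= 1
  s2 <- ifelse(df > 0, ss / df, NA_real_)
  se <- sqrt(s2 * (1 / sa$n + 1 / sb$n))
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate residual variance: identical values give p = 1 at zero
  # difference, p = 0 otherwise
  zero_var <- testable & !is.na(s2) & s2 == 0
  p[zero_var] <- ifelse(lfc[zero_var] == 0, 1, 0)
  p[!testable] <- NA_real_
  lfc[!testable] <- NA_real_

  out <- data.frame(protein_id = rownames(v), log2fc = lfc, p_value = p,
                    significant = FALSE,
                    direction = "none",
                    n_a = sa$n, n_b = sb$n,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- call_significance(out, thresholds)
  attr(out, "contrast") <- paste0(cohort_b, "_vs_", cohort_a)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Apply significance thresholds to a contrast table
#'
#' Sets `significant` and `direction` from the fold-change and p-value
#' gates: significant iff `|log2fc| >= log2(min_fold_change)` and
#' `p < alpha`; direction is the sign of the fold change for significant
#' proteins and `"none"` otherwise. Untestable proteins (`NA` p-value) are
#' never significant.
#'
#' @param tab A contrast table (from [fit_contrast()] or constructed).
#' @param thresholds A [de_thresholds()] object.
#' @return The table with `significant` and `direction` recomputed;
#'   thresholds recorded in attribute `thresholds`.
#' @export
call_significance <- function(tab, thresholds = de_thresholds()) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  gate <- log2(thresholds$min_fold_change)
  sig <- !is.na(tab$p_value) & !is.na(tab$log2fc) &
    abs(tab$log2fc) >= gate & tab$p_value < thresholds$alpha
  tab$significant <- sig
  tab$direction <- ifelse(sig & tab$log2fc > 0, "up",
                          ifelse(sig & tab$log2fc < 0, "down", "none"))
  attr(tab, "thresholds") <- thresholds
  tab
}

#' Summarize alteration counts for a contrast
#'
#' @param tab A contrast table with significance calls.
#' @param n_total Size of the quantified proteome used as the percentage
#'   denominator (defaults to the number of proteins in `tab`).
#' @return A list with counts `n_up`, `n_down`, `n_altered` and percentages
#'   of `n_total` (one decimal, half-up).
#' @export
summarize_alterations <- function(tab, n_total = nrow(tab)) {
  stop_if(n_total <= 0, "n_total must be positive")
  stop_if(n_total < nrow(tab), "n_total smaller than the table")
  n_up <- sum(tab$direction == "up")
  n_down <- sum(tab$direction == "down")
  n_alt <- n_up + n_down
  list(n_up = n_up, n_down = n_down, n_altered = n_alt, n_total = n_total,
       pct_up = round_half_up(100 * n_up / n_total, 1),
       pct_down = round_half_up(100 * n_down / n_total, 1),
       pct_altered = round_half_up(100 * n_alt / n_total, 1))
}

#' Write a contrast table as TSV
#'
#' @param tab A contrast table.
#' @param path Output path; the contrast label is written as a `#` header
#'   comment line.
#' @export
write_contrast_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# contrast: ", attr(tab, "contrast") %||% "unknown"),
             con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
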