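#' Classify therapy response of disease-altered proteins
#'
#' Every protein significantly altered in the disease-vs-control contrast is
#' assigned one reversal class from the movement of the treated cohort:
#'
#' * `FULL` — significant change in the treated-vs-disease contrast, in the
#'   direction opposite the disease change, such that the treated cohort no
#'   longer differs from control.
#' * `PARTIAL_A` — opposite-direction movement that does not reach
#'   significance versus disease, with the treated cohort not differing
#'   from control.
#' * `PARTIAL_B` — significant opposite-direction movement versus disease,
#'   but the treated cohort still differs significantly from control.
#' * `NONE` — everything else: same-direction movement, zero movement, or
#'   non-significant opposite movement that still differs from control.
#'
#' "Differs from control" uses the full significance rule (fold-change and
#' p-value gates), the same definition used for every other call in the
#' pipeline. A log2 fold change of exactly zero in the treated-vs-disease
#' contrast counts as not opposite.
#'
#' @param mi_vs_ctrl Contrast table, disease vs control.
#' @param micp_vs_mi Contrast table, treated vs disease.
#' @param micp_vs_ctrl Contrast table, treated vs control.
#' @return A `reversal_calls` data frame with one row per disease-altered
#'   protein: `protein_id`, `mi_direction`, `class`, and the six underlying
#'   fold-change/p-value pairs as evidence.
#' @export
classify_reversal <- function(mi_vs_ctrl, micp_vs_mi, micp_vs_ctrl) {
  ids <- mi_vs_ctrl$protein_id
  stop_if(!setequal(ids, micp_vs_mi$protein_id) ||
            !setequal(ids, micp_vs_ctrl$protein_id),
          "the three contrast tables must cover the same protein universe")
  t2 <- micp_vs_mi[match(ids, micp_vs_mi$protein_id), ]
  t3 <- micp_vs_ctrl[match(ids, micp_vs_ctrl$protein_id), ]

  altered <- mi_vs_ctrl$significant
  d <- ifelse(mi_vs_ctrl$direction == "up", 1, -1)
  lfc2 <- t2$log2fc
  opp <- !is.na(lfc2) & sign(lfc2) == -d & lfc2 != 0
  s2 <- t2$significant
  s3 <- t3$significant

  cls <- rep("NONE", length(ids))
  cls[opp & s2 & !s3] <- "FULL"
  cls[opp & !s2 & !s3] <- "PARTIAL_A"
  cls[opp & s2 & s3] <- "PARTIAL_B"

  out <- data.frame(
    protein_id = ids,
    mi_direction = mi_vs_ctrl$direction,
    class = cls,
    log2fc_mi_ctrl = mi_vs_ctrl$log2fc, p_mi_ctrl = mi_vs_ctrl$p_value,
    log2fc_micp_mi = lfc2, p_micp_mi = t2$p_value,
    log2fc_micp_ctrl = t3$log2fc, p_micp_ctrl = t3$p_value,
    stringsAsFactors = FALSE
  )[altered, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reversal_calls", "data.frame")
  out
}

#' Summarize reversal classes
#'
#' Counts and percentages (one decimal, half-up) of full, partial (types A
#' and B combined) and non-reversed proteins among all disease-altered
#' proteins, overall and stratified by the direction of the disease change.
#' "Responsive" proteins are those fully or partially reversed.
#'
#' @param calls A `reversal_calls` data frame from [classify_reversal()].
#' @return A list with `n_altered`, per-class counts and percentages,
#'   `n_responsive`/`pct_responsive`, and a `by_direction` data frame with
#'   the responsive percentage (integer, half-up) per disease direction.
#' @export
summarize_reversal <- function(calls) {
  stop_if(nrow(calls) == 0, "no reversal calls to summarize")
  n <- nrow(calls)
  n_full <- sum(calls$class == "FULL")
  n_pa <- sum(calls$class == "PARTIAL_A")
  n_pb <- sum(calls$class == "PARTIAL_B")
  n_partial <- n_pa + n_pb
  n_none <- sum(calls$class == "NONE")
  n_resp <- n_full + n_partial
  pct <- function(k) round_half_up(100 * k / n, 1)

  strata <- lapply(c(up = "up", down = "down"), function(dd) {
    sub <- calls[calls$mi_direction == dd, , drop = FALSE]
    k <- nrow(sub)
    r <- sum(sub$class != "NONE")
    data.frame(mi_direction = dd, n = k, n_responsive = r,
               pct_responsive = if (k > 0)
                 round_half_up(100 * r / k) else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(n_altered = n,
       n_full = n_full, pct_full = pct(n_full),
       n_partial = n_partial, pct_partial = pct(n_partial),
       n_partial_a = n_pa, n_partial_b = n_pb,
       n_none = n_none, pct_none = pct(n_none),
       n_responsive = n_resp, pct_responsive = pct(n_resp),
       by_direction = do.call(rbind, c(strata, make.row.names = FALSE)))
}

#' Write reversal calls as TSV
#'
#' @param calls A `reversal_calls` data frame.
#' @param path Output path.
#' @export
write_reversal_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
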