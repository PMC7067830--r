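#' Read a protein-to-category annotation
#'
#' Two-column TSV `protein_id<TAB>category`; each protein belongs to exactly
#' one functional class.
#'
#' @param path Path to the TSV file.
#' @return Named character vector of class labels, named by protein.
#' @export
read_category_annotation <- function(path) {
  stop_if(!file.exists(path), "category annotation not found: ", path)
  d <- utils::read.delim(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  stop_if(ncol(d) < 2, "category annotation needs two columns")
  stop_if(anyDuplicated(d[[1]]) > 0,
          "protein annotated with more than one category")
  stats::setNames(d[[2]], d[[1]])
}

#' Per-class impact of a contrast (Categorical Delta %)
#'
#' For every functional class, computes the fraction of its members
#' significantly changed in the given direction (Categorical Delta %,
#' radial displacement in the impact plots) and compares it against the
#' proteome-wide frequency (Total Delta %, the reference circle). A class
#' is overrepresented when its intra-class percentage strictly exceeds the
#' proteome-wide one; no statistical test is attached to this flag.
#' Proteins without an annotation are pooled into class `"unknown"`.
#'
#' @param tab A contrast table with significance calls; its protein set
#'   defines both the class sizes and the proteome denominator.
#' @param annotation Named character vector protein -> class (see
#'   [read_category_annotation()]).
#' @param direction `"up"` or `"down"`.
#' @return A `category_impact` data frame: `category`, `size`, `n_changed`,
#'   `categorical_delta_pct`, `total_delta_pct` (both one decimal,
#'   half-up), `overrepresented`; direction kept in attribute `direction`.
#' @export
categorical_impact <- function(tab, annotation, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stop_if(length(annotation) == 0, "empty category annotation")
  cls <- as.character(annotation[tab$protein_id])
  cls[is.na(cls)] <- "unknown"
  n_total <- nrow(tab)
  changed <- tab$direction == direction
  size <- table(cls)
  n_changed <- table(factor(cls, levels = names(size))[changed])
  total_pct <- 100 * sum(changed) / n_total
  out <- data.frame(
    category = names(size),
    size = as.integer(size),
    n_changed = as.integer(n_changed),
    categorical_delta_pct = round_half_up(
      100 * as.integer(n_changed) / as.integer(size), 1),
    total_delta_pct = round_half_up(total_pct, 1),
    stringsAsFactors = FALSE
  )
  # strict comparison on the unrounded frequencies
  out$overrepresented <- (as.integer(n_changed) / as.integer(size)) >
    (sum(changed) / n_total)
  out <- out[order(out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  class(out) <- c("category_impact", "data.frame")
  out
}

#' Remediation of disease-overrepresented classes after therapy
#'
#' Compares per-class changed-protein counts between the disease contrast
#' (disease vs control) and the treated contrast (treated vs control), for
#' one direction. A class is `reduced` when the treated count is strictly
#' smaller, `increased` when strictly larger, `unchanged` on ties. Among
#' classes overrepresented under disease, remediated = reduced.
#'
#' @param impact_disease `category_impact` for the disease contrast.
#' @param impact_treated `category_impact` for the treated contrast, same
#'   direction and class universe.
#' @return A list with the per-class `status` data frame, `n_remediated`,
#'   `n_overrepresented`, `pct_remediated` (integer, half-up) and
#'   `net_change` (treated total minus disease total, negative = net
#'   decrease).
#' @export
remediation_summary <- function(impact_disease, impact_treated) {
  stop_if(!setequal(impact_disease$category, impact_treated$category),
          "class universes differ between the two impact tables")
  trt <- impact_treated[match(impact_disease$category,
                              impact_treated$category), ]
  status <- ifelse(trt$n_changed < impact_disease$n_changed, "reduced",
                   ifelse(trt$n_changed > impact_disease$n_changed,
                          "increased", "unchanged"))
  over <- impact_disease$overrepresented
  n_rem <- sum(over & status == "reduced")
  n_over <- sum(over)
  per_class <- data.frame(category = impact_disease$category,
                          n_disease = impact_disease$n_changed,
                          n_treated = trt$n_changed,
                          overrepresented = over,
                          status = status,
                          remediated = over & status == "reduced",
                          stringsAsFactors = FALSE)
  list(per_class = per_class,
       n_remediated = n_rem,
       n_overrepresented = n_over,
       pct_remediated = if (n_over > 0)
         round_half_up(100 * n_rem / n_over) else NA_real_,
       net_change = sum(trt$n_changed) - sum(impact_disease$n_changed))
}

#' Combine up- and down-direction remediation summaries
#'
#' Pools overrepresented-class and remediated-class counts across the two
#' directions (a class can count once per direction).
#'
#' @param up,down Lists from [remediation_summary()] for the two
#'   directions.
#' @return A list with pooled `n_remediated`, `n_overrepresented` and
#'   `pct_remediated` (integer, half-up).
#' @export
combine_remediation <- function(up, down) {
  n_rem <- up$n_remediated + down$n_remediated
  n_over <- up$n_overrepresented + down$n_overrepresented
  list(n_remediated = n_rem, n_overrepresented = n_over,
       pct_remediated = if (n_over > 0)
         round_half_up(100 * n_rem / n_over) else NA_real_)
}
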