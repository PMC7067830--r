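#' Pipeline configuration
#'
#' Validates and normalizes a configuration for [run_pipeline()]. Can be
#' read from a YAML or JSON file via [read_pipeline_config()].
#'
#' @param matrix_path Wide intensity TSV (or MaxQuant proteinGroups file).
#' @param cohort_map_path Two-column sample-to-cohort TSV.
#' @param output_dir Directory for stage outputs (created if absent).
#' @param cohorts Character vector of length 3 naming the control, disease
#'   and treated cohorts, in that order.
#' @param dialect Input dialect, `"plain_tsv"` or
#'   `"maxquant_proteingroups"`.
#' @param category_path,term_path,regulator_path Optional annotation
#'   inputs.
#' @param min_fold_change,alpha Differential-expression gates.
#' @param enrichment_fdr BH q cutoff for term enrichment.
#' @param variance_mode `"pooled3"` or `"pairwise"`.
#' @param min_valid_per_cohort Detection filter.
#' @param seed Seed for any stochastic stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_path, cohort_map_path, output_dir,
                            cohorts = c("Ctrl", "MI", "MI+CP"),
                            dialect = "plain_tsv",
                            category_path = NULL, term_path = NULL,
                            regulator_path = NULL,
                            min_fold_change = 2, alpha = 0.01,
                            enrichment_fdr = 0.001,
                            variance_mode = "pooled3",
                            min_valid_per_cohort = 2, seed = 1L) {
  for (p in c(matrix_path, cohort_map_path, category_path, term_path,
              regulator_path)) {
    stop_if(!is.null(p) && !file.exists(p), "input file not found: ", p)
  }
  stop_if(length(cohorts) != 3, "exactly three cohort labels required")
  th <- de_thresholds(min_fold_change, alpha)  # validates gates
  structure(list(matrix_path = matrix_path,
                 cohort_map_path = cohort_map_path,
                 output_dir = output_dir, cohorts = cohorts,
                 dialect = dialect, category_path = category_path,
                 term_path = term_path, regulator_path = regulator_path,
                 thresholds = th, enrichment_fdr = enrichment_fdr,
                 variance_mode = variance_mode,
                 min_valid_per_cohort = min_valid_per_cohort,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; keys as in [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Sequences load, TIC normalization, log2 transform, detection filter,
#' the three pairwise contrasts, reversal classification, category impact
#' and remediation (when a category annotation is supplied), term
#' enrichment and regulator activation (when supplied), and state-space
#' PCA/displacement. Writes every stage table as TSV plus a
#' machine-readable `summary.json` and a timestamped `run.log` into the
#' output directory. Derived percentages in the summary are recomputed
#' from its own counts on every run.
#'
#' @param cfg A `pipeline_config` (or path to one).
#' @return The summary list, invisibly; all outputs on disk.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$output_dir, "run.log")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s: %s\n",
                format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg),
        file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ctrl <- cfg$cohorts[1]; dis <- cfg$cohorts[2]; trt <- cfg$cohorts[3]

  m <- stage("load", read_intensity_matrix(cfg$matrix_path,
                                           cfg$cohort_map_path,
                                           dialect = cfg$dialect))
  log_line("load", sprintf("%d proteins x %d samples", nrow(m$values),
                           ncol(m$values)))
  m <- stage("normalize", normalize_tic(m))
  em <- stage("log2", log2_transform(m))
  em <- stage("filter", filter_by_detection(em, cfg$min_valid_per_cohort))
  log_line("filter", sprintf("%d proteins retained, %d dropped",
                             nrow(em$values), length(attr(em, "dropped"))))

  fits <- stage("contrasts", list(
    mi_vs_ctrl = fit_contrast(em, ctrl, dis, cfg$variance_mode,
                              cfg$thresholds),
    micp_vs_mi = fit_contrast(em, dis, trt, cfg$variance_mode,
                              cfg$thresholds),
    micp_vs_ctrl = fit_contrast(em, ctrl, trt, cfg$variance_mode,
                                cfg$thresholds)))
  for (nm in names(fits))
    write_contrast_table(fits[[nm]],
                         file.path(cfg$output_dir,
                                   paste0("contrast_", nm, ".tsv")))
  n_total <- nrow(em$values)
  alt_dis <- summarize_alterations(fits$mi_vs_ctrl, n_total)
  alt_trt <- summarize_alterations(fits$micp_vs_ctrl, n_total)
  log_line("contrasts", sprintf("altered %d disease, %d treated",
                                alt_dis$n_altered, alt_trt$n_altered))

  calls <- stage("reversal", classify_reversal(fits$mi_vs_ctrl,
                                               fits$micp_vs_mi,
                                               fits$micp_vs_ctrl))
  write_reversal_calls(calls, file.path(cfg$output_dir,
                                        "reversal_calls.tsv"))
  rev_sum <- if (nrow(calls) > 0) summarize_reversal(calls) else NULL

  summary <- list(
    n_proteins = n_total,
    disease = alt_dis, treated = alt_trt,
    pct_eliminated = if (alt_dis$n_altered > 0) round_half_up(
      100 * (alt_dis$n_altered - alt_trt$n_altered) / alt_dis$n_altered)
      else NA_real_,
    reversal = if (!is.null(rev_sum))
      rev_sum[setdiff(names(rev_sum), "by_direction")],
    reversal_by_direction = rev_sum$by_direction
  )

  if (!is.null(cfg$category_path)) {
    ann <- read_category_annotation(cfg$category_path)
    rem <- stage("categories", {
      imp <- lapply(c(up = "up", down = "down"), function(d) list(
        disease = categorical_impact(fits$mi_vs_ctrl, ann, d),
        treated = categorical_impact(fits$micp_vs_ctrl, ann, d)))
      for (d in names(imp)) {
        utils::write.table(imp[[d]]$disease,
                           file.path(cfg$output_dir,
                                     paste0("impact_disease_", d, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(imp[[d]]$treated,
                           file.path(cfg$output_dir,
                                     paste0("impact_treated_", d, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      list(up = remediation_summary(imp$up$disease, imp$up$treated),
           down = remediation_summary(imp$down$disease, imp$down$treated))
    })
    summary$remediation <- list(
      up = rem$up[c("n_remediated", "n_overrepresented", "net_change")],
      down = rem$down[c("n_remediated", "n_overrepresented", "net_change")],
      combined = combine_remediation(rem$up, rem$down))
    log_line("categories", sprintf("remediated %d of %d",
                                   summary$remediation$combined$n_remediated,
                                   summary$remediation$combined$n_overrepresented))
  }

  if (!is.null(cfg$term_path)) {
    enr <- stage("enrichment", {
      ann <- read_term_annotation(cfg$term_path)
      target <- calls$protein_id[calls$class != "NONE"]
      if (length(target) == 0) target <- calls$protein_id
      hypergeometric_enrichment(target, rownames(em$values), ann,
                                fdr_alpha = cfg$enrichment_fdr)
    })
    utils::write.table(enr, file.path(cfg$output_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_enriched_terms <- nrow(enr)
  }

  if (!is.null(cfg$regulator_path)) {
    zs <- stage("regulators", {
      net <- read_regulator_network(cfg$regulator_path)
      list(disease = regulator_activation_z(fits$mi_vs_ctrl, net),
           reversal = regulator_activation_z(fits$micp_vs_mi, net))
    })
    utils::write.table(zs$disease,
                       file.path(cfg$output_dir, "regulator_z_disease.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(zs$reversal,
                       file.path(cfg$output_dir, "regulator_z_reversal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_regulators_scored <- nrow(zs$disease)
  }

  ss <- stage("statespace", {
    uni <- de_universe(fits$mi_vs_ctrl, fits$micp_vs_mi, fits$micp_vs_ctrl)
    if (length(uni) == 0) NULL else {
      d1 <- squared_distance(em, ctrl, dis, uni)
      d2 <- squared_distance(em, ctrl, trt, uni)
      d3 <- squared_distance(em, dis, trt, uni)
      pca <- pca_cohorts(em, uni)
      utils::write.table(pca$coordinates,
                         file.path(cfg$output_dir, "pca_coordinates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(displacement = displacement_summary(as.numeric(d1),
                                               as.numeric(d2),
                                               as.numeric(d3)),
           pca_variance = pca$variance_explained)
    }
  })
  if (!is.null(ss)) summary$statespace <- ss

  jsonlite::write_json(summary,
                       file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  log_line("done", "summary.json written")
  invisible(summary)
}

#' Headline summary of the deterministic worked-example fixture
#'
#' Runs the summary stages (alteration counts, reversal taxonomy, category
#' impact and remediation) over [make_paper_fixture()] and returns the
#' headline numbers as a flat list; optionally writes them as JSON.
#'
#' @param path Optional path for a JSON copy of the summary.
#' @return Named list of headline counts and percentages.
#' @export
fixture_summary <- function(path = NULL) {
  fx <- make_paper_fixture()
  alt_dis <- summarize_alterations(fx$contrasts$mi_vs_ctrl, fx$n_proteins)
  alt_trt <- summarize_alterations(fx$contrasts$micp_vs_ctrl, fx$n_proteins)
  calls <- classify_reversal(fx$contrasts$mi_vs_ctrl,
                             fx$contrasts$micp_vs_mi,
                             fx$contrasts$micp_vs_ctrl)
  rs <- summarize_reversal(calls)
  imp <- lapply(c(up = "up", down = "down"), function(d) list(
    disease = categorical_impact(fx$contrasts$mi_vs_ctrl, fx$categories, d),
    treated = categorical_impact(fx$contrasts$micp_vs_ctrl, fx$categories,
                                 d)))
  rem <- combine_remediation(
    remediation_summary(imp$up$disease, imp$up$treated),
    remediation_summary(imp$down$disease, imp$down$treated))
  by_dir <- rs$by_direction
  out <- list(
    n_proteins = fx$n_proteins,
    altered = alt_dis$n_altered, pct_altered = alt_dis$pct_altered,
    n_up = alt_dis$n_up, n_down = alt_dis$n_down,
    treated_altered = alt_trt$n_altered,
    pct_treated_altered = alt_trt$pct_altered,
    treated_up = alt_trt$n_up, treated_down = alt_trt$n_down,
    pct_eliminated = round_half_up(
      100 * (alt_dis$n_altered - alt_trt$n_altered) / alt_dis$n_altered),
    n_full = rs$n_full, pct_full = rs$pct_full,
    n_partial = rs$n_partial, pct_partial = rs$pct_partial,
    n_none = rs$n_none, pct_none = rs$pct_none,
    n_responsive = rs$n_responsive, pct_responsive = rs$pct_responsive,
    pct_responsive_up = by_dir$pct_responsive[by_dir$mi_direction == "up"],
    pct_responsive_down = by_dir$pct_responsive[by_dir$mi_direction ==
                                                  "down"],
    total_delta_up = imp$up$disease$total_delta_pct[1],
    total_delta_down = imp$down$disease$total_delta_pct[1],
    n_remediated = rem$n_remediated,
    n_overrepresented = rem$n_overrepresented,
    pct_remediated = rem$pct_remediated)
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  out
}
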