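#' Simulation configuration for synthetic three-cohort studies
#'
#' Defines the study conditions the simulator emulates: three cohorts
#' (Ctrl, MI, MI+CP) of `n_per_group` replicates, log-normal protein
#' intensities (normal on the log2 scale), a planted fraction of
#' disease-altered proteins with directional log2 effects, planted reversal
#' classes for the therapy cohort, sparse detection dropout, and a
#' category partition. Defaults mirror a chronic-infarction cell-therapy
#' design: 4 replicates per cohort, ~10% of the proteome altered with the
#' observed up/down balance, two-fold (1 log2 unit) significance gates
#' cleared by a 2 log2-unit planted effect, reversal-class mix matching
#' the observed full/partial/none proportions, ~0.3% missingness, and 33
#' functional classes.
#'
#' @param n_proteins Number of proteins.
#' @param n_per_group Replicates per cohort (>= 2).
#' @param baseline_log2_mean_range Interval the per-protein baseline log2
#'   mean is drawn from (log2 intensity units).
#' @param replicate_sd Within-cohort replicate standard deviation, log2
#'   units.
#' @param frac_altered Fraction of proteins altered by disease.
#' @param frac_up_among_altered Fraction of altered proteins shifted up.
#' @param effect_size_log2 Disease effect magnitude, log2 units (> 0; >= 1
#'   to clear the two-fold gate, >= 2 recommended so the PARTIAL_B pattern
#'   is plantable).
#' @param reversal_fractions Named simplex over
#'   `FULL, PARTIAL_A, PARTIAL_B, NONE` (must sum to 1).
#' @param partial_pullback_fraction Fraction of the disease effect removed
#'   in the therapy cohort for PARTIAL_A proteins, in (0, 1).
#' @param dropout_rate Per-cell probability of a missing value.
#' @param n_categories Number of functional classes partitioning the
#'   proteome.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_proteins = 2000,
                       n_per_group = 4,
                       baseline_log2_mean_range = c(20, 30),
                       replicate_sd = 0.3,
                       frac_altered = 0.1,
                       frac_up_among_altered = 207 / 450,
                       effect_size_log2 = 2,
                       reversal_fractions = c(FULL = 64, PARTIAL_A = 222,
                                              PARTIAL_B = 6,
                                              NONE = 158) / 450,
                       partial_pullback_fraction = 0.6,
                       dropout_rate = 0.003,
                       n_categories = 33,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_per_group = as.integer(n_per_group),
              baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
              replicate_sd = as.numeric(replicate_sd),
              frac_altered = as.numeric(frac_altered),
              frac_up_among_altered = as.numeric(frac_up_among_altered),
              effect_size_log2 = as.numeric(effect_size_log2),
              reversal_fractions = reversal_fractions,
              partial_pullback_fraction = as.numeric(partial_pullback_fraction),
              dropout_rate = as.numeric(dropout_rate),
              n_categories = as.integer(n_categories),
              seed = as.integer(seed))
  stop_if(!all(vapply(cfg[-8], function(x) all(is.finite(x)), TRUE)),
          "non-finite configuration value")
  stop_if(cfg$n_per_group < 2, "n_per_group must be >= 2")
  stop_if(cfg$frac_altered < 0 || cfg$frac_altered > 1,
          "frac_altered must be in [0, 1]")
  stop_if(cfg$dropout_rate < 0 || cfg$dropout_rate > 1,
          "dropout_rate must be in [0, 1]")
  stop_if(cfg$effect_size_log2 <= 0, "effect_size_log2 must be > 0")
  stop_if(cfg$partial_pullback_fraction <= 0 ||
            cfg$partial_pullback_fraction >= 1,
          "partial_pullback_fraction must be in (0, 1)")
  rf <- cfg$reversal_fractions
  stop_if(!setequal(names(rf), c("FULL", "PARTIAL_A", "PARTIAL_B", "NONE")),
          "reversal_fractions must be named FULL/PARTIAL_A/PARTIAL_B/NONE")
  stop_if(!all(is.finite(rf)) || any(rf < 0) || abs(sum(rf) - 1) > 1e-9,
          "reversal_fractions must be a simplex summing to 1")
  stop_if(cfg$n_categories < 1, "n_categories must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# One pseudo-random stream per generator stage, derived from the single
# config seed by fixed offsets so stages are independently reproducible.
sim_seed <- function(cfg, stage_offset) {
  set.seed((cfg$seed + stage_offset) %% .Machine$integer.max)
}

#' Generate a synthetic cohort intensity matrix with planted ground truth
#'
#' Draws per-protein baseline log2 means uniformly over the configured
#' range, adds the planted disease effect (`+/- effect_size_log2`) to the
#' MI cohort mean for altered proteins, and sets the MI+CP cohort mean by
#' planted reversal class: equal to the Ctrl mean (`FULL`), pulled back by
#' `partial_pullback_fraction` of the effect (`PARTIAL_A`), pulled back by
#' half the effect so the protein differs from both Ctrl and MI
#' (`PARTIAL_B`), or equal to the MI mean (`NONE`). Replicates are normal
#' on the log2 scale with sd `replicate_sd`; intensities are `2^` the log2
#' values. Dropout masks cells uniformly at random as missing (never
#' zero).
#'
#' @param cfg A [sim_config()].
#' @return A list: `matrix` (a `protein_matrix`, intensity scale, cohorts
#'   Ctrl/MI/MI+CP) and `truth` (data frame `protein_id`,
#'   `planted_altered`, `planted_direction`, `planted_reversal`).
#' @export
generate_cohort_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  np <- cfg$n_proteins
  ng <- cfg$n_per_group
  ids <- sprintf("P%05d", seq_len(np))

  sim_seed(cfg, 0L)
  baseline <- stats::runif(np, cfg$baseline_log2_mean_range[1],
                           cfg$baseline_log2_mean_range[2])

  sim_seed(cfg, 1L)
  n_alt <- round(np * cfg$frac_altered)
  altered_idx <- if (n_alt > 0) sample.int(np, n_alt) else integer(0)
  n_up <- round(n_alt * cfg$frac_up_among_altered)
  dir_num <- integer(np)
  dir_num[altered_idx] <- c(rep(1L, n_up), rep(-1L, n_alt - n_up))

  sim_seed(cfg, 2L)
  classes <- c("FULL", "PARTIAL_A", "PARTIAL_B", "NONE")
  rev_class <- rep("not_applicable", np)
  if (n_alt > 0) {
    # deterministic proportional allocation, remainders by largest fraction
    quota <- cfg$reversal_fractions[classes] * n_alt
    n_cls <- floor(quota)
    rem <- n_alt - sum(n_cls)
    if (rem > 0) {
      extra <- order(quota - n_cls, decreasing = TRUE)[seq_len(rem)]
      n_cls[extra] <- n_cls[extra] + 1
    }
    rev_class[altered_idx] <- sample(rep(classes, times = n_cls))
  }

  eff <- cfg$effect_size_log2
  mu_ctrl <- baseline
  mu_mi <- baseline + dir_num * eff
  pullback <- ifelse(rev_class == "FULL", 1,
                     ifelse(rev_class == "PARTIAL_A",
                            cfg$partial_pullback_fraction,
                            ifelse(rev_class == "PARTIAL_B", 0.5, 0)))
  mu_micp <- mu_mi - dir_num * eff * pullback

  sim_seed(cfg, 3L)
  draw <- function(mu) matrix(stats::rnorm(np * ng, mean = mu,
                                           sd = cfg$replicate_sd), np, ng)
  log2_vals <- cbind(draw(mu_ctrl), draw(mu_mi), draw(mu_micp))

  sim_seed(cfg, 4L)
  if (cfg$dropout_rate > 0) {
    mask <- stats::runif(length(log2_vals)) < cfg$dropout_rate
    log2_vals[mask] <- NA_real_
  }

  samples <- c(paste0("Ctrl_", seq_len(ng)), paste0("MI_", seq_len(ng)),
               paste0("MICP_", seq_len(ng)))
  dimnames(log2_vals) <- list(ids, samples)
  cohorts <- rep(c("Ctrl", "MI", "MI+CP"), each = ng)
  m <- protein_matrix(2^log2_vals, cohorts, scale = "intensity")

  truth <- data.frame(protein_id = ids,
                      planted_altered = dir_num != 0L,
                      planted_direction = ifelse(dir_num > 0, "up",
                                                 ifelse(dir_num < 0, "down",
                                                        "none")),
                      planted_reversal = rev_class,
                      stringsAsFactors = FALSE)
  list(matrix = m, truth = truth)
}

#' Generate category and term annotations for a synthetic proteome
#'
#' Categories partition the proteome: each protein gets exactly one of
#' `n_categories` synthetic class labels (sizes as equal as the total
#' allows, membership randomized under the config seed). Term annotations
#' are overlapping sets; `n_enriched` of the `n_terms` terms are planted
#' enriched among disease-altered proteins by giving altered proteins
#' `enrichment_factor`-fold higher membership probability.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [generate_cohort_matrix()].
#' @param n_terms Number of annotation terms.
#' @param n_enriched Number of terms planted enriched in the altered set.
#' @param term_prob Baseline membership probability per (protein, term).
#' @param enrichment_factor Membership-probability multiplier for altered
#'   proteins in enriched terms.
#' @return A list: `categories` (named vector protein -> class), `terms`
#'   (data frame `protein_id`, `term_id`), `enriched_terms` (character).
#' @export
generate_annotations <- function(cfg, truth, n_terms = 40, n_enriched = 4,
                                 term_prob = 0.05, enrichment_factor = 5) {
  stopifnot(inherits(cfg, "sim_config"))
  stop_if(cfg$n_categories < 1, "n_categories must be >= 1")
  ids <- truth$protein_id
  np <- length(ids)

  sim_seed(cfg, 10L)
  cat_labels <- sprintf("C%02d", seq_len(cfg$n_categories))
  categories <- stats::setNames(
    sample(rep_len(cat_labels, np)), ids)

  sim_seed(cfg, 11L)
  term_ids <- sprintf("T%03d", seq_len(n_terms))
  enriched <- term_ids[seq_len(min(n_enriched, n_terms))]
  altered <- truth$planted_altered
  rows <- lapply(term_ids, function(tm) {
    p <- rep(term_prob, np)
    if (tm %in% enriched)
      p[altered] <- pmin(1, term_prob * enrichment_factor)
    member <- stats::runif(np) < p
    if (!any(member)) return(NULL)
    data.frame(protein_id = ids[member], term_id = tm,
               stringsAsFactors = FALSE)
  })
  list(categories = categories,
       terms = do.call(rbind, rows),
       enriched_terms = enriched)
}

#' Generate a signed regulator network with planted activation structure
#'
#' Creates `n_planted` regulators whose targets are drawn from the
#' disease-altered proteins with edge signs matching (activated regulators)
#' or opposing (inhibited regulators) the planted disease directions, so
#' that downstream activation z-scores recover the planted state, plus
#' `n_noise` regulators with random targets and signs.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [generate_cohort_matrix()].
#' @param n_planted Number of planted regulators (alternating
#'   activated/inhibited; at least one activated-by-disease).
#' @param n_noise Number of random-sign regulators.
#' @param targets_per_regulator Targets per regulator.
#' @return A list: `network` (data frame `regulator`, `target`, `sign`)
#'   and `planted` (data frame `regulator`, `state` in
#'   activated/inhibited).
#' @export
generate_regulator_network <- function(cfg, truth, n_planted = 6,
                                       n_noise = 4,
                                       targets_per_regulator = 12) {
  stopifnot(inherits(cfg, "sim_config"))
  altered <- truth[truth$planted_altered, , drop = FALSE]
  stop_if(nrow(altered) < targets_per_regulator,
          "not enough altered proteins for the requested target sets")
  sim_seed(cfg, 20L)
  dir_num <- ifelse(altered$planted_direction == "up", 1L, -1L)
  edges <- list()
  planted <- data.frame(regulator = character(0), state = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_planted)) {
    reg <- sprintf("REG_%02d", i)
    state <- if (i %% 2 == 1) "activated" else "inhibited"
    pick <- sample.int(nrow(altered), targets_per_regulator)
    sgn <- if (state == "activated") dir_num[pick] else -dir_num[pick]
    edges[[length(edges) + 1]] <-
      data.frame(regulator = reg, target = altered$protein_id[pick],
                 sign = as.integer(sgn), stringsAsFactors = FALSE)
    planted <- rbind(planted, data.frame(regulator = reg, state = state,
                                         stringsAsFactors = FALSE))
  }
  for (i in seq_len(n_noise)) {
    reg <- sprintf("NOISE_%02d", i)
    pick <- sample.int(nrow(truth), targets_per_regulator)
    edges[[length(edges) + 1]] <-
      data.frame(regulator = reg, target = truth$protein_id[pick],
                 sign = sample(c(-1L, 1L), targets_per_regulator,
                               replace = TRUE),
                 stringsAsFactors = FALSE)
  }
  list(network = do.call(rbind, edges), planted = planted)
}

#' Write a simulation configuration as YAML or JSON
#'
#' @param cfg A [sim_config()].
#' @param path Output path; format chosen by extension (`.json` gives
#'   JSON, anything else YAML).
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$reversal_fractions <- as.list(x$reversal_fractions)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}
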