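test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(n_proteins = 200, seed = 5)
  a <- generate_cohort_matrix(cfg)
  b <- generate_cohort_matrix(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  ann1 <- generate_annotations(cfg, a$truth)
  ann2 <- generate_annotations(cfg, a$truth)
  expect_identical(ann1$categories, ann2$categories)
  expect_identical(ann1$terms, ann2$terms)
})

test_that("null configuration plants nothing and no dropout means no NA", {
  cfg <- sim_config(n_proteins = 300, frac_altered = 0, dropout_rate = 0,
                    seed = 2)
  sim <- generate_cohort_matrix(cfg)
  expect_false(any(sim$truth$planted_altered))
  expect_true(all(sim$truth$planted_reversal == "not_applicable"))
  expect_false(anyNA(sim$matrix$values))
})

test_that("reversal truth applies only to altered proteins", {
  sim <- generate_cohort_matrix(sim_config(n_proteins = 500, seed = 3))
  with_class <- sim$truth$planted_reversal != "not_applicable"
  expect_identical(with_class, sim$truth$planted_altered)
})

test_that("config validation rejects broken inputs", {
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(frac_altered = 1.5), "frac_altered")
  expect_error(sim_config(effect_size_log2 = -1), "effect_size_log2")
  expect_error(sim_config(reversal_fractions = c(FULL = 0.5, PARTIAL_A = 0.3,
                                                 PARTIAL_B = 0.1,
                                                 NONE = 0.2)), "simplex")
  expect_error(sim_config(n_categories = 0), "n_categories")
})

test_that("planted effects are detected with high power at the design point", {
  # closed-form pooled-t power at d = 2/0.3, n = 4, alpha = 0.01 is ~1,
  # so nearly all planted-altered proteins must be called significant
  cfg <- sim_config(n_proteins = 2000, n_per_group = 4,
                    effect_size_log2 = 2, replicate_sd = 0.3,
                    frac_altered = 0.1, seed = 7)
  sim <- generate_cohort_matrix(cfg)
  em <- filter_by_detection(log2_transform(normalize_tic(sim$matrix)))
  tab <- fit_contrast(em, "Ctrl", "MI")
  truth <- sim$truth[match(tab$protein_id, sim$truth$protein_id), ]
  hit <- tab$significant[truth$planted_altered]
  expect_gte(mean(hit), 0.90)
  # recovered directions agree with planted ones
  ok_dir <- tab$direction[truth$planted_altered & tab$significant] ==
    truth$planted_direction[truth$planted_altered & tab$significant]
  expect_gte(mean(ok_dir), 0.99)
})

test_that("categories partition the proteome, degenerate cases included", {
  cfg <- sim_config(n_proteins = 400, n_categories = 33, seed = 4)
  sim <- generate_cohort_matrix(cfg)
  ann <- generate_annotations(cfg, sim$truth)
  expect_equal(length(ann$categories), 400L)
  expect_equal(sum(table(ann$categories)), 400L)
  expect_equal(length(unique(ann$categories)), 33L)
  cfg1 <- sim_config(n_proteins = 100, n_categories = 1, seed = 4)
  sim1 <- generate_cohort_matrix(cfg1)
  ann1 <- generate_annotations(cfg1, sim1$truth)
  expect_equal(unique(unname(ann1$categories)), "C01")
})

test_that("a planted enriched term attains the smallest BH q", {
  cfg <- sim_config(n_proteins = 2000, seed = 8)
  sim <- generate_cohort_matrix(cfg)
  ann <- generate_annotations(cfg, sim$truth, n_terms = 30, n_enriched = 1,
                              term_prob = 0.05, enrichment_factor = 5)
  target <- sim$truth$protein_id[sim$truth$planted_altered]
  res <- hypergeometric_enrichment(target, sim$truth$protein_id,
                                   data.frame(protein_id = ann$terms$protein_id,
                                              term_id = ann$terms$term_id),
                                   filter = FALSE)
  expect_equal(res$term_id[which.min(res$q_value)], ann$enriched_terms)
  # oracle: the planted 2x2 table's own hypergeometric tail is tiny
  k <- res$k[res$term_id == ann$enriched_terms]
  K <- res$K[res$term_id == ann$enriched_terms]
  p_direct <- phyper(k - 1, K, 2000 - K, length(target),
                     lower.tail = FALSE)
  expect_equal(res$p_value[res$term_id == ann$enriched_terms], p_direct)
  expect_lt(p_direct, 1e-6)
})

test_that("planted regulator networks recover activation downstream", {
  cfg <- sim_config(n_proteins = 1500, seed = 9)
  sim <- generate_cohort_matrix(cfg)
  net <- generate_regulator_network(cfg, sim$truth)
  expect_true("activated" %in% net$planted$state)
  expect_false(anyDuplicated(net$network[, c("regulator", "target")]) > 0)
  em <- filter_by_detection(log2_transform(normalize_tic(sim$matrix)))
  tab <- fit_contrast(em, "Ctrl", "MI")
  z <- regulator_activation_z(tab, net$network)
  act <- net$planted$regulator[net$planted$state == "activated"]
  z_act <- z$z[z$regulator %in% act]
  expect_true(all(z_act >= 2))  # oracle: all targets agree, z = N/sqrt(N)
  inh <- net$planted$regulator[net$planted$state == "inhibited"]
  expect_true(all(z$z[z$regulator %in% inh] <= -2))
})

test_that("sim config round-trips through YAML", {
  cfg <- sim_config(n_proteins = 50, seed = 12)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  raw <- yaml::read_yaml(path)
  expect_equal(raw$n_proteins, 50)
  expect_equal(raw$seed, 12)
  expect_equal(sum(unlist(raw$reversal_fractions)), 1, tolerance = 1e-9)
})
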