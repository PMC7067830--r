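test_that("plain TSV loading coerces zeros to missing and validates IDs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  map <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1\ts2\ts3\ts4\ts5\ts6",
               "P1\t10\t12\t9\t11\t10\t10",
               "P2\t0\t5\t6\t5\t4\t6",
               "P3\t3\t3\t3\t3\t3\t3"), path)
  writeLines(c("sample_id\tcohort",
               paste0("s", 1:6, "\t", rep(c("Ctrl", "MI", "MI+CP"),
                                          each = 2))), map)
  m <- read_intensity_matrix(path, map)
  expect_equal(dim(m), c(3L, 6L))
  expect_true(is.na(m$values["P2", "s1"]))
  expect_equal(sum(is.na(m$values)), 1L)

  writeLines(c("protein_id\ts1\ts2\ts3\ts4\ts5\ts6",
               "P1\t1\t1\t1\t1\t1\t1",
               "P1\t2\t2\t2\t2\t2\t2"), path)
  expect_error(read_intensity_matrix(path, map), "duplicate")
})

test_that("MaxQuant proteinGroups dialect drops reverse/contaminant rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  header <- paste("Protein IDs", "LFQ intensity s1", "LFQ intensity s2",
                  "LFQ intensity s3", "LFQ intensity s4",
                  "LFQ intensity s5", "LFQ intensity s6",
                  "Reverse", "Potential contaminant", sep = "\t")
  rows <- vapply(1:10, function(i) {
    rev <- if (i <= 2) "+" else ""
    paste(c(paste0("Q", i), rep(100 * i, 6), rev, ""), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  cohorts <- setNames(rep(c("Ctrl", "MI", "MI+CP"), each = 2),
                      paste0("s", 1:6))
  m <- read_intensity_matrix(path, cohorts,
                             dialect = "maxquant_proteingroups")
  # oracle: manual count, 10 rows minus the 2 flagged reverse
  expect_equal(nrow(m$values), 8L)
  expect_false(any(c("Q1", "Q2") %in% rownames(m$values)))
  expect_equal(colnames(m$values), paste0("s", 1:6))
})

test_that("TIC normalization equalizes sample sums and is idempotent", {
  # 2x2 worked example: sums 2 and 4, grand mean 3
  v <- matrix(c(1, 1, 3, 1), 2, 2,
              dimnames = list(c("P1", "P2"), c("a", "b")))
  m <- protein_matrix(v, c("Ctrl", "MI"))
  n1 <- normalize_tic(m)
  expect_equal(n1$values, matrix(c(1.5, 1.5, 2.25, 0.75), 2, 2,
                                 dimnames = dimnames(v)))
  n2 <- normalize_tic(n1)
  expect_equal(n2$values, n1$values, tolerance = 1e-9)

  set.seed(1)
  big <- tiny_matrix(n_proteins = 50)
  big$values[3, 2] <- NA
  nb <- normalize_tic(big)
  sums <- colSums(nb$values, na.rm = TRUE)
  expect_equal(max(abs(sums / mean(sums) - 1)), 0, tolerance = 1e-9)
  expect_true(is.na(nb$values[3, 2]))
})

test_that("log2 transform is elementwise and rejects nonpositive values", {
  v <- matrix(c(8, 1, 2.5, 4, 4, 4), 3, 2,
              dimnames = list(c("P1", "P2", "P3"), c("a", "b")))
  em <- log2_transform(protein_matrix(v, c("Ctrl", "MI")))
  expect_equal(em$values[, 1], c(P1 = 3, P2 = 0, P3 = log2(2.5)))
  expect_equal(em$scale, "log2")
})

test_that("detection filter keeps proteins with enough values per cohort", {
  lv <- matrix(10, 4, 12)
  lv[1, 5:7] <- NA          # 3 of 4 MI samples missing -> dropped at min 2
  lv[2, 5] <- NA            # 3 valid in MI -> retained
  em <- tiny_log2(lv, rep(c("Ctrl", "MI", "MI+CP"), each = 4))
  f2 <- filter_by_detection(em, 2)
  expect_false("P1" %in% rownames(f2$values))
  expect_true("P2" %in% rownames(f2$values))
  expect_equal(attr(f2, "dropped"), "P1")
  f0 <- filter_by_detection(em, 0)
  expect_equal(nrow(f0$values), 4L)

  # brute-force oracle on random dropout
  set.seed(7)
  lv <- matrix(rnorm(200 * 12, 20), 200, 12)
  lv[runif(length(lv)) < 0.05] <- NA
  em <- tiny_log2(lv, rep(c("Ctrl", "MI", "MI+CP"), each = 4))
  keep_oracle <- vapply(seq_len(200), function(i) {
    all(vapply(split(lv[i, ], rep(1:3, each = 4)),
               function(x) sum(!is.na(x)) >= 2, TRUE))
  }, TRUE)
  expect_equal(nrow(filter_by_detection(em, 2)$values), sum(keep_oracle))
})

test_that("row z-scores have mean 0, sd 1; constant rows become zero", {
  lv <- rbind(c(1, 2, 3, 1, 2, 3), c(2, 4, 4, 6, 5, 5),
              c(7, 7, 7, 7, 7, 7))
  em <- tiny_log2(lv, rep(c("Ctrl", "MI", "MI+CP"), each = 2))
  expect_warning(z <- zscore_rows(em), "constant")
  expect_equal(unname(z[3, ]), rep(0, 6))
  expect_equal(rowMeans(z[1:2, ]), c(P1 = 0, P2 = 0), tolerance = 1e-12)
  expect_equal(apply(z[1:2, ], 1, sd), c(P1 = 1, P2 = 1),
               tolerance = 1e-12)
  # spec'd arithmetic case
  em4 <- tiny_log2(matrix(c(2, 4, 4, 6), 1), c("Ctrl", "Ctrl", "MI", "MI"))
  expect_equal(unname(zscore_rows(em4)[1, ]),
               c(-2, 0, 0, 2) / sd(c(2, 4, 4, 6)), tolerance = 1e-4)
})

test_that("write/read round-trip is lossless for plain TSV", {
  m <- tiny_matrix(n_proteins = 5)
  m$values[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_matrix(m, path)
  m2 <- read_intensity_matrix(path, m$cohorts)
  expect_equal(m2$values, m$values)
  expect_equal(m2$cohorts, m$cohorts)
})

test_that("log2 fold changes are invariant to per-sample rescaling", {
  m <- tiny_matrix(n_proteins = 30)
  m2 <- m
  m2$values[, 3] <- m2$values[, 3] * 7.5  # arbitrary loading difference
  t1 <- fit_contrast(log2_transform(normalize_tic(m)), "Ctrl", "MI")
  t2 <- fit_contrast(log2_transform(normalize_tic(m2)), "Ctrl", "MI")
  expect_equal(t1$log2fc, t2$log2fc, tolerance = 1e-9)
})
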