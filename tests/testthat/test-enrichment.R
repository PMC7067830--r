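test_that("hypergeometric p matches exhaustive enumeration for N <= 12", {
  # background 1..N, term = first K elements, target drawn as a set
  cases <- expand.grid(N = c(8, 10, 12), K = c(3, 5), n = c(4, 6))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; K <- cases$K[i]; n <- cases$n[i]
    bg <- sprintf("g%02d", 1:N)
    ann <- data.frame(protein_id = bg[1:K], term_id = "T1")
    k <- min(K, n) - 1                       # mixed target: k hits
    target <- c(bg[seq_len(k)], bg[(K + 1):(K + n - k)])
    res <- hypergeometric_enrichment(target, bg, ann, filter = FALSE)
    expect_equal(res$p_value, enum_hyper_p(k, K, n, N), tolerance = 1e-12,
                 label = sprintf("N=%d K=%d n=%d", N, K, n))
  }
  # worked case: N=10, K=5, n=4, k=4 -> 5/210
  bg <- sprintf("g%02d", 1:10)
  ann <- data.frame(protein_id = bg[1:5], term_id = "T1")
  res <- hypergeometric_enrichment(bg[1:4], bg, ann, filter = FALSE)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p_value, enum_hyper_p(4, 5, 4, 10), tolerance = 1e-12)
})

test_that("a term covering the whole background has p = 1", {
  bg <- sprintf("g%d", 1:9)
  ann <- data.frame(protein_id = bg, term_id = "ALL")
  res <- hypergeometric_enrichment(bg[1:3], bg, ann, filter = FALSE)
  expect_equal(res$p_value, 1)
})

test_that("BH q-values match the hand-computed step-up minima", {
  # p = (0.01, 0.02, 0.04), m = 3 -> q = (0.03, 0.03, 0.04)
  bg <- sprintf("g%02d", 1:40)
  # craft three terms with distinct p-values, then compare to p.adjust of
  # the same p set and to the hand computation
  ann <- rbind(data.frame(protein_id = bg[1:8], term_id = "A"),
               data.frame(protein_id = bg[c(1:4, 21:26)], term_id = "B"),
               data.frame(protein_id = bg[c(1:2, 27:36)], term_id = "C"))
  res <- hypergeometric_enrichment(bg[1:10], bg, ann, filter = FALSE)
  m <- nrow(res)
  p_sorted <- sort(res$p_value)
  q_hand <- rev(cummin(rev(p_sorted * m / seq_len(m))))
  expect_equal(sort(res$q_value), q_hand, tolerance = 1e-12)
  expect_true(all(res$q_value >= res$p_value))
  # direct hand example through the same step-up arithmetic
  p <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.04))
})

test_that("enrichment validates target/background containment", {
  bg <- sprintf("g%d", 1:10)
  ann <- data.frame(protein_id = bg[1:5], term_id = "T1")
  expect_error(hypergeometric_enrichment(character(0), bg, ann), "empty")
  expect_error(hypergeometric_enrichment(c("g1", "zz"), bg, ann), "subset")
})

test_that("activation z follows the closed form and is antisymmetric", {
  tab <- call_significance(data.frame(
    protein_id = sprintf("p%d", 1:6),
    log2fc = c(2, 2, 2, 2, -2, 2), p_value = rep(1e-4, 6)))
  net4 <- data.frame(regulator = "R1", target = sprintf("p%d", 1:4),
                     sign = c(1L, 1L, 1L, 1L))
  z <- regulator_activation_z(tab, net4, min_targets = 4)
  expect_equal(z$z, 2.0)  # 4 consistent: 4/sqrt(4)
  net22 <- data.frame(regulator = "R2", target = sprintf("p%d", 1:4),
                      sign = c(1L, 1L, -1L, -1L))
  expect_equal(regulator_activation_z(tab, net22, 4)$z, 0)
  net31 <- data.frame(regulator = "R3", target = sprintf("p%d", 1:4),
                      sign = c(1L, 1L, 1L, -1L))
  expect_equal(regulator_activation_z(tab, net31, 4)$z, 1.0)  # 2/sqrt(4)
  # flipping every edge sign negates every z
  flipped <- transform(net31, sign = -sign)
  expect_equal(regulator_activation_z(tab, flipped, 4)$z, -1.0)
  # regulators under min_targets are omitted
  expect_equal(nrow(regulator_activation_z(tab, net4, min_targets = 5)), 0L)
})

test_that("neighborhood networks take seeds plus first neighbors", {
  inter <- data.frame(from = c("a", "b"), to = c("b", "c"))
  net <- build_neighborhood_network("a", inter)
  expect_setequal(net$nodes, c("a", "b"))
  expect_equal(net$n_edges, 1L)
  # isolated seed retained
  net2 <- build_neighborhood_network(c("a", "zz"), inter)
  expect_true("zz" %in% net2$nodes)
  # set-union oracle on a random graph
  set.seed(13)
  edges <- unique(data.frame(
    from = sample(letters, 40, TRUE), to = sample(letters, 40, TRUE)))
  edges <- edges[edges$from != edges$to, ]
  seeds <- c("a", "b", "c")
  adj <- unique(c(edges$to[edges$from %in% seeds],
                  edges$from[edges$to %in% seeds]))
  oracle_nodes <- union(seeds, adj)
  net3 <- build_neighborhood_network(seeds, edges)
  expect_setequal(net3$nodes, oracle_nodes)
})

test_that("network overlap reports retention fractions", {
  expect_equal(network_overlap(letters[1:5], letters[1:5])$retention, 1.0)
  expect_equal(network_overlap(letters[1:5], letters[6:10])$retention, 0.0)
  # printed network sizes with a synthetic intersection of 300
  a <- sprintf("n%03d", 1:768)
  b <- sprintf("n%03d", c(1:300, 1001:1278))
  ov <- network_overlap(a, b)
  expect_equal(ov$n_a, 768L)
  expect_equal(ov$n_b, 578L)
  expect_equal(ov$retention, 0.391)
  expect_true(ov$retention < 0.5)
})

test_that("BH selection controls the false-term rate under the null", {
  # 200 null replicates: random target sets, no term truly enriched
  set.seed(99)
  bg <- sprintf("g%03d", 1:300)
  alpha <- 0.05
  fdp <- replicate(200, {
    ann <- data.frame(protein_id = sample(bg, 600, replace = TRUE),
                      term_id = rep(sprintf("T%02d", 1:20), each = 30))
    ann <- unique(ann)
    target <- sample(bg, 40)
    res <- hypergeometric_enrichment(target, bg, ann, fdr_alpha = alpha)
    if (nrow(attr(res, "all")) == 0) 0 else
      nrow(res) / max(1, nrow(res))  # all discoveries are false here
  })
  rate <- mean(fdp)
  se <- sqrt(alpha * (1 - alpha) / 200)
  expect_lte(rate, alpha + 3 * se)
})
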