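# Shared in-code fixtures for the test suite.

# small intensity matrix: 3 cohorts x 2 replicates
tiny_matrix <- function(values = NULL, n_proteins = 3) {
  if (is.null(values)) {
    set.seed(42)
    values <- matrix(2^stats::rnorm(n_proteins * 6, 20, 1), n_proteins, 6)
  }
  dimnames(values) <- list(sprintf("P%d", seq_len(nrow(values))),
                           sprintf("s%d", seq_len(ncol(values))))
  protein_matrix(values, rep(c("Ctrl", "MI", "MI+CP"), each = 2))
}

# log2-scale matrix built directly from given log2 values
tiny_log2 <- function(log2_values, cohorts) {
  if (is.null(rownames(log2_values)))
    rownames(log2_values) <- sprintf("P%d", seq_len(nrow(log2_values)))
  if (is.null(colnames(log2_values)))
    colnames(log2_values) <- sprintf("s%d", seq_len(ncol(log2_values)))
  protein_matrix(2^log2_values, cohorts) |> log2_transform()
}

# exhaustive hypergeometric upper-tail oracle: enumerate all size-n draws
# from a background of size N containing K term members, and count draws
# with >= k hits
enum_hyper_p <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # term members are elements 1..K
  mean(hits >= k)
}

# closed-form pooled two-sample t oracle
pooled_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  tt <- (mean(b) - mean(a)) / sqrt(s2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tt), na + nb - 2)
}
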