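# Independent oracles used across the suite. These deliberately take the
# dumbest correct path (explicit enumeration) rather than sharing code with
# the implementation.

# expected next-generation allele frequencies by enumerating all 16 ordered
# Hardy-Weinberg genotypes and splitting each into its two gametes
oracle_onestep_freqs <- function(p, scheme) {
  contrib <- numeric(4)
  for (i in 1:4) {
    for (j in 1:4) {
      g <- p[i] * p[j] * scheme$w[i, j]
      contrib[i] <- contrib[i] + g / 2
      contrib[j] <- contrib[j] + g / 2
    }
  }
  contrib / sum(contrib)
}

# brute-force H statistics straight from an allele matrix: count each
# distinct row by pairwise comparison, then apply the definitions
oracle_h_stats <- function(alleles) {
  n <- nrow(alleles)
  key <- apply(alleles, 1, paste, collapse = "|")
  counts <- as.integer(table(key))
  p <- sort(counts / n, decreasing = TRUE)
  H1 <- sum(p * p)
  p1 <- p[1]
  p2 <- if (length(p) > 1) p[2] else 0
  tail2 <- if (length(p) > 2) sum(p[3:length(p)]^2) else 0
  H12 <- (p1 + p2)^2 + tail2
  list(H1 = H1, H2 = H1 - p1^2, H12 = H12, H2_H1 = (H1 - p1^2) / H1)
}

# run the single-site model until the focal allele fixes or is lost
run_to_absorption <- function(N, scheme, init_counts, mu = 0,
                              fix_freq = 1, max_gen = 100000) {
  counts <- as.integer(init_counts)
  two_n <- 2L * N
  for (g in seq_len(max_gen)) {
    counts <- wf_generation(counts, scheme, N, mu)
    if (counts[2] == 0L) return(FALSE)
    if (counts[2] >= fix_freq * two_n) return(TRUE)
  }
  stop("no absorption within max_gen")
}

expect_within_3se <- function(est, se, truth, label = "estimate") {
  expect_lt(abs(est - truth), 3 * se,
            label = sprintf("%s = %g vs %g (3SE = %g)", label, est, truth, 3 * se))
}
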