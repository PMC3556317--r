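# Shared fixtures and independent oracles, built in code at test time.

# Tiny deterministic trio matrix: 4 genes, one stage, 2 replicates.
tiny_trio <- function() {
  counts <- matrix(
    c(10, 12, 20, 22, 15, 16,
      0,  0,  0,  0,  0,  0,
      100, 90, 10, 12, 55, 60,
      5,  6,  5,  7,  6,  5),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("g", 1:4),
                    c("P1_s1_r1", "P1_s1_r2", "P2_s1_r1", "P2_s1_r2",
                      "F1_s1_r1", "F1_s1_r2")))
  samples <- data.frame(
    sample = colnames(counts),
    genotype = rep(c("P1", "P2", "F1"), each = 2),
    stage = "s1",
    replicate = rep(1:2, 3),
    stringsAsFactors = FALSE)
  genes <- data.frame(gene = rownames(counts),
                      chrom = c("chr1", "chr1", "chr2", "chr3"),
                      start = c(100, 5000, 200, 1e6),
                      end = c(1099, 6999, 2199, 1e6 + 499),
                      length = c(1000, 2000, 2000, 500),
                      stringsAsFactors = FALSE)
  expression_matrix(counts, samples, genes)
}

# Independent conditional-exact-test oracle: brute-force enumeration using
# products of stats::dnbinom marginals (the mean parameter cancels on
# conditioning, so any positive mu works).
oracle_exact_p <- function(ya, yb, na, nb, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  a <- 0:t
  if (phi == 0) {
    pr <- stats::dbinom(a, t, na / (na + nb))
  } else {
    mu <- 7.3  # arbitrary positive mean; cancels under conditioning
    pr <- stats::dnbinom(a, size = na / phi, mu = na * mu) *
      stats::dnbinom(t - a, size = nb / phi, mu = nb * mu)
    pr <- pr / sum(pr)
  }
  obs <- pr[ya + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Naive O(n^3) average-linkage agglomerative clustering oracle.
oracle_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      h <- mean(d[active[[i]], active[[j]]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
    active[[best[2]]] <- NULL
  }
  heights
}

# Closed-form hypergeometric upper tail by explicit enumeration.
oracle_hyper_p <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

expect_no_error <- function(expr) expect_error(expr, NA)
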