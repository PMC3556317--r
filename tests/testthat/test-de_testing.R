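# de_testing: dispersion, exact test, BH, DEG calling, partition

test_that("dispersion: hand-computed MoM, Poisson data, degenerate gene", {
  # equal library sizes so normalization is the identity
  counts <- matrix(
    c(10, 30, 10, 30,   # s2 > mu pattern
      0, 0, 0, 0,       # all-zero gene -> common dispersion
      20, 20, 20, 20),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("gv", "gz", "gc"), paste0("s", 1:4)))
  # pad columns to equal totals
  counts <- rbind(counts, pad = as.integer(100 - colSums(counts)))
  samples <- data.frame(sample = paste0("s", 1:4),
                        genotype = c("P1", "P1", "F1", "F1"),
                        stage = "t", replicate = c(1, 2, 1, 2))
  genes <- data.frame(gene = rownames(counts), chrom = "chr1",
                      start = 1:4 * 1000, end = 1:4 * 1000 + 499,
                      length = 500)
  m <- expression_matrix(counts, samples, genes)
  ct <- make_contrast(m, "t", "R/F")
  raw <- estimate_dispersion(m, ct, shrink = FALSE)
  # gv: groups (10,30) and (10,30): mu_a = mu_b = 20,
  #     pooled s2 = (200 + 200)/2 = 200, phi = (200 - 20)/400 = 0.45
  expect_equal(unname(raw["gv"]), (200 - 20) / 20^2)
  # gc: constant -> s2 = 0 -> phi clipped at 0
  expect_equal(unname(raw["gc"]), 0)
  # gz: all-zero -> assigned the common value
  expect_equal(unname(raw["gz"]), attr(raw, "common"))
  shr <- estimate_dispersion(m, ct, prior_df = 20)
  common <- attr(shr, "common")
  expect_equal(unname(shr["gv"]), (2 * 0.45 + 20 * common) / 22)
  expect_true(all(shr >= 0))
})

test_that("Poisson-simulated data gives near-zero median dispersion", {
  sim <- simulate_trio_counts(simulation_config(
    n_genes = 2000, stages = "s1", dispersion = 0, frac_null = 1,
    seed = 13))
  m <- sim$matrix
  phi <- estimate_dispersion(m, make_contrast(m, "s1", "R/F"),
                             shrink = FALSE)
  expect_lte(stats::median(phi, na.rm = TRUE), 0.05)
})

test_that("exact test closed forms: balanced split, Poisson reduction", {
  # perfectly balanced split: observed outcome is modal -> p = 1
  a <- matrix(c(5L, 5L), 1); b <- matrix(c(5L, 5L), 1)
  expect_equal(exact_nb_test(a, b, 0.1,
                             lib_sizes = rep(100, 4))$pvalue, 1)
  # dispersion 0, group sums (10, 0), equal libraries:
  # two-sided binomial(10, 1/2) tail = 2 * (1/2)^10
  a <- matrix(c(6L, 4L), 1); b <- matrix(c(0L, 0L), 1)
  p <- exact_nb_test(a, b, 0, lib_sizes = rep(50, 4))$pvalue
  expect_equal(p, 2 * 0.5^10, tolerance = 1e-12)
  # total zero -> p = 1
  z <- matrix(0L, 1, 2)
  expect_equal(exact_nb_test(z, z, 0.1, lib_sizes = rep(10, 4))$pvalue, 1)
  expect_error(exact_nb_test(matrix(-1L, 1, 2), z, 0.1), "non-negative")
})

test_that("exact test matches brute-force enumeration (totals <= 50)", {
  set.seed(42)
  G <- 300
  na <- 2; nb <- 2
  ca <- matrix(rnbinom(G * na, mu = 4, size = 5), G)
  cb <- matrix(rnbinom(G * nb, mu = 6, size = 5), G)
  phi <- runif(G, 0, 0.5)
  phi[1:30] <- 0  # exercise the Poisson branch too
  lib <- rep(1000, na + nb)  # equal libraries: pseudo-counts = raw counts
  res <- exact_nb_test(ca, cb, phi, lib_sizes = lib)
  tot <- rowSums(ca) + rowSums(cb)
  keep <- which(tot <= 50)
  expect_gt(length(keep), 200)
  for (g in keep) {
    expect_equal(res$pvalue[g],
                 oracle_exact_p(sum(ca[g, ]), sum(cb[g, ]), na, nb, phi[g]),
                 tolerance = 1e-10)
  }
})

test_that("exact test is symmetric under group-label swap", {
  set.seed(7)
  G <- 100
  ca <- matrix(rnbinom(G * 2, mu = 20, size = 2), G)
  cb <- matrix(rnbinom(G * 2, mu = 30, size = 2), G)
  lib <- rep(2000, 4)
  p1 <- exact_nb_test(ca, cb, 0.2, lib_sizes = lib)$pvalue
  p2 <- exact_nb_test(cb, ca, 0.2, lib_sizes = lib)$pvalue
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("null p-values are stochastically >= uniform (conservative)", {
  set.seed(99)
  G <- 10000
  ca <- matrix(rnbinom(G * 2, mu = 15, size = 1 / 0.2), G)
  cb <- matrix(rnbinom(G * 2, mu = 15, size = 1 / 0.2), G)
  p <- exact_nb_test(ca, cb, 0.2, lib_sizes = rep(1000, 4))$pvalue
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(p <= alpha), alpha + 2 * sqrt(alpha * (1 - alpha) / G))
})

test_that("power sanity: 4x fold change, phi = 0.1, mean 100, n = 2", {
  set.seed(123)
  G <- 300
  ca <- matrix(rnbinom(G * 2, mu = 100, size = 10), G,
               dimnames = list(paste0("g", 1:G), NULL))
  cb <- matrix(rnbinom(G * 2, mu = 400, size = 10), G)
  res <- exact_nb_test(ca, cb, 0.1, lib_sizes = rep(sum(ca) / 2, 4))
  res <- call_degs(res)
  expect_gt(mean(res$is_deg), 0.5)
})

test_that("BH adjustment: forced arithmetic, oracle, monotonicity", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  expect_error(adjust_fdr(c(0.1, NA)), "NA")
  expect_error(adjust_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    q <- adjust_fdr(p)
    expect_equal(q, stats::p.adjust(p, "BH"))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))  # monotone in sorted-p order
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("DEG calling applies the inclusive conjunction thresholds", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(0.9, -1.0, 2.0, 1.5),
                    pvalue = c(1e-6, 1e-6, 1e-6, 0.9))
  # force known FDRs by construction: compute then inspect
  out <- call_degs(res, fdr_max = 0.05, min_abs_log2fc = 1)
  expect_false(out$is_deg[out$gene == "a"])  # |lfc| 0.9 < 1
  expect_true(out$is_deg[out$gene == "b"])   # boundary |lfc| = 1 inclusive
  expect_false(out$is_deg[out$gene == "d"])  # large p
  # FDR boundary inclusive: gene with fdr exactly 0.05 is a DEG
  res2 <- data.frame(gene = "x", log2fc = -1, pvalue = 0.05)
  expect_true(call_degs(res2)$is_deg)
})

test_that("DEG partition: set algebra and Venn identities", {
  part <- partition_degs(list(RF = c("g1", "g2"), XF = c("g2", "g3"),
                              RX = "g3"), "t")
  expect_setequal(part$dg_hp, c("g1", "g2", "g3"))
  expect_equal(unname(part$counts["DG_HP"]), 3)
  expect_identical(part$dg_pp, "g3")
  empty <- partition_degs(list(RF = character(0), XF = character(0),
                               RX = character(0)))
  expect_true(all(empty$counts == 0) && all(empty$venn == 0))
  expect_error(partition_degs(list(RF = "g1", XF = "g2")), "RX")
  # random sets: inclusion-exclusion and region sums
  set.seed(8)
  for (i in 1:20) {
    pool <- paste0("g", 1:50)
    rf <- sample(pool, sample(0:30, 1))
    xf <- sample(pool, sample(0:30, 1))
    rx <- sample(pool, sample(0:30, 1))
    p <- partition_degs(list(RF = rf, XF = xf, RX = rx))
    expect_equal(length(union(rf, xf)),
                 length(rf) + length(xf) - length(intersect(rf, xf)))
    expect_equal(unname(p$counts["DG_HP"]), length(union(rf, xf)))
    expect_equal(sum(p$venn), length(union(union(rf, xf), rx)))
    expect_equal(unname(p$counts["total"]),
                 length(union(p$dg_hp, p$dg_pp)))
  }
})

test_that("null simulation: DEG false-positive fraction is controlled", {
  sim <- simulate_trio_counts(simulation_config(n_genes = 2000,
                                                frac_null = 1, seed = 55))
  res <- de_contrast(sim$matrix, "tillering", "R/F")
  expect_lte(mean(res$is_deg), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
})
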