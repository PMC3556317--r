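# dominance_analysis: trio ANOVA fit, h_p classification, pattern summary

# log2 expression matrix for one stage with prescribed genotype means
make_log2_trio <- function(p1, p2, f1, noise_sd = 0, seed = 1,
                           rep_effect = c(0, 0)) {
  set.seed(seed)
  G <- length(p1)
  mu <- cbind(p1, p1, p2, p2, f1, f1) +
    rep(rep_effect, 3)[col(matrix(0, G, 6))]
  y <- mu + matrix(rnorm(G * 6, 0, noise_sd), G)
  dimnames(y) <- list(sprintf("g%04d", seq_len(G)),
                      c("P1_t_r1", "P1_t_r2", "P2_t_r1", "P2_t_r2",
                        "F1_t_r1", "F1_t_r2"))
  samples <- data.frame(sample = colnames(y),
                        genotype = rep(c("P1", "P2", "F1"), each = 2),
                        stage = "t", replicate = rep(1:2, 3))
  list(y = y, samples = samples)
}

test_that("noiseless fit interpolates exactly", {
  d <- make_log2_trio(p1 = c(10, 8), p2 = c(6, 8), f1 = c(9, 8))
  eff <- fit_trio_anova(d$y, d$samples, "t")
  # gene 1: P1 = 10, P2 = 6, F1 = 9 -> u = 8, [a] = 2, d = 1
  expect_equal(eff$u[1], 8)
  expect_equal(eff$a_abs[1], 2)
  expect_equal(eff$d[1], 1)
  expect_equal(eff$sigma2[1], 0)
  # gene 2: P1 = P2 = F1 -> a = d = 0
  expect_equal(eff$a_abs[2], 0)
  expect_equal(eff$d[2], 0)
  expect_equal(eff$df[1], 2)
})

test_that("replicate block effects are absorbed, not leaked into (a, d)", {
  d <- make_log2_trio(p1 = c(10, 5), p2 = c(6, 5), f1 = c(9, 7),
                      rep_effect = c(0.4, -0.4))
  eff <- fit_trio_anova(d$y, d$samples, "t")
  expect_equal(eff$a[1], 2)
  expect_equal(eff$d[1], 1)
  expect_equal(eff$d[2], 2)
  expect_equal(eff$sigma2, c(0, 0), tolerance = 1e-12)
})

test_that("missing genotype raises a named error", {
  d <- make_log2_trio(p1 = 1, p2 = 2, f1 = 3)
  keep <- d$samples$genotype != "P2"
  expect_error(fit_trio_anova(d$y[, keep, drop = FALSE],
                              d$samples[keep, ], "t"), "P2")
})

test_that("parameter recovery: MAE < 0.15 log2 units at noise sd 0.1", {
  set.seed(77)
  G <- 2000
  a <- rnorm(G, 0, 1); dd <- rnorm(G, 0, 0.8); u <- rnorm(G, 8, 1)
  d <- make_log2_trio(u + a, u - a, u + dd, noise_sd = 0.1, seed = 78,
                      rep_effect = c(0.05, -0.05))
  eff <- fit_trio_anova(d$y, d$samples, "t")
  expect_lt(mean(abs(eff$a - a)), 0.15)
  expect_lt(mean(abs(eff$d - dd)), 0.15)
})

test_that("classification follows the CI rules in both d directions", {
  # AHP limiting case: d > 0, a = 0, tiny variance -> CI for d - |a| > 0
  d <- make_log2_trio(p1 = c(8, 8), p2 = c(8, 8), f1 = c(10, 6),
                      noise_sd = 1e-4, seed = 5)
  eff <- fit_trio_anova(d$y, d$samples, "t")
  cls <- classify_hp(eff, variance_mode = "per_gene")
  expect_equal(cls$class[1], "AHP")   # d = +2, [a] = 0
  expect_equal(cls$class[2], "BLP")   # d = -2, [a] = 0
  # HPL: d = a > 0 with CI containing 0 (noisy, pooled variance)
  d2 <- make_log2_trio(p1 = rep(9, 50), p2 = rep(7, 50), f1 = rep(9, 50),
                       noise_sd = 0.2, seed = 6)
  eff2 <- classify_hp(fit_trio_anova(d2$y, d2$samples, "t"))
  expect_gt(mean(eff2$class == "HPL"), 0.9)
  # MPL: d > 0 but clearly below [a]
  d3 <- make_log2_trio(p1 = rep(10, 30), p2 = rep(6, 30), f1 = rep(8.4, 30),
                       noise_sd = 0.05, seed = 7)
  eff3 <- classify_hp(fit_trio_anova(d3$y, d3$samples, "t"))
  expect_gt(mean(eff3$class == "MPL"), 0.9)
  expect_error(classify_hp(eff, level = 1.2), "level")
})

test_that("noiseless classification agrees with the truth rule", {
  set.seed(10)
  G <- 300
  a <- rnorm(G); dd <- rnorm(G)
  d <- make_log2_trio(8 + a, 8 - a, 8 + dd)
  eff <- classify_hp(fit_trio_anova(d$y, d$samples, "t"),
                     variance_mode = "per_gene")
  expect_identical(eff$class, hp_true_class(a, dd))
  # the "none" branch requires [d] exactly zero
  eff0 <- fit_trio_anova(d$y, d$samples, "t")
  eff0$d[1] <- 0
  expect_equal(classify_hp(eff0, variance_mode = "per_gene")$class[1],
               "none")
})

test_that("class recovery >= 90% for well-separated effects", {
  set.seed(20)
  G <- 2000
  noise <- 0.1
  a <- rnorm(G, 0, 1); dd <- rnorm(G, 0, 1)
  d <- make_log2_trio(8 + a, 8 - a, 8 + dd, noise_sd = noise, seed = 21)
  eff <- classify_hp(fit_trio_anova(d$y, d$samples, "t"))
  truth <- hp_true_class(a, dd)
  sep <- abs(dd) >= 5 * noise & abs(abs(dd) - abs(a)) >= 5 * noise
  expect_gt(sum(sep), 500)
  expect_gte(mean(eff$class[sep] == truth[sep]), 0.9)
})

test_that("classification is invariant to relabeling P1 and P2", {
  set.seed(30)
  G <- 200
  a <- rnorm(G); dd <- rnorm(G)
  d <- make_log2_trio(8 + a, 8 - a, 8 + dd, noise_sd = 0.1, seed = 31)
  eff1 <- classify_hp(fit_trio_anova(d$y, d$samples, "t"))
  sw <- d$samples
  sw$genotype <- c(P1 = "P2", P2 = "P1", F1 = "F1")[sw$genotype]
  eff2 <- classify_hp(fit_trio_anova(d$y, sw, "t"))
  expect_equal(eff1$a_abs, eff2$a_abs, tolerance = 1e-12)
  expect_equal(eff1$d, eff2$d, tolerance = 1e-12)
  expect_identical(eff1$class, eff2$class)
})

test_that("widening the level only moves genes into boundary classes", {
  set.seed(40)
  G <- 500
  a <- rnorm(G); dd <- rnorm(G)
  d <- make_log2_trio(8 + a, 8 - a, 8 + dd, noise_sd = 0.3, seed = 41)
  eff <- fit_trio_anova(d$y, d$samples, "t")
  narrow <- classify_hp(eff, level = 0.9)$class
  wide <- classify_hp(eff, level = 0.998)$class
  # a gene HPL at the narrow level cannot become AHP/MPL at the wide level
  expect_false(any(narrow == "HPL" & wide %in% c("AHP", "MPL")))
  expect_false(any(narrow == "LPL" & wide %in% c("BLP", "MPL")))
})

test_that("null genes rarely classify into the extreme classes", {
  d <- make_log2_trio(rep(8, 3000), rep(8, 3000), rep(8, 3000),
                      noise_sd = 0.2, seed = 51)
  eff <- classify_hp(fit_trio_anova(d$y, d$samples, "t"), level = 0.998)
  frac_extreme <- mean(eff$class %in% c("AHP", "BLP"))
  expect_lte(frac_extreme, (1 - 0.998) + 0.01)
})

test_that("pattern summary counts, fractions and error contract", {
  d <- make_log2_trio(p1 = c(8, 8, 10), p2 = c(8, 8, 6), f1 = c(11, 5, 8.5),
                      noise_sd = 1e-4, seed = 60)
  eff <- classify_hp(fit_trio_anova(d$y, d$samples, "t"),
                     variance_mode = "per_gene")
  ps <- summarize_patterns(eff, c("g0001", "g0002"))
  expect_equal(as.integer(ps$counts[c("AHP", "BLP")]), c(1, 1))
  expect_equal(ps$up_fraction, 0.5)
  expect_equal(ps$down_fraction, 0.5)
  all_up <- summarize_patterns(eff, "g0001")
  expect_equal(all_up$up_fraction, 1)
  empty <- summarize_patterns(eff, character(0))
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$up_fraction))
  expect_error(summarize_patterns(eff, "nope"), "nope")
})

test_that("down-fraction recovers a constructed 70% LPL/BLP truth", {
  set.seed(70)
  G <- 1000
  down <- runif(G) < 0.7
  a <- runif(G, 0.5, 1.5) * sample(c(-1, 1), G, TRUE)
  dd <- ifelse(down, -1, 1) * (abs(a) + runif(G, 0.6, 1.5))  # AHP or BLP
  d <- make_log2_trio(8 + a, 8 - a, 8 + dd, noise_sd = 0.1, seed = 71)
  eff <- classify_hp(fit_trio_anova(d$y, d$samples, "t"))
  ps <- summarize_patterns(eff, rownames(d$y))
  expect_equal(ps$down_fraction, mean(down),
               tolerance = 3 * sqrt(0.7 * 0.3 / G) / 0.7)
})
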