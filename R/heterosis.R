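#' Build trait measurements from replicate values
#'
#' @param trait trait name.
#' @param p1,p2,f1 numeric replicate vectors (>= 2 values each) for the two
#'   parents and the hybrid.
#' @param units optional unit string.
#' @param larger_is_better if TRUE (default) the best parent is the one with
#'   the larger mean; set FALSE for traits where smaller is better.
#' @return list of class `TraitMeasurements`.
#' @export
trait_measurements <- function(trait, p1, p2, f1, units = NA_character_,
                               larger_is_better = TRUE) {
  for (v in list(p1, p2, f1)) {
    if (length(v) < 2) stop("each genotype needs >= 2 replicates")
    if (any(!is.finite(v))) stop("trait values must be finite")
  }
  structure(list(trait = trait, units = units, p1 = p1, p2 = p2, f1 = f1,
                 larger_is_better = isTRUE(larger_is_better)),
            class = "TraitMeasurements")
}

best_parent_mean <- function(t) {
  if (t$larger_is_better) max(mean(t$p1), mean(t$p2)) else
    min(mean(t$p1), mean(t$p2))
}

#' Mid-parent and high-parent heterosis
#'
#' `MPH = 100 * (F1 - MP) / MP` with `MP = (mean(P1) + mean(P2)) / 2`, and
#' `HPH = 100 * (F1 - HP) / HP` with `HP` the best parental mean (larger
#' mean by default). Values are reported in percent, rounded to 2 decimals
#' in `mph_2dp` / `hph_2dp` alongside the unrounded quantities.
#'
#' @param t a [trait_measurements()] object.
#' @return list of class `HeterosisResult`: trait, per-genotype mean and sd,
#'   mph, hph, mph_2dp, hph_2dp.
#' @examples
#' t <- trait_measurements("root length", p1 = rep(31.96, 2),
#'                         p2 = rep(25.58, 2), f1 = rep(33.34, 2))
#' compute_heterosis(t)$mph_2dp  # 15.88
#' @export
compute_heterosis <- function(t) {
  stopifnot(inherits(t, "TraitMeasurements"))
  mp <- (mean(t$p1) + mean(t$p2)) / 2
  hp <- best_parent_mean(t)
  if (mp == 0) stop("mid-parent mean is zero; MPH undefined for ", t$trait)
  if (hp == 0) stop("best-parent mean is zero; HPH undefined for ", t$trait)
  f1 <- mean(t$f1)
  mph <- 100 * (f1 - mp) / mp
  hph <- 100 * (f1 - hp) / hp
  structure(list(trait = t$trait,
                 means = c(P1 = mean(t$p1), P2 = mean(t$p2), F1 = f1),
                 sds = c(P1 = stats::sd(t$p1), P2 = stats::sd(t$p2),
                         F1 = stats::sd(t$f1)),
                 mp = mp, hp = hp,
                 mph = mph, hph = hph,
                 mph_2dp = round(mph, 2), hph_2dp = round(hph, 2)),
            class = "HeterosisResult")
}

# Welch-style t p-value with explicit zero-variance conventions:
# all variance terms zero -> p = 1 if the difference is zero, else p = 0.
welch_p <- function(diff, vterms, dfterms) {
  V <- sum(vterms)
  if (V == 0) return(if (diff == 0) 1 else 0)
  pos <- vterms > 0
  df <- V^2 / sum(vterms[pos]^2 / dfterms[pos])
  2 * stats::pt(-abs(diff) / sqrt(V), df)
}

#' Significance tests for MPH and HPH
#'
#' MPH: t statistic `(mean(F1) - mean(MP)) / sqrt(s2_F1/n_F1 +
#' (s2_P1/n_P1 + s2_P2/n_P2) / 4)` with Satterthwaite df. HPH: Welch
#' two-sample t of F1 against the best parent. Both two-sided. Degenerate
#' zero-variance cases follow the convention p = 1 for a zero difference and
#' p = 0 otherwise.
#'
#' @param t a [trait_measurements()] object.
#' @return list: `p_mph`, `p_hph`, and significance `stars` ("**" p <= 0.01,
#'   "*" p <= 0.05, "" otherwise) for each.
#' @export
test_heterosis <- function(t) {
  stopifnot(inherits(t, "TraitMeasurements"))
  n1 <- length(t$p1); n2 <- length(t$p2); nf <- length(t$f1)
  v1 <- stats::var(t$p1); v2 <- stats::var(t$p2); vf <- stats::var(t$f1)
  mp <- (mean(t$p1) + mean(t$p2)) / 2

  p_mph <- welch_p(mean(t$f1) - mp,
                   c(vf / nf, v1 / (4 * n1), v2 / (4 * n2)),
                   c(nf - 1, n1 - 1, n2 - 1))

  best <- if (best_parent_mean(t) == mean(t$p1)) t$p1 else t$p2
  p_hph <- welch_p(mean(t$f1) - mean(best),
                   c(vf / nf, stats::var(best) / length(best)),
                   c(nf - 1, length(best) - 1))

  star <- function(p) if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
  list(p_mph = p_mph, p_hph = p_hph,
       stars = c(mph = star(p_mph), hph = star(p_hph)))
}

#' Heterosis table for a set of traits
#'
#' Applies [compute_heterosis()] and [test_heterosis()] to a long-format
#' measurement table (as produced by [simulate_trait_measurements()] or read
#' from `traits.tsv`).
#'
#' @param measurements data.frame with columns `trait`, `genotype`
#'   (P1/P2/F1), `replicate`, `value`, optionally `stage`.
#' @return data.frame: trait (and stage if present), per-genotype means/sds,
#'   mph, hph, p_mph, p_hph, stars_mph, stars_hph.
#' @export
heterosis_table <- function(measurements) {
  need <- c("trait", "genotype", "value")
  if (!all(need %in% names(measurements)))
    stop("measurements must contain columns: ",
         paste(setdiff(need, names(measurements)), collapse = ", "))
  has_stage <- "stage" %in% names(measurements)
  key <- if (has_stage)
    interaction(measurements$trait, measurements$stage, drop = TRUE) else
      factor(measurements$trait)
  rows <- lapply(levels(key), function(k) {
    d <- measurements[key == k, , drop = FALSE]
    t <- trait_measurements(d$trait[1],
                            p1 = d$value[d$genotype == "P1"],
                            p2 = d$value[d$genotype == "P2"],
                            f1 = d$value[d$genotype == "F1"])
    h <- compute_heterosis(t)
    s <- test_heterosis(t)
    out <- data.frame(trait = t$trait,
                      p1_mean = h$means[["P1"]], p2_mean = h$means[["P2"]],
                      f1_mean = h$means[["F1"]],
                      p1_sd = h$sds[["P1"]], p2_sd = h$sds[["P2"]],
                      f1_sd = h$sds[["F1"]],
                      mph = h$mph_2dp, hph = h$hph_2dp,
                      p_mph = s$p_mph, p_hph = s$p_hph,
                      stars_mph = s$stars[["mph"]],
                      stars_hph = s$stars[["hph"]],
                      stringsAsFactors = FALSE)
    if (has_stage) out$stage <- d$stage[1]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
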