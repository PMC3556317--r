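#' Per-gene trio ANOVA: composite additive and dominance effects
#'
#' Fits, for every gene at one stage, the linear model
#' `y = u + (GA) + (GD) + (SR) + e` on the log2 expression scale, where the
#' genotype enters through an additive column (+1 for P1, -1 for P2, 0 for
#' F1) and a dominance column (1 for F1), and SR is a sum-to-zero replicate
#' (block) effect. Under this parameterization `u` is the mid-parent mean,
#' `a` is half the parental difference (P1 minus P2, signed) and `d` is the
#' deviation of the hybrid from the mid-parent, so positive `d` means the
#' hybrid sits above the mid-parent. The composite additive effect is
#' `[a] = |a|`; the composite dominance effect `[d] = d`.
#'
#' The design is shared by all genes, so the fit is a single multi-response
#' least-squares solve. With two replicates per genotype the residual df is
#' `6 - 4 = 2`.
#'
#' @param x numeric matrix of log2 expression (genes x samples), e.g.
#'   [log2_rpkm()] output.
#' @param samples sample metadata data.frame (`sample`, `genotype`, `stage`,
#'   `replicate`) matching the columns of `x`.
#' @param stage stage label to analyse.
#' @return data.frame of class `TrioEffects`: gene, u, a (signed), a_abs,
#'   d, sigma2 (residual variance), df, plus unscaled variance/covariance
#'   factors (v_aa, v_dd, v_ad) carried as columns for downstream CIs.
#' @examples
#' sim <- simulate_trio_counts(simulation_config(n_genes = 50, seed = 3))
#' y <- log2_rpkm(compute_rpkm(sim$matrix))
#' eff <- fit_trio_anova(y, sim$matrix$samples, "tillering")
#' head(eff)
#' @export
fit_trio_anova <- function(x, samples, stage) {
  x <- as.matrix(x)
  if (!identical(colnames(x), as.character(samples$sample)))
    stop("sample metadata must match expression matrix columns")
  keep <- samples$stage == stage
  if (!any(keep)) stop("stage not present: ", stage)
  s <- samples[keep, , drop = FALSE]
  y <- x[, keep, drop = FALSE]
  for (g in c("P1", "P2", "F1"))
    if (sum(s$genotype == g) < 2)
      stop("need >= 2 replicates of genotype ", g, " at stage ", stage)

  add <- ifelse(s$genotype == "P1", 1, ifelse(s$genotype == "P2", -1, 0))
  dom <- as.numeric(s$genotype == "F1")
  reps <- sort(unique(s$replicate))
  # sum-to-zero replicate block columns (R - 1 of them)
  rep_cols <- if (length(reps) > 1) {
    sapply(reps[-length(reps)], function(r)
      ifelse(s$replicate == r, 1, ifelse(s$replicate == reps[length(reps)],
                                         -1, 0)))
  } else NULL
  X <- cbind(u = 1, a = add, d = dom, rep_cols)
  p <- qr(X)$rank
  if (p < ncol(X)) stop("rank-deficient trio design at stage ", stage)
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, t(y))          # p x G
  resid <- t(y) - X %*% beta                   # n x G
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / max(df, 1)
  if (df == 0) sigma2 <- rep(0, ncol(resid))

  out <- data.frame(gene = rownames(x),
                    u = beta["u", ],
                    a = beta["a", ],
                    a_abs = abs(beta["a", ]),
                    d = beta["d", ],
                    sigma2 = sigma2,
                    df = df,
                    v_aa = XtXi["a", "a"],
                    v_dd = XtXi["d", "d"],
                    v_ad = XtXi["a", "d"],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "stage") <- stage
  class(out) <- c("TrioEffects", "data.frame")
  out
}

#' Classify the dominance ratio h_p from fitted trio effects
#'
#' Implements the confidence-interval procedure on `[d] - [a]` (for
#' `[d] > 0`) and `[d] + [a]` (for `[d] < 0`) at the given level (default
#' 99.8%). For `[d] > 0`: CI containing zero gives high-parent level (HPL,
#' h_p = 1); CI entirely positive gives above high-parent (AHP, h_p > 1);
#' CI entirely negative gives mid-parent level / partial dominance (MPL,
#' 0 < h_p < 1). For `[d] < 0` the mirror procedure on `[d] + [a]` gives
#' LPL / BLP / MPL. `[d]` exactly zero gives class "none".
#'
#' Because per-gene residual df is tiny with two replicates (df = 2),
#' the default `variance_mode = "pooled"` moderates each gene's residual
#' variance toward the median across genes:
#' `s2_mod = (pool_df * median(s2) + df * s2) / (pool_df + df)` with
#' effective df `df + pool_df`. Set `variance_mode = "per_gene"` to use raw
#' per-gene variances with df = residual df.
#'
#' @param effects a `TrioEffects` data.frame from [fit_trio_anova()].
#' @param level confidence level in (0, 1); default 0.998.
#' @param variance_mode "pooled" (default) or "per_gene".
#' @param pool_df pseudo-df given to the pooled (median) variance.
#' @return `effects` with columns `combo` (the tested combination), `se`,
#'   `df_eff`, `ci_low`, `ci_high`, `class` appended.
#' @export
classify_hp <- function(effects, level = 0.998,
                        variance_mode = c("pooled", "per_gene"),
                        pool_df = 20) {
  if (!inherits(effects, "TrioEffects"))
    stop("effects must come from fit_trio_anova()")
  if (!(level > 0 && level < 1)) stop("level must lie in (0, 1)")
  variance_mode <- match.arg(variance_mode)

  d <- effects$d; a <- effects$a
  s <- sign(a)
  up <- d > 0
  combo <- ifelse(up, d - abs(a), d + abs(a))
  # Var(d -+ sign(a) * a) in units of sigma^2
  vfac <- ifelse(up,
                 effects$v_dd + s^2 * effects$v_aa - 2 * s * effects$v_ad,
                 effects$v_dd + s^2 * effects$v_aa + 2 * s * effects$v_ad)

  if (variance_mode == "pooled") {
    s0 <- stats::median(effects$sigma2)
    s2 <- (pool_df * s0 + effects$df * effects$sigma2) /
      (pool_df + effects$df)
    df_eff <- effects$df + pool_df
  } else {
    s2 <- effects$sigma2
    df_eff <- rep(max(effects$df[1], 1), nrow(effects))
  }
  se <- sqrt(s2 * vfac)
  tq <- stats::qt(1 - (1 - level) / 2, df_eff)
  ci_low <- combo - tq * se
  ci_high <- combo + tq * se

  cls <- rep("none", nrow(effects))
  covers <- ci_low <= 0 & ci_high >= 0
  cls[up & covers] <- "HPL"
  cls[up & ci_low > 0] <- "AHP"
  cls[up & ci_high < 0] <- "MPL"
  dn <- d < 0
  cls[dn & covers] <- "LPL"
  cls[dn & ci_high < 0] <- "BLP"
  cls[dn & ci_low > 0] <- "MPL"

  effects$combo <- combo
  effects$se <- se
  effects$df_eff <- df_eff
  effects$ci_low <- ci_low
  effects$ci_high <- ci_high
  effects$class <- cls
  effects
}

#' Summarize expression-pattern classes over a DEG set
#'
#' Restricts classified trio effects to the hybrid/parent DEG set (DG_HP)
#' and tabulates the pattern classes. Up-regulated in the hybrid means
#' AHP or HPL; down-regulated means LPL or BLP.
#'
#' @param effects classified `TrioEffects` (after [classify_hp()]).
#' @param dg_hp character vector of DG_HP gene ids.
#' @return list of class `PatternSummary`: `stage`, `n` (size of DG_HP),
#'   `counts` (named, over AHP/HPL/MPL/LPL/BLP/none), `fractions` (over
#'   classified genes, i.e. class != "none"), `up_fraction`,
#'   `down_fraction` (NA when nothing is classified).
#' @export
summarize_patterns <- function(effects, dg_hp) {
  if (!"class" %in% names(effects))
    stop("effects must be classified first (classify_hp)")
  dg_hp <- unique(as.character(dg_hp))
  missing <- setdiff(dg_hp, effects$gene)
  if (length(missing) > 0)
    stop("DG_HP gene(s) missing a class: ",
         paste(utils::head(missing, 5), collapse = ", "))
  cls <- effects$class[match(dg_hp, effects$gene)]
  lv <- c("AHP", "HPL", "MPL", "LPL", "BLP", "none")
  counts <- table(factor(cls, levels = lv))
  n_cls <- sum(counts[lv != "none"])
  fractions <- if (n_cls > 0) as.numeric(counts[1:5]) / n_cls else
    rep(NA_real_, 5)
  names(fractions) <- lv[1:5]
  up <- if (n_cls > 0) (counts[["AHP"]] + counts[["HPL"]]) / n_cls else
    NA_real_
  dn <- if (n_cls > 0) (counts[["LPL"]] + counts[["BLP"]]) / n_cls else
    NA_real_
  structure(list(stage = attr(effects, "stage"), n = length(dg_hp),
                 counts = counts, fractions = fractions,
                 up_fraction = up, down_fraction = dn),
            class = "PatternSummary")
}
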