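#' Define a two-group contrast within one stage
#'
#' Contrast labels follow the trio convention: `"R/F"` compares parent P1
#' against the hybrid, `"X/F"` parent P2 against the hybrid, and `"R/X"` the
#' two parents. Group A is the first genotype of the label, group B the
#' second, and fold changes are reported B over A — so for the two
#' hybrid/parent contrasts a positive log2 fold change means up-regulated in
#' the hybrid.
#'
#' @param m an [expression_matrix()].
#' @param stage stage label present in the sample metadata.
#' @param label one of "R/F", "X/F", "R/X".
#' @return list of class `Contrast`: `label`, `stage`, `samples_a`,
#'   `samples_b` (sample ids).
#' @export
make_contrast <- function(m, stage, label = c("R/F", "X/F", "R/X")) {
  validate_expression_matrix(m)
  label <- match.arg(label)
  if (!stage %in% m$samples$stage)
    stop("stage not present in sample metadata: ", stage)
  pick <- function(g) m$samples$sample[m$samples$genotype == g &
                                         m$samples$stage == stage]
  ab <- switch(label,
               "R/F" = list(a = pick("P1"), b = pick("F1")),
               "X/F" = list(a = pick("P2"), b = pick("F1")),
               "R/X" = list(a = pick("P1"), b = pick("P2")))
  if (length(ab$a) < 2 || length(ab$b) < 2)
    stop("contrast ", label, " at stage ", stage,
         " needs >= 2 replicates per group")
  structure(list(label = label, stage = stage,
                 samples_a = ab$a, samples_b = ab$b),
            class = "Contrast")
}

# Scale each column to the geometric mean of the library sizes and round:
# the integer pseudo-counts on which the conditional exact test operates.
equalize_libsizes <- function(counts, lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  ref <- exp(mean(log(lib_sizes)))
  pseudo <- round(sweep(counts, 2, ref / lib_sizes, "*"))
  storage.mode(pseudo) <- "integer"
  list(pseudo = pseudo, ref = ref, lib_sizes = lib_sizes)
}

#' Gene-wise NB dispersion with shrinkage toward the common value
#'
#' Method-of-moments estimate on library-size-normalized counts. For each
#' gene the pooled within-group variance s^2 and the mean mu of the two group
#' means give `phi_raw = max(0, (s^2 - mu) / mu^2)`; gene-wise values are then
#' shrunk toward the common dispersion (a 10%-trimmed mean of the raw values
#' over expressed genes) with a fixed prior weight of `prior_df`
#' degrees-of-freedom equivalents:
#' `phi = (df_g * phi_raw + prior_df * phi_common) / (df_g + prior_df)`.
#' Genes with zero counts throughout get the common dispersion.
#'
#' @param m an [expression_matrix()].
#' @param contrast a [make_contrast()] object.
#' @param prior_df shrinkage weight (default 20); with two replicates per
#'   group the gene-wise residual df is 2, so the common value dominates.
#' @param shrink set FALSE to return the raw method-of-moments values
#'   (still with the degenerate-gene rule applied).
#' @return numeric vector of dispersions (>= 0), one per gene, with the
#'   common dispersion as attribute `"common"`.
#' @export
estimate_dispersion <- function(m, contrast, prior_df = 20, shrink = TRUE) {
  validate_expression_matrix(m)
  stopifnot(inherits(contrast, "Contrast"))
  ca <- m$counts[, contrast$samples_a, drop = FALSE]
  cb <- m$counts[, contrast$samples_b, drop = FALSE]
  if (ncol(ca) < 2 || ncol(cb) < 2)
    stop("each group needs >= 2 replicates to estimate dispersion")
  eq <- equalize_libsizes(cbind(ca, cb))
  na <- ncol(ca); nb <- ncol(cb)
  norm <- sweep(cbind(ca, cb), 2, eq$ref / eq$lib_sizes, "*")
  xa <- norm[, seq_len(na), drop = FALSE]
  xb <- norm[, na + seq_len(nb), drop = FALSE]
  mu_a <- rowMeans(xa); mu_b <- rowMeans(xb)
  ss <- rowSums((xa - mu_a)^2) + rowSums((xb - mu_b)^2)
  df_g <- na + nb - 2
  s2 <- ss / df_g
  mu <- (mu_a + mu_b) / 2
  phi_raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), NA_real_)
  expressed <- !is.na(phi_raw)
  common <- if (any(expressed)) mean(phi_raw[expressed], trim = 0.1) else 0
  out <- if (shrink) {
    (df_g * phi_raw + prior_df * common) / (df_g + prior_df)
  } else phi_raw
  out[!expressed] <- common
  names(out) <- rownames(m$counts)
  attr(out, "common") <- common
  out
}

# Conditional log-pmf of the group-A sum given the total, when each group sum
# is NB with size r_a / r_b and a shared probability parameter (equal means
# per sample under H0). The mean parameter cancels; what remains is a
# negative hypergeometric in a = 0..t.
cond_log_pmf <- function(a_seq, t, r_a, r_b) {
  lgamma(a_seq + r_a) - lgamma(r_a) - lgamma(a_seq + 1) +
    lgamma(t - a_seq + r_b) - lgamma(r_b) - lgamma(t - a_seq + 1) -
    (lgamma(t + r_a + r_b) - lgamma(r_a + r_b) - lgamma(t + 1))
}

#' Negative-binomial conditional exact test for one contrast
#'
#' For each gene, counts are first equalized to a common library size
#' (scaling to the geometric-mean library size and rounding); the test then
#' conditions on the total pseudo-count across both groups and sums the
#' probabilities of all splits at most as probable as the observed one
#' (a two-sided exact test, the analogue of the Fisher test under NB
#' sampling). With dispersion 0 the NB reduces to Poisson and the
#' conditional law is binomial with probability n_A / (n_A + n_B).
#'
#' @param counts_a,counts_b integer matrices (genes x replicates) for the two
#'   groups, same genes in the same order.
#' @param dispersion per-gene NB dispersion phi (>= 0), recycled if scalar.
#' @param lib_sizes optional per-sample library sizes for columns of
#'   `cbind(counts_a, counts_b)`; default column sums.
#' @return data.frame: gene, mean_a, mean_b (normalized scale), log2fc
#'   (B over A, with a pseudo-mean of 0.5 per group), pvalue.
#' @export
exact_nb_test <- function(counts_a, counts_b, dispersion, lib_sizes = NULL) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b))
    stop("count matrices must have the same genes")
  if (any(counts_a < 0) || any(counts_b < 0))
    stop("counts must be non-negative")
  G <- nrow(counts_a)
  phi <- rep_len(dispersion, G)
  if (any(phi < 0)) stop("dispersion must be >= 0")
  na <- ncol(counts_a); nb <- ncol(counts_b)
  eq <- equalize_libsizes(cbind(counts_a, counts_b), lib_sizes)
  pa <- eq$pseudo[, seq_len(na), drop = FALSE]
  pb <- eq$pseudo[, na + seq_len(nb), drop = FALSE]
  ya <- rowSums(pa); yb <- rowSums(pb)
  tot <- ya + yb

  pval <- numeric(G)
  for (g in seq_len(G)) {
    t <- tot[g]
    if (t == 0) { pval[g] <- 1; next }
    a_seq <- 0:t
    if (phi[g] == 0) {
      lp <- stats::dbinom(a_seq, t, na / (na + nb), log = TRUE)
    } else {
      lp <- cond_log_pmf(a_seq, t, na / phi[g], nb / phi[g])
    }
    lobs <- lp[ya[g] + 1]
    pval[g] <- min(1, sum(exp(lp[lp <= lobs + 1e-9])))
  }

  norm <- sweep(cbind(counts_a, counts_b), 2, eq$ref / eq$lib_sizes, "*")
  mean_a <- rowMeans(norm[, seq_len(na), drop = FALSE])
  mean_b <- rowMeans(norm[, na + seq_len(nb), drop = FALSE])
  gene <- rownames(counts_a)
  if (is.null(gene)) gene <- sprintf("g%d", seq_len(G))
  data.frame(gene = gene, mean_a = mean_a, mean_b = mean_b,
             log2fc = log2((mean_b + 0.5) / (mean_a + 0.5)),
             pvalue = pval, stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as `p`.
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(is.nan(p))) stop("p-values must not be NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Flag differentially expressed genes
#'
#' The conjunction rule: a gene is a DEG when `FDR <= fdr_max` and
#' `|log2FC| >= min_abs_log2fc` (both thresholds inclusive).
#'
#' @param results data.frame with columns `log2fc` and `pvalue` (from
#'   [exact_nb_test()]); an `fdr` column is (re)computed.
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 1).
#' @return `results` with columns `fdr` and logical `is_deg` appended.
#' @export
call_degs <- function(results, fdr_max = 0.05, min_abs_log2fc = 1) {
  if (!all(c("log2fc", "pvalue") %in% names(results)))
    stop("results must contain log2fc and pvalue columns")
  results$fdr <- adjust_fdr(results$pvalue)
  results$is_deg <- results$fdr <= fdr_max &
    abs(results$log2fc) >= min_abs_log2fc
  results
}

#' Run one DE contrast end to end
#'
#' Convenience wrapper: build the contrast, estimate dispersion, run the
#' exact test and flag DEGs.
#'
#' @inheritParams make_contrast
#' @inheritParams call_degs
#' @param prior_df dispersion shrinkage weight, see [estimate_dispersion()].
#' @return a DE result data.frame (see [exact_nb_test()], [call_degs()])
#'   with attributes `"contrast"` and `"stage"`.
#' @export
de_contrast <- function(m, stage, label, fdr_max = 0.05, min_abs_log2fc = 1,
                        prior_df = 20) {
  ct <- make_contrast(m, stage, label)
  phi <- estimate_dispersion(m, ct, prior_df = prior_df)
  res <- exact_nb_test(m$counts[, ct$samples_a, drop = FALSE],
                       m$counts[, ct$samples_b, drop = FALSE],
                       phi)
  res <- call_degs(res, fdr_max, min_abs_log2fc)
  attr(res, "contrast") <- label
  attr(res, "stage") <- stage
  res
}

#' Partition DEGs into hybrid-parent and parent-parent sets
#'
#' `DG_HP` is the union of the DEGs from the two hybrid/parent contrasts
#' (R/F and X/F); `DG_PP` is the parent/parent (R/X) DEG set. Venn region
#' counts over the three sets are reported.
#'
#' @param deg_sets named list with character vectors `RF`, `XF`, `RX` of DEG
#'   gene ids (one stage).
#' @param stage stage label carried through to the output.
#' @return list of class `DEGPartition`: `stage`, `dg_hp`, `dg_pp`, `counts`
#'   (per-contrast sizes, |DG_HP|, |DG_PP|, total = |DG_HP union DG_PP|) and
#'   `venn` (the 7 region counts, names like "RF_only", "RF_XF", ...).
#' @export
partition_degs <- function(deg_sets, stage = NA_character_) {
  need <- c("RF", "XF", "RX")
  if (!all(need %in% names(deg_sets)))
    stop("missing contrast(s): ", paste(setdiff(need, names(deg_sets)),
                                        collapse = ", "))
  rf <- unique(as.character(deg_sets$RF))
  xf <- unique(as.character(deg_sets$XF))
  rx <- unique(as.character(deg_sets$RX))
  dg_hp <- union(rf, xf)
  dg_pp <- rx
  all_g <- union(dg_hp, dg_pp)
  inset <- function(x, s) all_g %in% s
  a <- all_g %in% rf; b <- all_g %in% xf; c_ <- all_g %in% rx
  venn <- c(
    RF_only = sum(a & !b & !c_),
    XF_only = sum(!a & b & !c_),
    RX_only = sum(!a & !b & c_),
    RF_XF = sum(a & b & !c_),
    RF_RX = sum(a & !b & c_),
    XF_RX = sum(!a & b & c_),
    RF_XF_RX = sum(a & b & c_))
  structure(list(stage = stage, dg_hp = sort(dg_hp), dg_pp = sort(dg_pp),
                 counts = c(RF = length(rf), XF = length(xf),
                            RX = length(rx), DG_HP = length(dg_hp),
                            DG_PP = length(dg_pp), total = length(all_g)),
                 venn = venn),
            class = "DEGPartition")
}
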