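#' RPKM normalization
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `RPKM[g, s] = count[g, s] * 1e9 / (length_bp[g] * total[s])`.
#' The per-sample denominator defaults to the column sum of the gene-level
#' count matrix; supply `totals` to use externally determined mapped-read
#' totals instead.
#'
#' @param m an [expression_matrix()].
#' @param totals optional named numeric vector of per-sample totals; names
#'   must cover all sample ids. Default: column sums of `m$counts`.
#' @return a list of class `RPKMMatrix` with elements `rpkm` (numeric matrix,
#'   same dimnames as the counts), `totals`, `samples`, `genes`.
#' @examples
#' sim <- simulate_trio_counts(simulation_config(n_genes = 20, seed = 1))
#' r <- compute_rpkm(sim$matrix)
#' range(r$rpkm)
#' @export
compute_rpkm <- function(m, totals = NULL) {
  validate_expression_matrix(m)
  len <- m$genes$length
  if (any(len <= 0))
    stop("zero or negative gene length for: ",
         paste(utils::head(m$genes$gene[len <= 0], 5), collapse = ", "))
  if (is.null(totals)) {
    totals <- colSums(m$counts)
  } else {
    if (is.null(names(totals)) || !all(colnames(m$counts) %in% names(totals)))
      stop("totals must be named and cover every sample")
    totals <- totals[colnames(m$counts)]
  }
  if (any(totals <= 0))
    stop("zero total count for sample: ",
         paste(colnames(m$counts)[totals <= 0], collapse = ", "))
  rpkm <- sweep(m$counts * 1e9 / len, 2, totals, "/")
  structure(list(rpkm = rpkm, totals = totals, samples = m$samples,
                 genes = m$genes),
            class = "RPKMMatrix")
}

#' Per-gene, per-sample transcript coverage
#'
#' Estimated fold-coverage of each transcript: mapped reads times the read
#' length, divided by the summed exon length of the locus.
#'
#' @param m an [expression_matrix()].
#' @param read_len_bp read length in bp (default 100).
#' @return numeric matrix of coverage values, same dimnames as the counts.
#' @export
compute_coverage <- function(m, read_len_bp = 100) {
  validate_expression_matrix(m)
  len <- m$genes$length
  if (any(len <= 0))
    stop("zero or negative gene length for: ",
         paste(utils::head(m$genes$gene[len <= 0], 5), collapse = ", "))
  if (read_len_bp <= 0) stop("read_len_bp must be positive")
  m$counts * read_len_bp / len
}

#' Detection summary
#'
#' A gene counts as detected when it is represented by at least one read in
#' at least one sample.
#'
#' @param m an [expression_matrix()].
#' @return list with `n_detected`, `n_total`, `fraction`.
#' @export
detection_summary <- function(m) {
  validate_expression_matrix(m)
  det <- sum(rowSums(m$counts) >= 1)
  n <- nrow(m$counts)
  list(n_detected = det, n_total = n,
       fraction = if (n > 0) det / n else NA_real_)
}

#' Log2-transformed RPKM
#'
#' The expression scale used downstream for the trio ANOVA and for sample
#' clustering: `log2(RPKM + pseudocount)`.
#'
#' @param r an `RPKMMatrix` from [compute_rpkm()], or a plain RPKM matrix.
#' @param pseudocount added before the log (default 1).
#' @return numeric matrix of log2 expression values.
#' @export
log2_rpkm <- function(r, pseudocount = 1) {
  x <- if (inherits(r, "RPKMMatrix")) r$rpkm else as.matrix(r)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  log2(x + pseudocount)
}
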