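#' Hypergeometric term over-representation test
#'
#' For each annotation term, tests whether the gene set contains more genes
#' annotated with the term than expected by chance, against a background
#' universe: one-sided upper-tail hypergeometric
#' `p = P(X >= k)`, `X ~ Hypergeom(N, K, n)` with `N` the background size,
#' `K` the background genes carrying the term, `n` the set size and `k` the
#' set genes carrying the term. Benjamini-Hochberg FDR is computed within
#' each namespace.
#'
#' @param gene_set character vector of gene ids (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe (e.g. all detected
#'   genes).
#' @param annotation data.frame with columns `gene`, `term` and optionally
#'   `name`, `namespace`. Annotations of genes outside the background are
#'   ignored.
#' @param p_max raw-p significance threshold flagged in the output
#'   (default 0.05).
#' @return data.frame of class `EnrichmentResult`: term, name, namespace,
#'   k, K, n, N, pvalue, fdr, significant (raw p <= p_max),
#'   significant_fdr (fdr <= p_max); sorted by p-value.
#' @examples
#' bg <- paste0("g", 1:10)
#' ann <- data.frame(gene = bg[1:5], term = "T1")
#' enrich(bg[1:4], bg, ann)$pvalue  # 5/210
#' @export
enrich <- function(gene_set, background, annotation, p_max = 0.05) {
  gene_set <- unique(as.character(gene_set))
  background <- unique(as.character(background))
  bad <- setdiff(gene_set, background)
  if (length(bad) > 0)
    stop("gene(s) in set absent from background: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (!all(c("gene", "term") %in% names(annotation)))
    stop("annotation must contain columns gene and term")
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  if (nrow(ann) == 0)
    stop("no annotation overlaps the background universe")
  if (is.null(ann$name)) ann$name <- NA_character_
  if (is.null(ann$namespace)) ann$namespace <- "default"

  N <- length(background)
  n <- length(gene_set)
  key <- paste(ann$term, ann$namespace, sep = "\r")
  terms <- !duplicated(key)
  res <- data.frame(term = ann$term[terms], name = ann$name[terms],
                    namespace = ann$namespace[terms],
                    stringsAsFactors = FALSE)
  ann_split <- split(ann$gene, key)
  ord_key <- key[terms]
  res$K <- vapply(ann_split[ord_key],
                  function(g) length(unique(g)), integer(1))
  res$k <- vapply(ann_split[ord_key],
                  function(g) length(intersect(unique(g), gene_set)),
                  integer(1))
  res$n <- n
  res$N <- N
  res$pvalue <- stats::phyper(res$k - 1, res$K, N - res$K, n,
                              lower.tail = FALSE)
  res$fdr <- NA_real_
  for (ns in unique(res$namespace)) {
    i <- res$namespace == ns
    res$fdr[i] <- adjust_fdr(res$pvalue[i])
  }
  res$significant <- res$pvalue <= p_max
  res$significant_fdr <- res$fdr <= p_max
  res <- res[order(res$pvalue), c("term", "name", "namespace", "k", "K",
                                  "n", "N", "pvalue", "fdr", "significant",
                                  "significant_fdr")]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}
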