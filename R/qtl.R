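#' Map genes into QTL marker intervals
#'
#' Assigns genes (1-based inclusive genomic coordinates) to QTL intervals.
#' Under the default `"contained"` rule a gene must lie entirely inside the
#' interval (`gene start >= interval start` and `gene end <= interval end`);
#' the `"overlap"` rule accepts any intersection. Matching uses
#' GenomicRanges overlap machinery.
#'
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (the gene annotation of an [expression_matrix()]).
#' @param intervals data.frame with columns `trait`, `chrom`, `start`,
#'   `end` and optionally `marker_left`, `marker_right`. Every interval
#'   chromosome must occur in the gene annotation.
#' @param rule "contained" (default) or "overlap".
#' @return list of class `OverlapResult`: `pairs` (data.frame gene, trait,
#'   chrom, interval start/end, markers), `per_trait` (named counts of
#'   distinct genes per trait), `rule`.
#' @export
map_genes_to_intervals <- function(genes, intervals,
                                   rule = c("contained", "overlap")) {
  rule <- match.arg(rule)
  need_g <- c("gene", "chrom", "start", "end")
  if (!all(need_g %in% names(genes)))
    stop("genes must contain columns: ",
         paste(setdiff(need_g, names(genes)), collapse = ", "))
  need_i <- c("trait", "chrom", "start", "end")
  if (!all(need_i %in% names(intervals)))
    stop("intervals must contain columns: ",
         paste(setdiff(need_i, names(intervals)), collapse = ", "))
  if (any(intervals$start > intervals$end))
    stop("interval start must be <= end")
  unknown <- setdiff(unique(intervals$chrom), unique(genes$chrom))
  if (length(unknown) > 0)
    stop("unknown chromosome(s) in intervals: ",
         paste(unknown, collapse = ", "))

  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  gr_i <- GenomicRanges::GRanges(intervals$chrom,
                                 IRanges::IRanges(intervals$start,
                                                  intervals$end))
  type <- if (rule == "contained") "within" else "any"
  ov <- GenomicRanges::findOverlaps(gr_g, gr_i, type = type)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  pairs <- data.frame(
    gene = genes$gene[qh],
    trait = intervals$trait[sh],
    chrom = as.character(genes$chrom[qh]),
    gene_start = genes$start[qh],
    gene_end = genes$end[qh],
    interval_start = intervals$start[sh],
    interval_end = intervals$end[sh],
    marker_left = if ("marker_left" %in% names(intervals))
      intervals$marker_left[sh] else NA_character_,
    marker_right = if ("marker_right" %in% names(intervals))
      intervals$marker_right[sh] else NA_character_,
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$trait, pairs$chrom, pairs$gene_start,
                       pairs$gene), , drop = FALSE]
  rownames(pairs) <- NULL
  per_trait <- vapply(split(pairs$gene, pairs$trait),
                      function(g) length(unique(g)), integer(1))
  structure(list(pairs = pairs, per_trait = per_trait, rule = rule),
            class = "OverlapResult")
}
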