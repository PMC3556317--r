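#' Trio expression matrix
#'
#' The central container of the package: an integer read-count matrix (genes
#' in rows, samples in columns) together with per-sample metadata (genotype,
#' developmental stage, replicate index) and per-gene annotation (genomic
#' coordinates and summed exon length in bp).
#'
#' Genotype labels follow the trio convention `P1` and `P2` for the two
#' parents and `F1` for the hybrid.
#'
#' @param counts integer matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids). Counts must be non-negative and integral.
#' @param samples data.frame with one row per sample and columns
#'   `sample`, `genotype` (one of "P1", "P2", "F1"), `stage`, `replicate`.
#' @param genes data.frame with one row per gene and columns `gene`,
#'   `chrom`, `start`, `end`, `length` (summed exon length, bp > 0).
#'   Coordinates are 1-based inclusive.
#' @return An object of class `ExpressionMatrix` (a list with elements
#'   `counts`, `samples`, `genes`).
#' @examples
#' sim <- simulate_trio_counts(simulation_config(n_genes = 50, seed = 1))
#' em <- sim$matrix
#' dim(em$counts)
#' @export
expression_matrix <- function(counts, samples, genes) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  obj <- structure(list(counts = counts, samples = samples, genes = genes),
                   class = "ExpressionMatrix")
  validate_expression_matrix(obj)
}

#' @rdname expression_matrix
#' @param x object to validate / test.
#' @export
validate_expression_matrix <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  counts <- x$counts; samples <- x$samples; genes <- x$genes
  need_s <- c("sample", "genotype", "stage", "replicate")
  if (!all(need_s %in% names(samples)))
    stop("samples metadata must contain columns: ",
         paste(setdiff(need_s, names(samples)), collapse = ", "))
  need_g <- c("gene", "chrom", "start", "end", "length")
  if (!all(need_g %in% names(genes)))
    stop("gene annotation must contain columns: ",
         paste(setdiff(need_g, names(genes)), collapse = ", "))
  if (anyDuplicated(rownames(counts)))
    stop("gene ids must be unique")
  if (!setequal(rownames(counts), genes$gene) ||
      !identical(rownames(counts), as.character(genes$gene)))
    stop("gene annotation rows must match count matrix rows (same order)")
  if (!identical(colnames(counts), as.character(samples$sample)))
    stop("sample metadata rows must match count matrix columns (same order)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(!samples$genotype %in% c("P1", "P2", "F1")))
    stop("genotype must be one of P1, P2, F1")
  if (any(genes$length <= 0))
    stop("gene lengths must be > 0; offenders: ",
         paste(utils::head(genes$gene[genes$length <= 0], 5), collapse = ", "))
  x
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  genotypes:", paste(table(x$samples$genotype), names(table(x$samples$genotype)),
                            collapse = ", "), "\n")
  cat("  stages:", paste(unique(x$samples$stage), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an ExpressionMatrix by samples
#'
#' @param x ExpressionMatrix.
#' @param keep logical or integer index over samples.
#' @return ExpressionMatrix restricted to the selected samples.
#' @export
subset_samples <- function(x, keep) {
  validate_expression_matrix(x)
  expression_matrix(x$counts[, keep, drop = FALSE],
                    x$samples[keep, , drop = FALSE], x$genes)
}

# ---- readers / writers ------------------------------------------------------

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trio expression dataset from TSV files
#'
#' Reads the three-file interchange format written by [write_fixture_set()]:
#' `counts.tsv` (first column `gene`, remaining columns one per sample),
#' `samples.tsv` (`sample`, `genotype`, `stage`, `replicate`) and `genes.tsv`
#' (`gene`, `chrom`, `start`, `end`, `length`, 1-based inclusive coordinates).
#'
#' @param counts_path path to counts.tsv.
#' @param samples_path path to samples.tsv.
#' @param genes_path path to genes.tsv.
#' @return An [expression_matrix()].
#' @export
read_expression_set <- function(counts_path, samples_path, genes_path) {
  cdf <- read_tsv_strict(counts_path)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf[[1]]
  samples <- read_tsv_strict(samples_path)
  genes <- read_tsv_strict(genes_path)
  genes <- genes[match(rownames(counts), genes$gene), , drop = FALSE]
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  expression_matrix(counts, samples, genes)
}

#' Write a trio expression dataset to TSV files
#'
#' @param x ExpressionMatrix.
#' @param counts_path,samples_path,genes_path output paths.
#' @return invisibly, the three paths.
#' @export
write_expression_set <- function(x, counts_path, samples_path, genes_path) {
  validate_expression_matrix(x)
  cdf <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv_strict(cdf, counts_path)
  write_tsv_strict(x$samples, samples_path)
  write_tsv_strict(x$genes, genes_path)
  invisible(c(counts_path, samples_path, genes_path))
}

#' Summed exon lengths from a GFF3 file
#'
#' Sums exon span widths per gene from a GFF3 annotation, as an alternative to
#' supplying `genes.tsv` lengths directly. Exon features are grouped by their
#' `Parent` (fallback: `gene_id`/`ID`) attribute.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `gene`, `length`.
#' @export
gene_lengths_from_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3 files")
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0) stop("no exon features in ", path)
  par <- if (!is.null(ex$Parent) && any(lengths(ex$Parent) > 0)) {
    vapply(as.list(ex$Parent), function(p) p[1], character(1))
  } else if (!is.null(ex$gene_id)) as.character(ex$gene_id) else
    as.character(ex$ID)
  len <- tapply(GenomicRanges::width(ex), par, sum)
  data.frame(gene = names(len), length = as.integer(len),
             stringsAsFactors = FALSE, row.names = NULL)
}
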