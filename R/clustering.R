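#' Hierarchical clustering of samples on log2 expression
#'
#' Agglomerative clustering of the sample columns of a log2 RPKM matrix,
#' by default with distance `1 - Pearson correlation` across genes and
#' average linkage — the combination used to compare transcriptome profiles
#' of trio samples across stages. An uncentered-correlation option mirrors
#' the Cluster 3.0 default; Euclidean distance is also available.
#'
#' @param x numeric matrix (genes x samples), e.g. [log2_rpkm()] output.
#' @param metric "pearson" (default), "uncentered" or "euclidean".
#' @param linkage passed to [stats::hclust()] (default "average").
#' @return list of class `ClusterTree`: `hclust` (the stats::hclust object),
#'   `merge`, `height`, `order`, `labels`, `metric`, `linkage`.
#' @export
cluster_samples <- function(x, metric = c("pearson", "uncentered",
                                          "euclidean"),
                            linkage = "average") {
  x <- as.matrix(x)
  metric <- match.arg(metric)
  if (ncol(x) < 2) stop("need >= 2 samples to cluster")
  if (anyNA(x)) stop("missing values not allowed")
  if (metric %in% c("pearson", "uncentered")) {
    sds <- apply(x, 2, stats::sd)
    if (metric == "pearson" && any(sds == 0))
      stop("constant sample(s) under correlation metric: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
    if (metric == "uncentered" && any(colSums(x^2) == 0))
      stop("all-zero sample(s) under uncentered correlation: ",
           paste(colnames(x)[colSums(x^2) == 0], collapse = ", "))
    r <- if (metric == "pearson") stats::cor(x) else {
      xs <- sweep(x, 2, sqrt(colSums(x^2)), "/")
      crossprod(xs)
    }
    d <- stats::as.dist(1 - r)
  } else {
    d <- stats::dist(t(x))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels,
                 metric = metric, linkage = linkage),
            class = "ClusterTree")
}

#' Serialize a cluster tree to Newick
#'
#' Branch lengths are merge-height differences (ultrametric tree).
#'
#' @param tree a `ClusterTree` from [cluster_samples()].
#' @param path optional file path; when NULL the Newick string is returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_cluster_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "ClusterTree"))
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Nearest leaf of a given sample in a cluster tree
#'
#' The co-clustered sample with the smallest cophenetic distance; used to
#' ask which parent the hybrid's expression profile is closest to.
#'
#' @param tree a `ClusterTree`.
#' @param label sample label.
#' @return the label of the nearest other leaf.
#' @export
nearest_leaf <- function(tree, label) {
  stopifnot(inherits(tree, "ClusterTree"))
  cd <- as.matrix(stats::cophenetic(tree$hclust))
  if (!label %in% rownames(cd)) stop("unknown sample: ", label)
  v <- cd[label, ]
  v <- v[names(v) != label]
  names(v)[which.min(v)]
}
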