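#' Hierarchical clustering of subjects (Ward / Euclidean)
#'
#' Clusters subject aSpC profiles by agglomerative hierarchical clustering
#' with Ward's minimum-variance criterion on Euclidean distances
#' (\code{stats::hclust}, method \code{"ward.D2"}). By default the
#' profiles are \code{log2(x + 1)} transformed first: Euclidean distance
#' on raw spectral counts is dominated by the handful of most abundant
#' proteins, which makes the tree unstable under realistic long-tailed
#' abundance distributions. \code{"none"} clusters the matrix as prepared.
#'
#' @param x a subject-level [SpcExperiment-class].
#' @param transform \code{"log2p1"} (default) or \code{"none"}.
#' @return an object of class \code{hclust} with subject ids as labels and
#'   the transform recorded in attribute \code{"transform"}.
#' @export
clusterSubjects <- function(x, transform = c("log2p1", "none")) {
  stopifnot(is(x, "SpcExperiment"))
  transform <- match.arg(transform)
  if (spcLevel(x) != "subject")
    stop("clustering is defined on the subject-level matrix")
  if (ncol(x) < 2L)
    stop("at least 2 subjects are required")
  m <- t(spc(x))
  if (transform == "log2p1") m <- log2(m + 1)
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  if (is.unsorted(hc$height))
    stop("internal error: non-monotone merge heights")   # Ward guarantee
  attr(hc, "transform") <- transform
  hc
}

#' Cut a dendrogram into k canonical groups
#'
#' Cuts the tree at \code{k} clusters and relabels them deterministically:
#' clusters are ordered by decreasing size, ties broken by the smallest
#' member subject id, and named A, B, C, ... in that order. The labeling is
#' therefore independent of input column order.
#'
#' @param hc an \code{hclust} tree from [clusterSubjects()].
#' @param k number of groups (default 3).
#' @return named character vector subject id -> group label.
#' @export
cutTree <- function(hc, k = 3) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (k < 1 || k > n)
    stop("k must be between 1 and the number of subjects (", n, ")")
  raw <- stats::cutree(hc, k = k)
  canonicalizeLabels(raw)
}

# relabels integer cluster ids as A, B, C, ... by decreasing cluster size,
# ties by smallest member id (lexicographic)
canonicalizeLabels <- function(raw) {
  sizes <- table(raw)
  firsts <- vapply(names(sizes), function(cl)
    min(names(raw)[raw == cl]), character(1))
  ord <- order(-as.integer(sizes), firsts)
  map <- stats::setNames(LETTERS[seq_along(ord)], names(sizes)[ord])
  out <- map[as.character(raw)]
  names(out) <- names(raw)
  out
}

#' Export a dendrogram in Newick format
#'
#' Writes the clustering tree with merge heights as branch lengths,
#' readable by any phylogenetics/tree viewer.
#'
#' @param hc an \code{hclust} tree.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDendrogramNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
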