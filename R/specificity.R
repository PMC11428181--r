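#' Filter genes by expression level
#'
#' Retains genes whose maximum FPKM across samples is at least
#' \code{min_fpkm} (lowly expressed transcripts carry no usable specificity
#' signal); row order is preserved.
#'
#' @param matrix An \code{\link{expression_matrix}}.
#' @param min_fpkm Detection threshold (default 1 FPKM; genes below it in
#'   every sample are dropped).
#' @return The filtered \code{\link{expression_matrix}}.
#' @export
filter_expressed <- function(matrix, min_fpkm = 1.0) {
  keep <- apply(matrix, 1, max) >= min_fpkm
  if (!any(keep)) warning("no genes at or above ", min_fpkm, " FPKM")
  expression_matrix(matrix[keep, , drop = FALSE], focal_sample(matrix))
}

#' Specificity (SPM) scores
#'
#' For a gene's expression vector X over samples, the specificity score in
#' sample i is the cosine of X against the ideal profile expressed only in i:
#' \deqn{SPM_i = x_i / \sqrt{\sum_j x_j^2}.}
#' Scores lie in [0,1], their squares sum to 1 for any nonzero gene, and an
#' all-zero gene scores 0 everywhere. The score is invariant to rescaling X.
#'
#' @param matrix An \code{\link{expression_matrix}} (typically filtered).
#' @return data.frame with columns \code{gene_id} and \code{focal_spm}, plus
#'   attributes \code{spm} (full gene x sample score matrix) and
#'   \code{focal_sample}.
#' @export
spm_scores <- function(matrix) {
  norms <- sqrt(rowSums(matrix^2))
  spm <- matrix / ifelse(norms > 0, norms, 1)
  fs <- focal_sample(matrix)
  out <- data.frame(gene_id = rownames(matrix), focal_spm = spm[, fs],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "spm") <- spm
  attr(out, "focal_sample") <- fs
  out
}

#' Cluster genes by focal-sample specificity
#'
#' k-means (k clusters, 10 random restarts under a fixed seed) on the 1-D
#' focal-sample SPM values; the cluster with the highest centroid is the
#' candidate-specific cluster. Clustering in 1-D keeps the partition
#' checkable against an exhaustive threshold search and is invariant to any
#' monotone transform of the score.
#'
#' @param results Output of \code{\link{spm_scores}}.
#' @param k Number of clusters (default 2: specific vs not).
#' @param seed RNG seed for the restarts.
#' @return \code{results} with an added integer \code{cluster} column and the
#'   attribute \code{high_cluster} (label of the highest-centroid cluster).
#' @export
cluster_specific <- function(results, k = 2, seed) {
  x <- results$focal_spm
  if (length(x) < k) stop("fewer genes than clusters")
  if (length(unique(x)) < k) stop("no separation")
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 10)
  results$cluster <- km$cluster
  attr(results, "high_cluster") <- which.max(km$centers)
  attr(results, "centers") <- as.numeric(km$centers)
  results
}

#' Select focal-condition-specific lincRNAs
#'
#' From the high-centroid cluster, keeps genes detected (FPKM >=
#' \code{min_fpkm}) in the focal sample and in at most
#' \code{max_other_tissues} non-focal samples — i.e. genes exclusively
#' expressed in the focal condition, allowing for detection in a single other
#' tissue.
#'
#' @param results Output of \code{\link{cluster_specific}}.
#' @param matrix The \code{\link{expression_matrix}} the scores came from.
#' @param max_other_tissues Maximum number of non-focal samples in which the
#'   gene may be detected (default 1).
#' @param min_fpkm Detection threshold (default 1 FPKM).
#' @return Sorted character vector of selected gene IDs.
#' @export
select_lincES <- function(results, matrix, max_other_tissues = 1,
                          min_fpkm = 1.0) {
  if (is.null(results$cluster)) stop("run cluster_specific first")
  high <- attr(results, "high_cluster")
  cand <- results$gene_id[results$cluster == high]
  fs <- focal_sample(matrix)
  m <- matrix[cand, , drop = FALSE]
  focal_ok <- m[, fs] >= min_fpkm
  others <- m[, setdiff(colnames(m), fs), drop = FALSE]
  n_other <- rowSums(others >= min_fpkm)
  sort(cand[focal_ok & n_other <= max_other_tissues])
}

#' Recovery of planted specific genes
#'
#' @param selected Character vector of selected gene IDs.
#' @param truth Atlas truth (list with \code{specific_gene_ids}) or a
#'   character vector of planted IDs.
#' @return Named numeric: \code{sensitivity} (recall) and \code{precision};
#'   both 0 when the respective denominator is empty.
#' @export
recover_truth <- function(selected, truth) {
  ids <- if (is.list(truth)) truth$specific_gene_ids else truth
  hit <- length(intersect(selected, ids))
  c(sensitivity = if (length(ids) > 0) hit / length(ids) else 0,
    precision = if (length(selected) > 0) hit / length(selected) else 0)
}
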