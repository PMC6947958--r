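#' Ward hierarchical clustering of samples over signature probes
#'
#' Agglomerative clustering of samples under Ward's minimum-variance
#' criterion on Euclidean distances (hclust `"ward.D2"`, which operates on
#' squared dissimilarities as Ward's criterion requires), with labels at a
#' k-group cut. Used to check that signature probes separate cases from
#' controls.
#'
#' @param beta Probe x sample beta matrix, typically restricted to signature
#'   probes; >= 2 samples.
#' @param k Number of groups for the cut (default 2).
#' @return List: `hclust` (the merge tree), `labels` (named integer cluster
#'   labels), `dist` (the distance object).
#' @export
ward_cluster <- function(beta, k = 2) {
  if (ncol(beta) < 2) stop("clustering needs at least 2 samples")
  x <- t(beta)
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L)))
    warning("constant beta matrix: all merge heights are zero")
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(hc, k = min(k, ncol(beta)))
  list(hclust = hc, labels = labels, dist = d)
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson scaling of the pairwise Euclidean distances between samples:
#' double-centre the squared-distance matrix and take the top eigenpairs.
#' For data that truly lie in a `dims`-dimensional subspace the embedding
#' reproduces the distances exactly (up to rotation/reflection).
#'
#' @param beta Probe x sample beta matrix (>= 3 samples), typically over
#'   signature probes.
#' @param dims Embedding dimension (default 2); must be < number of samples.
#' @return Object of class `embedding2d`: `points` (samples x dims, centred),
#'   `eig` (all eigenvalues, non-increasing).
#' @export
mds_embed <- function(beta, dims = 2) {
  n <- ncol(beta)
  if (n < 3) stop("MDS needs at least 3 samples")
  if (dims > n - 1) stop("dims must be at most samples - 1")
  fit <- stats::cmdscale(stats::dist(t(beta)), k = dims, eig = TRUE)
  pts <- fit$points
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  structure(list(points = pts, eig = fit$eig), class = "embedding2d")
}
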