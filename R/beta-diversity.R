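# Beta-diversity diagnostics of SIP gradient fractions: Morisita-Horn
# dissimilarities and principal coordinates analysis, used to visualise
# community shifts toward the labelled density window.

#' Pairwise Morisita-Horn dissimilarity between samples
#'
#' \deqn{MH(x, y) = 1 - \frac{2 \sum_i x_i y_i}{(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2) X Y}}
#' with \eqn{X = \sum_i x_i}, \eqn{Y = \sum_i y_i}; values lie in
#' \[0, 1\], 0 for identical relative compositions, 1 for disjoint
#' supports. Computed with [vegan::vegdist()] (`method = "horn"`).
#'
#' @param counts samples x OTUs matrix of (normalised) counts; row sums
#'   must be positive.
#' @return symmetric matrix of dissimilarities with zero diagonal.
#' @export
#' @examples
#' morisita_horn_matrix(rbind(a = c(1, 1), b = c(1, 0)))["a", "b"]  # 1/3
morisita_horn_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) <= 0))
    stop("every sample must have a positive total count")
  d <- as.matrix(vegan::vegdist(counts, method = "horn"))
  dimnames(d) <- list(rownames(counts), rownames(counts))
  d
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centres \eqn{-D^2/2} and eigendecomposes it; coordinates are
#' the top-`k` eigenvectors scaled by the square roots of their
#' (positive) eigenvalues. Negative eigenvalues (non-Euclidean input)
#' are reported but not used. Thin wrapper over [stats::cmdscale()].
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param k number of coordinate axes (default 2).
#' @return list with `points` (samples x k), `eigenvalues` (all), and
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  n_pos_max <- nrow(d) - 1
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, n_pos_max),
                         eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > 1e-8)
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalues; returning ", n_pos,
            " axes instead of ", k)
    k <- n_pos
  }
  k <- min(k, ncol(fit$points))
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eigenvalues = eig,
       negative_eigenvalues = eig[eig < -1e-8])
}
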