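#' Radial basis function kernel matrix
#'
#' Builds the Gram matrix \eqn{K_{ij} = \exp(-\sigma \|G_i - G_j\|^2)}.
#' Note the inverse-width convention: `sigma` multiplies the squared
#' Euclidean distance directly (as in the kernlab family of kernels), not
#' the `exp(-d^2 / (2\sigma^2))` bandwidth convention — the two differ by a
#' factor of \eqn{2\sigma^2}. The benchmark setting is `sigma = 0.01`.
#'
#' @param G Numeric matrix, samples in rows.
#' @param sigma Positive inverse-width parameter.
#' @return An n x n symmetric kernel matrix with unit diagonal.
#' @export
rbf_kernel <- function(G, sigma = 0.01) {
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  G <- as.matrix(G)
  sq <- rowSums(G^2)
  D2 <- -2 * tcrossprod(G)
  D2 <- D2 + sq          # adds |G_i|^2 along rows
  D2 <- t(D2) + sq       # adds |G_j|^2 along columns
  D2[D2 < 0] <- 0
  K <- exp(-sigma * D2)
  (K + t(K)) / 2
}

#' Double-center a kernel matrix
#'
#' Applies the feature-space centering
#' \eqn{K \leftarrow K - \mathbf{1}K/n - K\mathbf{1}/n + \mathbf{1}K\mathbf{1}/n^2},
#' which makes the implicit feature vectors mean-zero. The result is
#' symmetric and positive semidefinite up to numerical tolerance.
#'
#' @param K Symmetric kernel matrix.
#' @return The centered kernel matrix.
#' @export
center_kernel <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("'K' must be square", call. = FALSE)
  cm <- colMeans(K)
  rm_ <- rowMeans(K)
  m <- mean(cm)
  Kc <- K - rm_                 # subtract row means (recycles along rows)
  Kc <- t(Kc) - cm              # subtract column means
  Kc <- t(Kc) + m
  (Kc + t(Kc)) / 2
}

# Leading spectrum of a PSD matrix via rank-revealing pivoted Cholesky.
# The centered RBF kernel of a small CpG set has numerical rank close to p,
# so for large n this is far cheaper than a full eigendecomposition.
psd_leading_spectrum <- function(Kc, tol_factor = 1e-9) {
  n <- nrow(Kc)
  ch <- suppressWarnings(chol(Kc, pivot = TRUE, tol = tol_factor * n))
  m <- attr(ch, "rank")
  piv <- attr(ch, "pivot")
  if (m == 0L) stop("centered kernel is numerically zero", call. = FALSE)
  B <- t(ch[seq_len(m), , drop = FALSE])     # rows in pivoted order
  B <- B[order(piv), , drop = FALSE]         # Kc ~ B B'
  e <- eigen(crossprod(B), symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  values <- e$values[keep]
  vectors <- B %*% e$vectors[, keep, drop = FALSE]
  vectors <- sweep(vectors, 2, sqrt(values), "/")
  list(values = values, vectors = vectors)
}

#' Kernel PCA set test
#'
#' Forms the RBF kernel of the CpG set, double-centers it, and
#' eigendecomposes it; the kernel principal component scores (eigenvectors
#' scaled by the square roots of their eigenvalues) replace the CpGs, and
#' the smallest number of leading components whose cumulative eigenvalue
#' share reaches `variance_threshold` is tested by the same k-df logistic
#' likelihood ratio test as the linear PCA test. With `kernel = "linear"`
#' the centered Gram matrix of the raw beta-values is used, which
#' reproduces ordinary PCA.
#'
#' For large n (above `exact_n`) the leading spectrum is extracted through
#' a rank-revealing pivoted Cholesky factorization of the centered kernel,
#' which is numerically low-rank for small CpG sets; the cumulative share
#' is still measured against the exact trace.
#'
#' @inheritParams pca_test
#' @param sigma RBF inverse width, see [rbf_kernel()].
#' @param kernel `"rbf"` or `"linear"`.
#' @param exact_n Sample size up to which the full eigendecomposition is
#'   used.
#' @return A `cpg_set_test` with method `"KPCA"`.
#' @export
kpca_test <- function(G, y, X = NULL, sigma = 0.01, variance_threshold = 0.8,
                      kernel = c("rbf", "linear"), exact_n = 600L) {
  kernel <- match.arg(kernel)
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("'variance_threshold' must be in (0, 1]", call. = FALSE)
  }
  G <- as.matrix(G)
  n <- nrow(G)
  K <- if (kernel == "rbf") rbf_kernel(G, sigma) else tcrossprod(G)
  Kc <- center_kernel(K)
  total <- sum(diag(Kc))
  if (total <= n * .Machine$double.eps * 100) {
    stop("centered kernel has zero trace; all samples identical", call. = FALSE)
  }

  if (n <= exact_n) {
    e <- eigen(Kc, symmetric = TRUE)
    keep <- e$values > max(e$values) * 1e-12
    values <- e$values[keep]
    vectors <- e$vectors[, keep, drop = FALSE]
  } else {
    sp <- psd_leading_spectrum(Kc)
    values <- sp$values
    vectors <- sp$vectors
  }

  frac <- cumsum(values) / total
  k <- which(frac >= min(variance_threshold, frac[length(frac)]) - 1e-12)[1]
  scores <- vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(values[seq_len(k)]), each = n)

  lrt <- logistic_lrt(y, scores, X)
  set_test_result("KPCA", lrt$statistic, lrt$df, lrt$p.value,
                  detail = list(k = k, sigma = if (kernel == "rbf") sigma else NA,
                                kernel = kernel,
                                explained = frac[k],
                                scores = scores))
}
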