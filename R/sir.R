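#' Sliced inverse regression decomposition of a CpG set
#'
#' Standardizes the methylation matrix to
#' \eqn{Z = \Sigma_{GG}^{-1/2}(G - \bar G)}, partitions the samples into `H`
#' slices of the response (a binary phenotype gives exactly two slices),
#' and decomposes the weighted between-slice covariance of the slice means,
#' \eqn{M = \sum_h \hat p_h \hat m_h \hat m_h'}. The eigenvectors, mapped
#' back through \eqn{\Sigma_{GG}^{-1/2}}, are the SIR directions in the
#' original scale.
#'
#' The inverse square root uses a symmetric eigendecomposition of the
#' sample covariance; a ridge of `1e-8 * trace / p` is added when the
#' smallest eigenvalue falls below `1e-10` times the largest.
#'
#' @param G Methylation matrix, samples in rows.
#' @param y Response; the implemented path is a binary 0/1 phenotype,
#'   sliced into its two classes.
#' @param n_slices Number of slices `H` (must be 2 for a binary response).
#' @return A list with `slice_proportions`, `slice_means` (rows are
#'   \eqn{\hat m_h}), `eigenvalues` (nonincreasing), `directions`
#'   (columns, original scale), and `H`.
#' @export
sir_decompose <- function(G, y, n_slices = 2L) {
  G <- as.matrix(G)
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(G)) stop("missing values are not supported", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("response is constant; only one slice is possible", call. = FALSE)
  }
  if (all(y %in% c(0, 1))) {
    if (n_slices != 2L) stop("a binary response admits exactly two slices", call. = FALSE)
    slice <- as.integer(y) + 1L
  } else {
    slice <- as.integer(cut(rank(y, ties.method = "first"), n_slices, labels = FALSE))
  }
  n <- nrow(G); p <- ncol(G)
  H <- length(unique(slice))
  if (H < 2L) stop("fewer than two nonempty slices", call. = FALSE)

  ctr <- colMeans(G)
  S <- stats::cov(G)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values)) {
    S <- S + diag(1e-8 * sum(diag(S)) / p, p)
    e <- eigen(S, symmetric = TRUE)
  }
  S_inv_half <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  Z <- sweep(G, 2, ctr) %*% S_inv_half

  ph <- tabulate(slice, H) / n
  mh <- rowsum(Z, slice) / (n * ph)          # slice means of Z
  M <- crossprod(mh * sqrt(ph))              # sum_h p_h m_h m_h'
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)

  list(slice_proportions = ph,
       slice_means = mh,
       eigenvalues = pmax(em$values, 0),
       directions = S_inv_half %*% em$vectors,
       H = H)
}

#' SIR set test (test of no directions)
#'
#' The classical sliced-inverse-regression dimension test of the null
#' hypothesis that there is no SIR direction: the statistic
#' \eqn{n \sum_j \hat\lambda_j} (n times the sum of the eigenvalues of the
#' between-slice covariance) is referred to a chi-square distribution with
#' \eqn{p (H - 1)} degrees of freedom. For a binary phenotype \eqn{H = 2}
#' and the between-slice matrix has rank one.
#'
#' @inheritParams sir_decompose
#' @return A `cpg_set_test` with method `"SIR"`.
#' @export
sir_test <- function(G, y) {
  dec <- sir_decompose(G, y)
  n <- nrow(as.matrix(G)); p <- ncol(as.matrix(G))
  stat <- n * sum(dec$eigenvalues)
  df <- p * (dec$H - 1L)
  set_test_result("SIR", stat, df,
                  stats::pchisq(stat, df, lower.tail = FALSE),
                  detail = list(eigenvalues = dec$eigenvalues, H = dec$H))
}
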