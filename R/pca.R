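#' Principal component reduction of a CpG set
#'
#' Centers the columns of `G` and eigendecomposes the sample covariance.
#' Beta-values share the common \[0,1\] scale, so columns are centered but
#' not variance-scaled by default; set `scale = TRUE` for correlation-based
#' components. Zero-variance columns are dropped with a warning.
#'
#' @param G Methylation matrix, samples in rows.
#' @param variance_threshold Retain the smallest number `k` of leading
#'   components whose cumulative share of total variance reaches this
#'   fraction (the benchmark design uses 0.8).
#' @param scale Scale columns to unit variance before decomposition.
#' @return A list with `scores` (n x k), `k`, `explained` (fractions per
#'   retained component), `eigenvalues` (full spectrum), and `rotation`.
#' @export
pca_reduce <- function(G, variance_threshold = 0.8, scale = FALSE) {
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("'variance_threshold' must be in (0, 1]", call. = FALSE)
  }
  G <- drop_constant_columns(as.matrix(G))
  Gc <- base::scale(G, center = TRUE, scale = scale)
  S <- crossprod(Gc) / (nrow(G) - 1)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  frac <- cumsum(ev) / sum(ev)
  k <- which(frac >= variance_threshold - 1e-12)[1]
  rot <- e$vectors[, seq_len(k), drop = FALSE]
  list(scores = Gc %*% rot, k = k,
       explained = ev[seq_len(k)] / sum(ev),
       eigenvalues = ev, rotation = rot)
}

drop_constant_columns <- function(G, context = "analysis") {
  v <- matrixStats_colVars(G)
  zero <- v <= .Machine$double.eps * 100
  if (all(zero)) {
    stop("all CpG columns have zero variance; the set test is degenerate",
         call. = FALSE)
  }
  if (any(zero)) {
    warning(sprintf("dropping %d zero-variance CpG column(s) before %s",
                    sum(zero), context))
    G <- G[, !zero, drop = FALSE]
  }
  G
}

matrixStats_colVars <- function(G) {
  n <- nrow(G)
  (colSums(G^2) - n * colMeans(G)^2) / (n - 1)
}

#' PCA set test (k-df likelihood ratio test)
#'
#' Replaces the `p` CpGs by the `k` leading principal components that
#' explain at least `variance_threshold` of the total variance, then tests
#' their joint association with the phenotype by a k-df likelihood ratio
#' test in the logistic model.
#'
#' @inheritParams pca_reduce
#' @param y Binary 0/1 phenotype.
#' @param X Optional covariates included in both null and full fits.
#' @return A `cpg_set_test` with method `"PCA"`.
#' @export
pca_test <- function(G, y, X = NULL, variance_threshold = 0.8) {
  red <- pca_reduce(G, variance_threshold)
  lrt <- logistic_lrt(y, red$scores, X)
  set_test_result("PCA", lrt$statistic, lrt$df, lrt$p.value,
                  detail = list(k = red$k,
                                explained = sum(red$explained)))
}
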