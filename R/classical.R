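#' Hotelling's two-sample T-squared test
#'
#' Classical multivariate comparison of the case and control mean
#' methylation vectors with the pooled covariance, using the exact F
#' reference: \eqn{F = T^2 (n_1 + n_2 - p - 1) / (p (n_1 + n_2 - 2))} with
#' \eqn{(p, n_1 + n_2 - p - 1)} degrees of freedom.
#'
#' @param G Methylation matrix, samples in rows.
#' @param y Binary 0/1 phenotype defining the two groups.
#' @return A `cpg_set_test` with method `"T2"`; `df` holds the numerator
#'   degrees of freedom `p`, `detail` the F statistic and both df.
#' @export
hotelling_t2_test <- function(G, y) {
  G <- as.matrix(G)
  y <- check_phenotype(y)
  p <- ncol(G)
  g1 <- G[y == 1, , drop = FALSE]
  g0 <- G[y == 0, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  if (n1 < p + 1 || n0 < p + 1) {
    stop(sprintf("each group needs at least p + 1 = %d observations", p + 1),
         call. = FALSE)
  }
  d <- colMeans(g1) - colMeans(g0)
  S <- ((n1 - 1) * stats::cov(g1) + (n0 - 1) * stats::cov(g0)) / (n1 + n0 - 2)
  Sd <- tryCatch(solve(S, d), error = function(e)
    stop("pooled covariance is singular; reduce the CpG set", call. = FALSE))
  T2 <- (n1 * n0 / (n1 + n0)) * drop(crossprod(d, Sd))
  df2 <- n1 + n0 - p - 1
  Fs <- T2 * df2 / (p * (n1 + n0 - 2))
  set_test_result("T2", T2, p,
                  stats::pf(Fs, p, df2, lower.tail = FALSE),
                  detail = list(F = Fs, df1 = p, df2 = df2,
                                n_cases = n1, n_controls = n0))
}

#' Bonferroni-corrected minimum-p t-test
#'
#' The single-marker comparison benchmark: a two-sample t-test per CpG,
#' with the set-level p-value defined as the smallest per-CpG p-value
#' multiplied by the number of CpGs tested (capped at 1). Pooled-variance
#' t-tests are the default; set `var_equal = FALSE` for Welch.
#'
#' @inheritParams hotelling_t2_test
#' @param var_equal Use the pooled-variance t statistic (default) rather
#'   than the Welch statistic.
#' @return A `cpg_set_test` with method `"MINP_T"`; the statistic is the
#'   most extreme per-CpG t value, `detail` carries the per-CpG p-values.
#' @export
minp_bonferroni_t_test <- function(G, y, var_equal = TRUE) {
  G <- as.matrix(G)
  y <- check_phenotype(y)
  G <- drop_constant_columns(G, "per-CpG t-tests")
  g1 <- G[y == 1, , drop = FALSE]
  g0 <- G[y == 0, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  if (n1 < 2 || n0 < 2) stop("both groups need at least two observations", call. = FALSE)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- matrixStats_colVars(g1); v0 <- matrixStats_colVars(g0)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    tt <- (m1 - m0) / sqrt(sp * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, ncol(G))
  } else {
    se2 <- v1 / n1 + v0 / n0
    tt <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  pj <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  j <- which.min(pj)
  set_test_result("MINP_T", unname(tt[j]), NA_integer_,
                  min(1, ncol(G) * pj[j]),
                  detail = list(per_cpg_p = pj, min_index = j,
                                n_tests = ncol(G)))
}
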