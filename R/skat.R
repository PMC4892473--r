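#' SKAT variance-component score statistic
#'
#' The sequence kernel association test models the CpG effects as random
#' with common variance component \eqn{\tau}; testing \eqn{H_0: \tau = 0}
#' yields the score statistic
#' \deqn{Q = (y - \hat\mu)' G W W G' (y - \hat\mu) = \|W G'(y - \hat\mu)\|^2,}
#' computed here without forming the n x n kernel. \eqn{\hat\mu} are the
#' fitted means of the null logistic model and `W = diag(weights)`.
#'
#' @param y Binary phenotype, or ignored if `null` is supplied with its own.
#' @param null A [fit_null_logistic()] object.
#' @param G Methylation matrix.
#' @param weights Nonnegative per-CpG weights (default all ones, the equal
#'   weighting used for quantitative methylation values).
#' @return The scalar statistic `Q >= 0`.
#' @export
skat_statistic <- function(y, null, G, weights = NULL) {
  G <- as.matrix(G)
  p <- ncol(G)
  if (is.null(weights)) weights <- rep(1, p)
  if (length(weights) != p || any(weights < 0)) {
    stop("'weights' must be nonnegative with one entry per CpG", call. = FALSE)
  }
  stopifnot(inherits(null, "cpg_null_model"))
  u <- drop(crossprod(G, null$residuals)) * weights
  sum(u^2)
}

# eigenvalues of W G' P0 G W, where P0 = V - V X (X'VX)^{-1} X'V is the
# projected working variance of the null logistic model
skat_null_eigenvalues <- function(null, G, weights) {
  G <- as.matrix(G)
  V <- null$weights
  X <- null$design
  GV <- G * V
  A <- crossprod(GV, G)                 # G' V G
  GVX <- crossprod(GV, X)               # G' V X
  XVX <- crossprod(X * V, X)
  A <- A - GVX %*% solve(XVX, t(GVX))
  A <- A * tcrossprod(weights)
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) {
    stop("degenerate SKAT null: no positive eigenvalue in the score spectrum",
         call. = FALSE)
  }
  ev[ev > 1e-10 * max(ev)]
}

#' SKAT set test for a dichotomous trait
#'
#' Fits the null logistic model (intercept plus optional covariates),
#' computes the variance-component score statistic with a linear kernel
#' and the given weights, and refers it to its null distribution — a
#' weighted mixture of 1-df chi-squares whose weights are the eigenvalues
#' of \eqn{W G' P_0 G W} — via [quadform_pvalue()].
#'
#' @inheritParams skat_statistic
#' @param X Optional covariate matrix.
#' @return A `cpg_set_test` with method `"SKAT"`; `detail` carries the
#'   mixture eigenvalues and the tail method used (`"davies"` or `"liu"`).
#' @export
skat_test <- function(G, y, X = NULL, weights = NULL) {
  G <- as.matrix(G)
  check_beta_range(G)
  null <- fit_null_logistic(y, X)
  if (is.null(weights)) weights <- rep(1, ncol(G))
  Q <- skat_statistic(y, null, G, weights)
  lambda <- skat_null_eigenvalues(null, G, weights)
  p <- quadform_pvalue(Q, lambda)
  set_test_result("SKAT", Q, NA_integer_, as.numeric(p),
                  detail = list(eigenvalues = lambda,
                                tail_method = attr(p, "method")))
}

check_beta_range <- function(G) {
  if (anyNA(G)) stop("methylation matrix contains missing values", call. = FALSE)
  if (any(G < 0) || any(G > 1)) {
    stop("methylation beta-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(G)
}
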