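#' Fit the null logistic model
#'
#' Maximum-likelihood logistic regression of the phenotype on an intercept
#' and optional covariates, with the CpG set excluded. Every set test uses
#' this fit as its reference: SKAT scores against its residuals, the LRT
#' tests add score columns to its design.
#'
#' @param y Binary 0/1 phenotype vector containing both classes.
#' @param X Optional numeric covariate matrix (columns must be linearly
#'   independent of the intercept).
#' @return An object of class `cpg_null_model` with elements `fitted_means`,
#'   `residuals` (`y - fitted`), `design` (including the intercept),
#'   `log_likelihood`, `deviance`, and `weights` (`mu * (1 - mu)`).
#' @export
fit_null_logistic <- function(y, X = NULL) {
  y <- check_phenotype(y)
  n <- length(y)
  design <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
            else {
              X <- as.matrix(X)
              if (nrow(X) != n) stop("'X' must have one row per sample", call. = FALSE)
              cbind("(Intercept)" = 1, X)
            }
  if (qr(design)$rank < ncol(design)) {
    stop("covariate matrix is rank-deficient with the intercept", call. = FALSE)
  }
  fit <- stats::glm.fit(design, y, family = stats::binomial())
  if (!fit$converged) {
    stop("null logistic fit did not converge", call. = FALSE)
  }
  mu <- fit$fitted.values
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    warning("null model fitted probabilities numerically at 0/1 (possible separation)")
  }
  structure(
    list(fitted_means = mu,
         residuals = y - mu,
         design = design,
         coefficients = fit$coefficients,
         log_likelihood = binomial_loglik(y, mu),
         deviance = fit$deviance,
         weights = mu * (1 - mu),
         y = y),
    class = "cpg_null_model"
  )
}

#' @export
print.cpg_null_model <- function(x, ...) {
  cat(sprintf("Null logistic model: n = %d, %d coefficient(s), logLik = %.4f\n",
              length(x$y), length(x$coefficients), x$log_likelihood))
  invisible(x)
}

binomial_loglik <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(y * log(mu) + (1 - y) * log1p(-mu))
}

check_phenotype <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("phenotype contains missing values", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("phenotype must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("phenotype contains a single class; association is undefined", call. = FALSE)
  }
  y
}

#' Likelihood ratio test for added score columns
#'
#' Compares the logistic fit of `y` on the null design (intercept plus
#' optional covariates) against the fit that adds the columns of `Z`,
#' referring twice the log-likelihood gain to a chi-square distribution
#' whose degrees of freedom equal the number of added columns that are
#' linearly independent of the null design. Collinear columns are dropped
#' with a warning; if nothing remains the statistic is 0 with p = 1.
#'
#' @param y Binary 0/1 phenotype.
#' @param Z Numeric matrix of scores to test (e.g. principal component
#'   scores), one row per sample.
#' @param X Optional covariates, as in [fit_null_logistic()].
#' @return A list with `statistic`, `df`, and `p.value`.
#' @export
logistic_lrt <- function(y, Z, X = NULL) {
  null <- if (inherits(y, "cpg_null_model")) y else fit_null_logistic(y, X)
  y <- null$y
  Z <- as.matrix(Z)
  if (nrow(Z) != length(y)) stop("'Z' must have one row per sample", call. = FALSE)

  M <- cbind(null$design, Z)
  q <- qr(M)
  rank_null <- qr(null$design)$rank
  df <- q$rank - rank_null
  if (df < ncol(Z)) {
    warning(sprintf("%d score column(s) collinear with the null design were dropped",
                    ncol(Z) - df))
  }
  if (df == 0L) {
    return(list(statistic = 0, df = 0L, p.value = 1))
  }
  keep <- q$pivot[seq_len(q$rank)]
  fit <- stats::glm.fit(M[, keep, drop = FALSE], y, family = stats::binomial())
  if (!fit$converged) {
    stop("full logistic fit did not converge in the likelihood ratio test",
         call. = FALSE)
  }
  stat <- max(0, null$deviance - fit$deviance)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

## Small dense-design IRLS ----------------------------------------------------
##
## glm.fit carries noticeable per-call overhead; the SPCA permutation loop
## fits thousands of tiny logistic models per dataset, so it uses this lean
## Newton-Raphson solver. Agreement with glm.fit to 1e-8 is asserted in the
## test suite.

fast_logistic <- function(Xd, y, max_iter = 30L, tol = 1e-9) {
  nc <- ncol(Xd)
  beta <- numeric(nc)
  beta[1] <- stats::qlogis(mean(y))     # warm start at the intercept MLE
  mu <- w <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    XtWX <- crossprod(Xd * w, Xd)
    step <- tryCatch(drop(solve(XtWX, crossprod(Xd, y - mu))),
                     error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol * (1 + max(abs(beta)))) break
  }
  eta <- drop(Xd %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(Xd * w, Xd)
  vcv <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, nc, nc))
  list(coefficients = beta, log_likelihood = binomial_loglik(y, mu),
       vcov = vcv, fitted = mu)
}
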