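#' Specify a logistic disease model over a CpG set
#'
#' The case/control status of individual \eqn{i} follows
#' \deqn{\mathrm{logit}\,P(D_i = 1) = \beta_0 + \sum_j \beta_j G_{ij},}
#' where the sum runs over the causal CpGs. `causal_indices` may be empty
#' (the null model, used for type I error studies).
#'
#' @param intercept Intercept \eqn{\beta_0}. If `NULL`, it is resolved at
#'   sampling time to \eqn{-\sum_j \beta_j \mu_j} (centring the linear
#'   predictor at the marginal means, so the expected prevalence is about
#'   one half and quota sampling stays efficient).
#' @param causal_indices Integer column indices of the causal CpGs (1-based).
#' @param effects Effect sizes \eqn{\beta_j}, one per causal CpG.
#' @param covariate_effects Optional coefficients for a covariate matrix
#'   (unused by the built-in scenarios, which have no covariates).
#' @return An object of class `disease_model`.
#' @examples
#' disease_model()                        # null model: no causal CpG
#' disease_model(causal_indices = 1, effects = 0.7)
#' @export
disease_model <- function(intercept = NULL, causal_indices = integer(),
                          effects = numeric(), covariate_effects = NULL) {
  causal_indices <- as.integer(causal_indices)
  effects <- as.numeric(effects)
  if (length(causal_indices) != length(effects)) {
    stop("'causal_indices' and 'effects' must have the same length", call. = FALSE)
  }
  if (length(causal_indices) && (any(causal_indices < 1) || anyDuplicated(causal_indices))) {
    stop("'causal_indices' must be distinct positive integers", call. = FALSE)
  }
  if (!is.null(intercept)) stopifnot(is.numeric(intercept), length(intercept) == 1L)
  structure(
    list(intercept = intercept, causal_indices = causal_indices,
         effects = effects, covariate_effects = covariate_effects),
    class = "disease_model"
  )
}

#' @export
print.disease_model <- function(x, ...) {
  if (length(x$causal_indices) == 0) {
    cat("Disease model: null (no causal CpG)\n")
  } else {
    cat(sprintf("Disease model: causal CpGs {%s}, effects {%s}, intercept %s\n",
                paste(x$causal_indices, collapse = ", "),
                paste(format(x$effects), collapse = ", "),
                if (is.null(x$intercept)) "auto" else format(x$intercept)))
  }
  invisible(x)
}

resolve_intercept <- function(model, marginals) {
  if (!is.null(model$intercept)) return(model$intercept)
  if (length(model$causal_indices) == 0) return(0)
  mu <- vapply(marginals[model$causal_indices], function(m) m$mean, 0)
  -sum(model$effects * mu)
}

#' Disease probability under the logistic model
#'
#' @param G A numeric vector (one individual) or matrix (individuals in
#'   rows) of methylation beta-values.
#' @param model A [disease_model()]. A `NULL` intercept is treated as 0
#'   here; quota samplers resolve it against the scenario marginals first.
#' @return Probabilities in (0,1), one per row of `G`.
#' @examples
#' m <- disease_model(intercept = 0, causal_indices = 1, effects = 0.7)
#' outcome_probability(c(0.6, 0.1), m)  # plogis(0.42)
#' @export
outcome_probability <- function(G, model) {
  stopifnot(inherits(model, "disease_model"))
  if (is.vector(G)) G <- matrix(G, nrow = 1)
  if (any(G < 0) || any(G > 1)) {
    stop("methylation values must lie in [0, 1]", call. = FALSE)
  }
  b0 <- if (is.null(model$intercept)) 0 else model$intercept
  eta <- rep(b0, nrow(G))
  if (length(model$causal_indices)) {
    if (max(model$causal_indices) > ncol(G)) {
      stop("causal index exceeds the number of CpG columns", call. = FALSE)
    }
    eta <- eta + drop(G[, model$causal_indices, drop = FALSE] %*% model$effects)
  }
  stats::plogis(eta)
}
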