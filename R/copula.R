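## Gaussian-copula machinery for correlated beta methylation values.
##
## The simulator couples arbitrary beta marginals through a latent
## multivariate normal: a row is Z ~ N(0, Rho), mapped coordinate-wise by
## pnorm and then by each marginal's beta quantile function. The latent
## correlation Rho ("copula correlation") needed to induce a desired Pearson
## correlation between the beta-values is found pair by pair with a monotone
## one-dimensional root search, the induced correlation being evaluated by
## two-dimensional Gauss-Hermite quadrature.

GH_NODES <- 48L

gh_rule <- function(n = GH_NODES) {
  gh <- pracma::gaussHermite(n)
  # rescale from weight exp(-x^2) to the standard normal density
  list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

# Pearson correlation between qbeta(pnorm(Z1)) and qbeta(pnorm(Z2)) when
# (Z1, Z2) is standard bivariate normal with correlation rho.
induced_pearson <- function(rho, m1, m2, gh = gh_rule()) {
  q1 <- stats::qbeta(stats::pnorm(gh$x), m1$shape1, m1$shape2)
  if (abs(rho) >= 1) {
    q2 <- stats::qbeta(stats::pnorm(sign(rho) * gh$x), m2$shape1, m2$shape2)
    exy <- sum(gh$w * q1 * q2)
  } else {
    z2 <- outer(gh$x * rho, gh$x * sqrt(1 - rho^2), "+")
    q2 <- matrix(stats::qbeta(stats::pnorm(z2), m2$shape1, m2$shape2), nrow = length(gh$x))
    exy <- sum(gh$w * q1 * (q2 %*% gh$w))
  }
  (exy - m1$mean * m2$mean) / (beta_marginal_sd(m1) * beta_marginal_sd(m2))
}

# solve induced_pearson(rho) = target for one pair
calibrate_pair <- function(target, m1, m2, tolerance, gh) {
  if (target == 0) return(0)
  r_hi <- induced_pearson(1, m1, m2, gh)
  r_lo <- induced_pearson(-1, m1, m2, gh)
  if (target > r_hi + tolerance || target < r_lo - tolerance) {
    stop(sprintf(paste0("target correlation %.3f is outside the attainable ",
                        "(Fréchet) range [%.3f, %.3f] for marginals ",
                        "Beta(%.3g,%.3g) / Beta(%.3g,%.3g)"),
                 target, r_lo, r_hi, m1$shape1, m1$shape2, m2$shape1, m2$shape2),
         call. = FALSE)
  }
  if (target >= r_hi) return(1)
  if (target <= r_lo) return(-1)
  stats::uniroot(function(rho) induced_pearson(rho, m1, m2, gh) - target,
                 lower = -1, upper = 1, f.lower = r_lo - target,
                 f.upper = r_hi - target, tol = min(tolerance, 1e-5))$root
}

#' Exchangeable correlation matrix
#'
#' @param p Dimension.
#' @param r Common off-diagonal Pearson correlation.
#' @return A `p` x `p` correlation matrix with unit diagonal and constant
#'   off-diagonal `r`.
#' @export
exchangeable_correlation <- function(p, r) {
  stopifnot(p >= 1, r >= -1, r <= 1)
  R <- matrix(r, p, p)
  diag(R) <- 1
  R
}

check_correlation_target <- function(target) {
  if (!is.matrix(target) || nrow(target) != ncol(target)) {
    stop("correlation target must be a square matrix", call. = FALSE)
  }
  if (max(abs(target - t(target))) > 1e-8) {
    stop("correlation target must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(target) - 1)) > 1e-8) {
    stop("correlation target must have a unit diagonal", call. = FALSE)
  }
  if (any(target < -1 - 1e-8) || any(target > 1 + 1e-8)) {
    stop("correlation target entries must lie in [-1, 1]", call. = FALSE)
  }
  invisible(target)
}

# project a symmetric matrix to the nearest PSD correlation matrix by
# eigenvalue clipping, then rescaling to a unit diagonal
nearest_psd_correlation <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(matrix = R, repaired = FALSE))
  v <- pmax(e$values, eps)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  list(matrix = (M + t(M)) / 2, repaired = TRUE)
}

#' Calibrate a Gaussian copula to target Pearson correlations of beta marginals
#'
#' Finds, for every pair of CpGs, the latent normal correlation whose
#' Gaussian copula induces the requested Pearson correlation between the two
#' beta marginals. Each pair is solved independently by a monotone root
#' search (the induced correlation is evaluated by 48-node two-dimensional
#' Gauss-Hermite quadrature); the assembled latent matrix is projected to the
#' nearest positive semidefinite correlation matrix if the pairwise solution
#' is indefinite, and the induced correlations are re-evaluated afterwards.
#'
#' @param marginals List of [beta_marginal()] objects, one per CpG.
#' @param target Symmetric correlation matrix with unit diagonal: the desired
#'   pairwise Pearson correlations of the sampled beta-values.
#' @param tolerance Calibration tolerance on each pairwise correlation.
#' @return An object of class `copula_spec` with elements
#'   `latent_correlation`, `marginals`, `achieved` (induced Pearson
#'   correlations after any repair), `repaired` (logical), and the
#'   Cholesky factor and quantile tables used by [sample_correlated_beta()].
#' @examples
#' m <- replicate(3, beta_marginal(0.6, 10), simplify = FALSE)
#' sp <- calibrate_copula(m, exchangeable_correlation(3, 0.4))
#' sp$latent_correlation[1, 2]
#' @export
calibrate_copula <- function(marginals, target, tolerance = 1e-4) {
  marginals <- as_marginal_list(marginals)
  check_correlation_target(target)
  p <- length(marginals)
  if (nrow(target) != p) {
    stop("dimension of 'target' must match the number of marginals", call. = FALSE)
  }
  if (tolerance <= 0) stop("'tolerance' must be positive", call. = FALSE)

  gh <- gh_rule()
  latent <- diag(p)
  cache <- new.env(parent = emptyenv())
  if (p > 1) {
    for (j in seq_len(p - 1)) {
      for (k in (j + 1):p) {
        m1 <- marginals[[j]]; m2 <- marginals[[k]]
        key <- paste(signif(c(m1$shape1, m1$shape2, m2$shape1, m2$shape2,
                              target[j, k]), 12), collapse = "|")
        if (is.null(cache[[key]])) {
          cache[[key]] <- calibrate_pair(target[j, k], m1, m2, tolerance, gh)
        }
        latent[j, k] <- latent[k, j] <- cache[[key]]
      }
    }
  }

  rep_out <- nearest_psd_correlation(latent)
  latent <- rep_out$matrix

  achieved <- diag(p)
  if (p > 1) {
    for (j in seq_len(p - 1)) {
      for (k in (j + 1):p) {
        achieved[j, k] <- achieved[k, j] <-
          induced_pearson(latent[j, k], marginals[[j]], marginals[[k]], gh)
      }
    }
  }

  tables <- lapply(marginals, function(m) build_beta_qtable(m$shape1, m$shape2))

  structure(
    list(latent_correlation = latent,
         marginals = marginals,
         target = target,
         achieved = achieved,
         repaired = rep_out$repaired,
         chol = chol(latent),
         tables = tables,
         tolerance = tolerance),
    class = "copula_spec"
  )
}

#' @export
print.copula_spec <- function(x, ...) {
  p <- length(x$marginals)
  off <- x$achieved[upper.tri(x$achieved)]
  cat(sprintf("Gaussian copula spec: %d beta marginals%s\n", p,
              if (isTRUE(x$repaired)) " (latent matrix PSD-repaired)" else ""))
  if (length(off)) {
    cat(sprintf("  induced pairwise Pearson r: %.3f .. %.3f\n",
                min(off), max(off)))
  }
  invisible(x)
}

#' Sample correlated beta-distributed methylation values
#'
#' Draws `n` rows from a calibrated Gaussian copula: a latent multivariate
#' normal row is mapped coordinate-wise through the standard normal
#' distribution function and each marginal's beta quantile function. The
#' quantile transform uses the spec's precomputed lookup tables (absolute
#' error below 1e-7); set `exact = TRUE` to evaluate `qbeta` directly.
#'
#' @param spec A `copula_spec` from [calibrate_copula()].
#' @param n Number of samples (rows).
#' @param seed Optional integer seed; the same seed yields an identical
#'   matrix. The caller's RNG state is restored on exit.
#' @param exact Use the exact `qbeta` transform instead of the tabulated one.
#' @return An `n` x `p` matrix of beta-values, all entries strictly in (0,1).
#' @export
sample_correlated_beta <- function(spec, n, seed = NULL, exact = FALSE) {
  stopifnot(inherits(spec, "copula_spec"), n >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  p <- length(spec$marginals)
  Z <- matrix(stats::rnorm(n * p), nrow = n) %*% spec$chol
  G <- matrix(0, n, p)
  for (j in seq_len(p)) {
    if (exact) {
      m <- spec$marginals[[j]]
      G[, j] <- stats::qbeta(stats::pnorm(Z[, j]), m$shape1, m$shape2)
    } else {
      G[, j] <- qtable_lookup(spec$tables[[j]], Z[, j])
    }
  }
  # the transform is strictly interior for any finite z; clamp defensively
  eps <- .Machine$double.eps
  G[G <= 0] <- eps
  G[G >= 1] <- 1 - eps
  G
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
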