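#' Supervised principal component set test with a permutation null
#'
#' Supervised PCA screens the CpG set down to the markers most associated
#' with the phenotype before extracting the first principal component:
#'
#' 1. each CpG is scored by its univariate logistic score statistic;
#' 2. a screening threshold is chosen from `screen_fractions` (each fraction
#'    keeps the top `ceiling(f * p)` CpGs by absolute score); the retained
#'    size is the one whose PC1 carries the strongest association with the
#'    phenotype — by logistic score statistic (`selection = "score"`, the
#'    default), by maximized likelihood ratio (`"lrt"`), or by K-fold
#'    cross-validated held-out log-likelihood (`"cv"`);
#' 3. the first principal component of the selected columns is computed;
#' 4. the statistic is the Wald ratio \eqn{T = \hat\beta_1 / se(\hat\beta_1)}
#'    from the logistic fit of the phenotype on PC1 (plus covariates).
#'
#' Because screening uses the outcome, `T` is not referred to a t
#' distribution; the p-value comes from a full-procedure permutation null:
#' steps 1-4 are recomputed on label-permuted data and
#' \eqn{p = (1 + \#\{|T_b| \ge |T_{obs}|\}) / (B + 1)}. Selection bias is
#' thereby accounted for, whichever selection rule is used, since the
#' permuted datasets pass through the identical adaptive procedure.
#'
#' The column covariances, candidate-subset principal components and their
#' sample scores do not depend on the phenotype labels, so they are cached
#' across permutations.
#'
#' @inheritParams pca_test
#' @param screen_fractions Candidate screening fractions in (0, 1].
#' @param n_permutations Number of label permutations `B` (at least 99).
#' @param selection Threshold selection rule: `"score"`, `"lrt"` or `"cv"`.
#' @param n_folds Folds for `selection = "cv"`.
#' @param seed Optional seed for the permutation draws (caller's RNG state
#'   is restored on exit).
#' @return A `cpg_set_test` with method `"SPCA"`; `detail` carries the
#'   selected CpG count and indices and the permutation count.
#' @export
spca_test <- function(G, y, X = NULL, screen_fractions = seq(0.1, 1, 0.1),
                      n_permutations = 199L, selection = c("score", "lrt", "cv"),
                      n_folds = 5L, seed = NULL) {
  selection <- match.arg(selection)
  if (n_permutations < 99L) stop("'n_permutations' must be at least 99", call. = FALSE)
  if (any(screen_fractions <= 0) || any(screen_fractions > 1)) {
    stop("'screen_fractions' must lie in (0, 1]", call. = FALSE)
  }
  G <- as.matrix(G)
  check_beta_range(G)
  G <- drop_constant_columns(G, "supervised screening")
  y <- check_phenotype(y)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }

  n <- nrow(G); p <- ncol(G)
  sizes <- sort(unique(pmin(pmax(ceiling(screen_fractions * p), 1L), p)))

  ctx <- spca_context(G, y, X, n_folds)
  obs <- spca_single(ctx, y, sizes, selection)

  if (is.null(X) && selection == "score") {
    # compiled permutation engine; identical procedure, label matrix built
    # here so the permutation stream matches the interpreted path
    Y <- matrix(0, n, n_permutations + 1L)
    Y[, 1L] <- y
    for (b in seq_len(n_permutations)) Y[, b + 1L] <- y[sample.int(n)]
    Tall <- spca_perm_stats_cpp(ctx$Gc, ctx$Gn, ctx$CGG, sizes, Y)
    obs$T <- Tall[1L]
    perm_T <- Tall[-1L]
  } else {
    perm_T <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      yb <- y[sample.int(n)]
      perm_T[b] <- spca_single(ctx, yb, sizes, selection)$T
    }
  }
  pval <- (1 + sum(abs(perm_T) >= abs(obs$T))) / (n_permutations + 1)

  set_test_result("SPCA", obs$T, NA_integer_, pval,
                  detail = list(selected = sort(obs$selected),
                                n_selected = length(obs$selected),
                                selection = selection,
                                n_permutations = n_permutations))
}

# permutation-invariant context: centered columns, their cross-products
# (the column covariances do not depend on the labels), the null design,
# and a cache of PC1 score vectors keyed by CpG subset
spca_context <- function(G, y, X, n_folds = 5L) {
  Gc <- base::scale(G, center = TRUE, scale = FALSE)
  colSS <- colSums(Gc^2)
  list(G = G, Gc = Gc,
       colSS = colSS,
       # columns pre-scaled so that crossprod(Gn, y) is the screening score
       # up to a factor constant across label permutations
       Gn = Gc * rep(1 / sqrt(colSS), each = nrow(G)),
       CGG = crossprod(Gc),
       X = X,
       design0 = if (is.null(X)) matrix(1, nrow(G), 1) else cbind(1, as.matrix(X)),
       n_folds = n_folds,
       pc1_cache = new.env(parent = emptyenv()))
}

# PC1 sample scores (and their sum of squares) of a column subset; label-free,
# so cached under a bitmask key that is order-invariant in `sel`
spca_pc1_entry <- function(ctx, sel) {
  if (length(sel) == 1L) {
    return(list(s = ctx$Gc[, sel], ss = ctx$colSS[sel], sel = sel))
  }
  key <- as.character(sum(2^(sel - 1)))
  ent <- ctx$pc1_cache[[key]]
  if (is.null(ent)) {
    v1 <- eigen(ctx$CGG[sel, sel], symmetric = TRUE)$vectors[, 1]
    s <- drop(ctx$Gc[, sel, drop = FALSE] %*% v1)
    ent <- list(s = s, ss = sum(s^2), sel = sel)
    ctx$pc1_cache[[key]] <- ent
  }
  ent
}

# one full SPCA pass (screen, select, PC1, Wald T) for a given label vector
spca_single <- function(ctx, y, sizes, selection) {
  if (is.null(ctx$X)) {
    u <- abs(drop(crossprod(ctx$Gn, y)))      # |screening score|, common scale
    ord <- order(u, decreasing = TRUE)
  } else {
    ord <- order(-abs(spca_screen_scores(ctx, y)))
  }

  if (selection == "cv" && length(sizes) > 1L) {
    m_best <- spca_cv_size(ctx, y, sizes)
    ent <- spca_pc1_entry(ctx, ord[seq_len(m_best)])
  } else if (selection == "lrt" && length(sizes) > 1L) {
    best_ll <- -Inf
    for (m in sizes) {
      e <- spca_pc1_entry(ctx, ord[seq_len(m)])
      ll <- fast_logistic(cbind(ctx$design0, e$s), y)$log_likelihood
      if (ll > best_ll) { best_ll <- ll; ent <- e }
    }
  } else {
    # PC1 with the largest logistic score statistic; the null-variance
    # factor is constant across candidates and permutations, so comparing
    # (s'y)^2 / s's suffices (PC1 scores are exactly mean-zero)
    best_val <- -Inf
    for (m in sizes) {
      e <- spca_pc1_entry(ctx, ord[seq_len(m)])
      val <- if (is.null(ctx$X)) sum(e$s * y)^2 / e$ss
             else spca_pc1_score_stat(ctx, y, e$s)
      if (val > best_val) { best_val <- val; ent <- e }
    }
  }

  if (is.null(ctx$X)) {
    list(T = fast_logistic_slope(ent$s, y)$T, selected = ent$sel)
  } else {
    fit <- fast_logistic(cbind(ctx$design0, ent$s), y)
    j <- length(fit$coefficients)
    list(T = fit$coefficients[j] / sqrt(fit$vcov[j, j]),
         selected = ent$sel)
  }
}

# covariate-adjusted squared score statistic of one candidate score vector
spca_pc1_score_stat <- function(ctx, y, s) {
  null <- fit_null_logistic(y, ctx$X)
  u <- sum(s * null$residuals)
  Vw <- null$weights
  Xd <- null$design
  sx <- crossprod(Xd * Vw, s)
  v <- sum(s^2 * Vw) - drop(crossprod(sx, solve(crossprod(Xd * Vw, Xd), sx)))
  u^2 / v
}

# Newton-Raphson logistic fit of y on an intercept and one score vector,
# with the 2x2 system solved in closed form; returns the Wald ratio of the
# slope. Agreement with glm is asserted in the test suite.
fast_logistic_slope <- function(s, y, max_iter = 30L, tol = 1e-8) {
  b0 <- stats::qlogis(mean(y)); b1 <- 0
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(b0 + b1 * s)
    w <- mu * (1 - mu)
    sw <- sum(w); sws <- sum(w * s); swss <- sum(w * s * s)
    r <- y - mu
    u0 <- sum(r); u1 <- sum(r * s)
    det <- sw * swss - sws * sws
    if (det <= 0) break
    d0 <- (swss * u0 - sws * u1) / det
    d1 <- (sw * u1 - sws * u0) / det
    b0 <- b0 + d0; b1 <- b1 + d1
    if (abs(d0) + abs(d1) < tol * (1 + abs(b0) + abs(b1))) break
  }
  mu <- stats::plogis(b0 + b1 * s)
  w <- mu * (1 - mu)
  sw <- sum(w); sws <- sum(w * s); swss <- sum(w * s * s)
  det <- sw * swss - sws * sws
  list(T = b1 / sqrt(sw / det), b0 = b0, b1 = b1, fitted = mu)
}

# univariate logistic score statistics; with covariates the scores are
# computed against the covariate-adjusted null model
spca_screen_scores <- function(ctx, y) {
  if (is.null(ctx$X)) {
    ybar <- mean(y)
    u <- drop(crossprod(ctx$Gc, y))
    v <- ybar * (1 - ybar) * ctx$colSS
  } else {
    null <- fit_null_logistic(y, ctx$X)
    Vw <- null$weights
    Xd <- null$design
    GV <- ctx$G * Vw
    u <- drop(crossprod(ctx$G, null$residuals))
    GVX <- crossprod(GV, Xd)
    XVX <- crossprod(Xd * Vw, Xd)
    v <- colSums(ctx$G * GV) - rowSums((GVX %*% solve(XVX)) * GVX)
  }
  u / sqrt(pmax(v, 1e-300))
}

# cross-validated choice of the screening size: held-out log-likelihood of
# the PC1 fit, folds assigned by a deterministic stripe of the sample order
spca_cv_size <- function(ctx, y, sizes) {
  n <- length(y)
  fold <- rep_len(seq_len(ctx$n_folds), n)
  cvll <- numeric(length(sizes))
  for (f in seq_len(ctx$n_folds)) {
    tr <- fold != f
    Gtr <- ctx$G[tr, , drop = FALSE]
    ctr <- colMeans(Gtr)
    Gtrc <- sweep(Gtr, 2, ctr)
    fold_ctx <- list(G = Gtr, Gc = Gtrc, colSS = colSums(Gtrc^2),
                     X = if (is.null(ctx$X)) NULL else ctx$X[tr, , drop = FALSE])
    ztr <- spca_screen_scores(fold_ctx, y[tr])
    ordtr <- order(-abs(ztr))
    Gte <- sweep(ctx$G[!tr, , drop = FALSE], 2, ctr)
    for (i in seq_along(sizes)) {
      sel <- ordtr[seq_len(sizes[i])]
      if (length(sel) == 1L) {
        str_ <- Gtrc[, sel]; ste <- Gte[, sel]
      } else {
        v1 <- eigen(crossprod(Gtrc[, sel, drop = FALSE]), symmetric = TRUE)$vectors[, 1]
        str_ <- drop(Gtrc[, sel, drop = FALSE] %*% v1)
        ste <- drop(Gte[, sel, drop = FALSE] %*% v1)
      }
      fit <- fast_logistic(cbind(1, str_), y[tr])
      mu_te <- stats::plogis(fit$coefficients[1] + fit$coefficients[2] * ste)
      cvll[i] <- cvll[i] + binomial_loglik(y[!tr], mu_te)
    }
  }
  sizes[which.max(cvll)]
}
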