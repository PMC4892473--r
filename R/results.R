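SET_TEST_METHODS <- c("PCA", "SPCA", "KPCA", "SKAT", "SIR", "T2", "MINP_T")

# shared constructor for the per-method result objects
set_test_result <- function(method, statistic, df, p.value, detail = list()) {
  stopifnot(method %in% SET_TEST_METHODS, is.finite(statistic))
  if (!is.na(p.value) && (p.value < 0 || p.value > 1)) {
    stop("internal error: p-value outside [0, 1]", call. = FALSE)
  }
  structure(
    list(method = method, statistic = statistic, df = df,
         p.value = p.value, detail = detail),
    class = "cpg_set_test"
  )
}

#' @export
print.cpg_set_test <- function(x, ...) {
  cat(sprintf("CpG set test: %s\n", x$method))
  cat(sprintf("  statistic = %.6g%s, p-value = %s\n",
              x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) sprintf(", df = %g", x$df) else "",
              format_pvalue_scientific(x$p.value)))
  extras <- setdiff(names(x$detail), "")
  if (length(extras)) {
    flat <- vapply(extras, function(nm) {
      v <- x$detail[[nm]]
      if (is.numeric(v) && length(v) <= 4) paste(signif(v, 4), collapse = ", ")
      else if (length(v) == 1) as.character(v)
      else sprintf("<%d values>", length(v))
    }, "")
    cat(sprintf("  %s\n", paste(sprintf("%s: %s", extras, flat), collapse = "; ")))
  }
  invisible(x)
}

#' Run a battery of CpG set tests
#'
#' Applies the requested set-level tests to the same methylation matrix and
#' phenotype, collecting one row per method.
#'
#' @param G Methylation beta-value matrix (samples x CpGs).
#' @param y Binary 0/1 phenotype.
#' @param X Optional covariate matrix (ignored by the two-sample tests
#'   `T2` and `MINP_T`, which are defined without covariates).
#' @param methods Character vector from
#'   `c("PCA","SPCA","KPCA","SKAT","SIR","T2","MINP_T")`.
#' @param ... Passed on to the individual tests (e.g. `sigma`,
#'   `variance_threshold`, `n_permutations`).
#' @return A data frame with columns `method`, `statistic`, `df`, `p.value`.
#' @export
run_set_tests <- function(G, y, X = NULL, methods = SET_TEST_METHODS, ...) {
  methods <- match.arg(methods, SET_TEST_METHODS, several.ok = TRUE)
  dots <- list(...)
  res <- lapply(methods, function(m) {
    r <- switch(m,
      PCA    = do.call(pca_test,  c(list(G, y, X), dots[names(dots) %in% "variance_threshold"])),
      SPCA   = do.call(spca_test, c(list(G, y, X),
                 dots[names(dots) %in% c("screen_fractions", "n_permutations", "selection")])),
      KPCA   = do.call(kpca_test, c(list(G, y, X),
                 dots[names(dots) %in% c("sigma", "variance_threshold", "kernel")])),
      SKAT   = do.call(skat_test, c(list(G, y, X), dots[names(dots) %in% "weights"])),
      SIR    = sir_test(G, y),
      T2     = hotelling_t2_test(G, y),
      MINP_T = do.call(minp_bonferroni_t_test,
                       c(list(G, y), dots[names(dots) %in% "var_equal"]))
    )
    data.frame(method = r$method, statistic = r$statistic,
               df = if (is.null(r$df) || is.na(r$df)) NA_real_ else r$df,
               p.value = r$p.value)
  })
  do.call(rbind, res)
}

format_pvalue_scientific <- function(p) {
  if (is.na(p)) return("NA")
  toupper(formatC(p, format = "e", digits = 2))
}
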