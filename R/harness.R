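#' Estimate empirical rejection rates by Monte Carlo
#'
#' Draws `n_replications` datasets from a scenario and applies a battery of
#' set tests to each; the per-method fraction of p-values at or below
#' `alpha` estimates the type I error (null scenario) or power (scenario
#' with causal CpGs). Replication `t` is seeded with `base_seed + t`, so
#' every replication is individually reproducible and the results do not
#' depend on execution order. All methods see the same dataset within a
#' replication (common random numbers). Method errors are caught and
#' counted separately — never as non-rejections; a summary with more than
#' 1% errored replications is flagged invalid.
#'
#' @param scenario A [scenario_spec()] (e.g. from [cpg_scenario()]).
#' @param methods Methods to run, see [run_set_tests()].
#' @param n_replications Number of Monte Carlo replications.
#' @param alpha Significance level.
#' @param base_seed Integer base seed.
#' @param ... Additional arguments passed to the individual tests.
#' @return A data frame with one row per method: `scenario_label`,
#'   `method`, `alpha`, `n_replications`, `n_rejections`, `n_errors`,
#'   `rejection_rate`, `mc_standard_error`, `base_seed`, `valid`.
#' @export
estimate_rejection_rate <- function(scenario, methods, n_replications,
                                    alpha = 0.05, base_seed = 1L, ...) {
  stopifnot(inherits(scenario, "scenario_spec"),
            n_replications >= 1, alpha > 0, alpha <= 1)
  methods <- match.arg(methods, SET_TEST_METHODS, several.ok = TRUE)
  rej <- err <- structure(integer(length(methods)), names = methods)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  for (t in seq_len(n_replications)) {
    set.seed((base_seed + t) %% .Machine$integer.max)
    dat <- sample_case_control(scenario)
    for (m in methods) {
      p <- tryCatch(
        run_set_tests(dat$G, dat$y, methods = m, ...)$p.value,
        error = function(e) NA_real_
      )
      if (is.na(p)) err[m] <- err[m] + 1L
      else if (p <= alpha) rej[m] <- rej[m] + 1L
    }
  }

  ok <- n_replications - err
  data.frame(
    scenario_label = scenario$label,
    method = methods,
    alpha = alpha,
    n_replications = n_replications,
    n_rejections = unname(rej),
    n_errors = unname(err),
    rejection_rate = unname(ifelse(ok > 0, rej / ok, NA_real_)),
    mc_standard_error = unname(ifelse(ok > 0,
      sqrt(pmax(rej / ok * (1 - rej / ok), 0) / ok), NA_real_)),
    base_seed = base_seed,
    valid = unname(err <= 0.01 * n_replications),
    row.names = NULL
  )
}

#' Type I error table over a scenario sweep
#'
#' Convenience sweep reproducing the layout of the benchmark type-I-error
#' tables: one row per correlation level (virtual scenarios) or gene
#' template, one column per method.
#'
#' @param scenarios Either a list of [scenario_spec()] objects, or a
#'   character vector of built-in labels; virtual labels are crossed with
#'   `r_grid`.
#' @param methods Methods to run.
#' @param n_replications Replications per cell.
#' @param alpha Significance level.
#' @param base_seed Base seed; cell `i` uses `base_seed + (i-1) * n_replications`.
#' @param r_grid Exchangeable correlations for virtual scenario labels.
#' @param mean Common marginal mean for `"1.x"` labels.
#' @param ... Passed to the tests.
#' @return A list with `table` (rows = scenarios, columns = methods) and
#'   `summaries` (the long-form data frame of all cells).
#' @export
type1_table <- function(scenarios, methods, n_replications, alpha = 0.05,
                        base_seed = 1L, r_grid = c(0.2, 0.4, 0.6, 0.8),
                        mean = 0.6, ...) {
  if (is.character(scenarios)) {
    built <- list()
    for (lab in scenarios) {
      if (lab %in% c("PTPRD", "MLH1")) {
        built[[lab]] <- cpg_scenario(lab, mean = 0.5)
      } else {
        for (r in r_grid) {
          built[[sprintf("%s[r=%g]", lab, r)]] <-
            cpg_scenario(lab, r = r, mean = mean)
        }
      }
    }
    scenarios <- built
  }
  rows <- list()
  offset <- 0L
  for (nm in names(scenarios)) {
    rows[[nm]] <- estimate_rejection_rate(scenarios[[nm]], methods,
                                          n_replications, alpha,
                                          base_seed + offset, ...)
    rows[[nm]]$cell <- nm
    offset <- offset + n_replications
  }
  long <- do.call(rbind, rows)
  tab <- matrix(NA_real_, length(scenarios), length(methods),
                dimnames = list(names(scenarios), methods))
  for (i in seq_len(nrow(long))) {
    tab[long$cell[i], long$method[i]] <- long$rejection_rate[i]
  }
  list(table = tab, summaries = long)
}

#' Power curve over an effect-size grid
#'
#' Sweeps the causal effect size of a built-in scenario over a grid at a
#' fixed correlation, estimating power per method at each point. The zero
#' effect reduces to the type I error of the matching null scenario.
#'
#' @param scenario_label Built-in scenario label with causal CpGs
#'   (e.g. `"1.2"`, `"2.3"`, `"PTPRD"`).
#' @param effect_grid Effect sizes to sweep.
#' @param methods,n_replications,alpha,base_seed,... As in
#'   [estimate_rejection_rate()].
#' @param r Exchangeable correlation (virtual scenarios).
#' @param mean Common marginal mean where applicable.
#' @return A list with `table` (rows = effects, columns = methods, entries =
#'   power) and `summaries`.
#' @export
power_curve <- function(scenario_label, effect_grid, methods,
                        n_replications, alpha = 0.05, base_seed = 1L,
                        r = NULL, mean = 0.6, ...) {
  rows <- list()
  offset <- 0L
  for (b in effect_grid) {
    sc <- if (b == 0) {
      null_label <- if (scenario_label %in% c("PTPRD", "MLH1")) scenario_label
                    else sub("\\..*$", ".1", scenario_label)
      cpg_scenario(null_label, r = r, mean = mean)
    } else {
      cpg_scenario(scenario_label, r = r, effect = b, mean = mean)
    }
    s <- estimate_rejection_rate(sc, methods, n_replications, alpha,
                                 base_seed + offset, ...)
    s$effect <- b
    rows[[as.character(b)]] <- s
    offset <- offset + n_replications
  }
  long <- do.call(rbind, rows)
  tab <- matrix(NA_real_, length(effect_grid), length(methods),
                dimnames = list(as.character(effect_grid), methods))
  for (i in seq_len(nrow(long))) {
    tab[as.character(long$effect[i]), long$method[i]] <- long$rejection_rate[i]
  }
  list(table = tab, summaries = long)
}
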