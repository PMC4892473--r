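#' Assemble a simulation scenario
#'
#' A scenario bundles everything needed to draw one case/control methylation
#' dataset: the beta marginals of the CpGs, the target Pearson correlation
#' matrix among them, the logistic disease model, and the case/control
#' quotas. The Gaussian copula is calibrated once at construction.
#'
#' @param marginals List of [beta_marginal()] objects.
#' @param correlation Target Pearson correlation matrix (symmetric, unit
#'   diagonal), with dimension equal to the number of marginals.
#' @param disease A [disease_model()].
#' @param n_cases,n_controls Case and control quotas.
#' @param label Scenario label used in summaries (e.g. `"1.2"`, `"PTPRD"`).
#' @param tolerance Copula calibration tolerance, passed to
#'   [calibrate_copula()].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(marginals, correlation, disease = disease_model(),
                          n_cases = 1000, n_controls = 1000,
                          label = "custom", tolerance = 1e-4) {
  marginals <- as_marginal_list(marginals)
  check_correlation_target(correlation)
  if (nrow(correlation) != length(marginals)) {
    stop("number of marginals must equal the correlation dimension", call. = FALSE)
  }
  stopifnot(inherits(disease, "disease_model"),
            n_cases >= 1, n_controls >= 1)
  if (length(disease$causal_indices) &&
      max(disease$causal_indices) > length(marginals)) {
    stop("causal index exceeds the number of CpGs in the scenario", call. = FALSE)
  }
  structure(
    list(marginals = marginals, correlation = correlation, disease = disease,
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         label = as.character(label),
         copula = calibrate_copula(marginals, correlation, tolerance)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d CpGs, %d cases / %d controls\n",
              x$label, length(x$marginals), x$n_cases, x$n_controls))
  print(x$disease)
  invisible(x)
}

## Built-in scenario library -------------------------------------------------

# printed 6x6 (PTPRD) and 9x9 (MLH1) correlation matrices of the two
# HM450 gene-region templates
lower_tri_correlation <- function(vals, p) {
  R <- diag(p)
  R[upper.tri(R)] <- 0
  k <- 1L
  for (i in 2:p) {
    for (j in 1:(i - 1)) {
      R[i, j] <- R[j, i] <- vals[k]
      k <- k + 1L
    }
  }
  stopifnot(k - 1L == length(vals))
  R
}

ptprd_correlation <- function() {
  lower_tri_correlation(c(
    0.264,
    0.469, 0.257,
    0.778, 0.224, 0.458,
    0.890, 0.248, 0.410, 0.819,
    0.374, 0.894, 0.286, 0.315, 0.364), 6)
}

mlh1_correlation <- function() {
  lower_tri_correlation(c(
    0.432,
    0.138, 0.303,
    0.331, 0.709, 0.292,
    0.679, 0.576, 0.146, 0.440,
    0.272, 0.600, 0.268, 0.660, 0.308,
    0.311, 0.421, 0.538, 0.518, 0.307, 0.443,
    0.113, 0.585, 0.453, 0.668, 0.262, 0.417, 0.449,
    0.610, 0.498, 0.065, 0.378, 0.710, 0.299, 0.210, 0.160), 9)
}

ptprd_cpgs <- function() c("cg08719869", "cg09371281", "cg09781601",
                           "cg13723825", "cg14080967", "cg14458619")
mlh1_cpgs <- function() c("cg02103401", "cg04726821", "cg04841293",
                          "cg05670953", "cg10990993", "cg11291081",
                          "cg18320188", "cg21109167", "cg24607398")

# virtual-dataset design grid: 10 CpGs, 1000 cases + 1000 controls,
# exchangeable correlation r in {0.2, 0.4, 0.6, 0.8}
scenario_table <- function() {
  list(
    "1.1" = list(family = "same",  causal = integer(), grid = numeric()),
    "1.2" = list(family = "same",  causal = 1L,        grid = seq(0.5, 1.0, 0.1)),
    "1.3" = list(family = "same",  causal = c(1L, 2L), grid = seq(0.1, 0.5, 0.1)),
    "2.1" = list(family = "diff",  causal = integer(), grid = numeric()),
    "2.2" = list(family = "diff",  causal = 1L,        grid = seq(0.5, 1.0, 0.1)),
    "2.3" = list(family = "diff",  causal = 5L,        grid = seq(0.5, 1.0, 0.1)),
    "2.4" = list(family = "diff",  causal = 10L,       grid = seq(0.5, 1.0, 0.1)),
    "2.5" = list(family = "diff",  causal = c(1L, 5L), grid = seq(0.1, 0.5, 0.1)),
    "2.6" = list(family = "diff",  causal = c(1L, 10L), grid = seq(0.1, 0.5, 0.1)),
    "2.7" = list(family = "diff",  causal = c(5L, 10L), grid = seq(0.1, 0.5, 0.1)),
    "PTPRD" = list(family = "ptprd", causal = 1L, grid = c(4, 5)),
    "MLH1"  = list(family = "mlh1",  causal = 1L, grid = c(4, 5))
  )
}

DIFF_MEANS <- c(0.2, 0.2, 0.3, 0.4, 0.5, 0.5, 0.6, 0.7, 0.8, 0.8)

#' List the built-in simulation scenarios
#'
#' @return A data frame describing each built-in scenario: label, marginal
#'   family, number of CpGs, causal CpG locations, the effect-size grid the
#'   design varies over, and the case/control quotas.
#' @export
list_scenarios <- function() {
  tab <- scenario_table()
  data.frame(
    label = names(tab),
    family = vapply(tab, function(x) switch(x$family,
      same  = "10 CpGs, common mean (default 0.6)",
      diff  = "10 CpGs, means 0.2-0.8",
      ptprd = "6 CpGs, PTPRD template correlations",
      mlh1  = "9 CpGs, MLH1 template correlations"), ""),
    n_cpgs = vapply(tab, function(x) switch(x$family, same = 10L, diff = 10L,
                                            ptprd = 6L, mlh1 = 9L), 0L),
    causal = vapply(tab, function(x)
      if (length(x$causal)) paste(x$causal, collapse = ",") else "-", ""),
    effect_grid = vapply(tab, function(x)
      if (length(x$grid)) paste(format(x$grid), collapse = "/") else "-", ""),
    n_cases = vapply(tab, function(x)
      if (x$family %in% c("ptprd", "mlh1")) 50L else 1000L, 0L),
    n_controls = vapply(tab, function(x)
      if (x$family %in% c("ptprd", "mlh1")) 50L else 1000L, 0L),
    row.names = NULL
  )
}

#' Build a built-in scenario
#'
#' Instantiates one row of the benchmark design: ten exchangeably correlated
#' CpGs with a common mean (`"1.1"`-`"1.3"`), ten CpGs with distinct means
#' 0.2-0.8 (`"2.1"`-`"2.7"`), or one of the two gene-region templates with
#' printed correlation matrices (`"PTPRD"`, 6 CpGs; `"MLH1"`, 9 CpGs). The
#' virtual scenarios use 1000 cases and 1000 controls; the templates use 50
#' of each.
#'
#' @param label Scenario label (see [list_scenarios()]).
#' @param r Exchangeable pairwise correlation for the virtual scenarios
#'   (ignored by the templates, which carry their own matrices).
#' @param effect Effect size \eqn{\beta_j} shared by the causal CpGs;
#'   required when the scenario has causal CpGs.
#' @param mean Common marginal mean for the `"1.x"` scenarios (the design
#'   varies it over 0.2/0.4/0.6/0.8; default 0.6) and for the template
#'   scenarios, whose marginal means are not part of the printed templates.
#' @param precision Beta precision shared by all CpGs (default 10).
#' @return A [scenario_spec()].
#' @examples
#' sc <- cpg_scenario("1.1", r = 0.2)
#' sc$n_cases
#' @export
cpg_scenario <- function(label, r = NULL, effect = NULL, mean = 0.6,
                         precision = 10) {
  tab <- scenario_table()
  label <- as.character(label)
  if (!label %in% names(tab)) {
    stop(sprintf("unknown scenario '%s'; see list_scenarios()", label), call. = FALSE)
  }
  row <- tab[[label]]

  if (row$family %in% c("same", "diff")) {
    if (is.null(r)) stop("scenario requires an exchangeable correlation 'r'", call. = FALSE)
    means <- if (row$family == "same") rep(mean, 10) else DIFF_MEANS
    corr <- exchangeable_correlation(10, r)
    n_cases <- n_controls <- 1000L
    ids <- sprintf("cpg%02d", 1:10)
  } else {
    means <- rep(mean, if (row$family == "ptprd") 6 else 9)
    corr <- if (row$family == "ptprd") ptprd_correlation() else mlh1_correlation()
    n_cases <- n_controls <- 50L
    ids <- if (row$family == "ptprd") ptprd_cpgs() else mlh1_cpgs()
  }
  dimnames(corr) <- list(ids, ids)

  template <- row$family %in% c("ptprd", "mlh1")
  if (length(row$causal) && (!template || !is.null(effect))) {
    # the gene templates cover both designs: effect absent means the null
    # (type I error) configuration, effect present the single causal CpG
    if (is.null(effect)) {
      stop(sprintf("scenario '%s' has causal CpGs; supply 'effect'", label),
           call. = FALSE)
    }
    dis <- disease_model(causal_indices = row$causal,
                         effects = rep(effect, length(row$causal)))
  } else {
    dis <- disease_model()
  }

  marg <- lapply(means, beta_marginal, precision = precision)
  sc <- scenario_spec(marg, corr, dis, n_cases, n_controls, label)
  sc$cpg_ids <- ids
  sc
}

## Quota sampling -------------------------------------------------------------

#' Sample a case/control methylation dataset from a scenario
#'
#' Individuals are generated prospectively: a methylation row is drawn from
#' the scenario's copula, the disease status is a Bernoulli draw with the
#' logistic disease probability, and individuals are retained until the case
#' and control quotas are both met. Rows are returned in randomized order.
#' When the scenario has no causal CpG the disease probability is a constant,
#' so retention does not alter the methylation distribution; the sampler then
#' draws exactly the required rows and assigns a shuffled quota phenotype,
#' which is distributionally identical and much faster.
#'
#' @param scenario A [scenario_spec()].
#' @param seed Optional integer seed (same seed, same dataset). The caller's
#'   RNG state is restored on exit.
#' @param draw_budget Maximum number of prospective draws, as a multiple of
#'   the total quota; exceeded budgets raise an error reporting the
#'   acceptance rates.
#' @return A list with elements `G` (n x p beta-value matrix with CpG column
#'   names), `y` (0/1 phenotype vector), and `scenario_label`.
#' @export
sample_case_control <- function(scenario, seed = NULL, draw_budget = 1000) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n_cases <- scenario$n_cases
  n_controls <- scenario$n_controls
  n <- n_cases + n_controls
  model <- scenario$disease
  model$intercept <- resolve_intercept(model, scenario$marginals)

  if (length(model$causal_indices) == 0) {
    # phenotype independent of methylation: exact shortcut
    G <- sample_correlated_beta(scenario$copula, n)
    y <- sample(rep(c(1L, 0L), c(n_cases, n_controls)))
  } else {
    got_cases <- 0L; got_controls <- 0L
    Gc <- vector("list", 0L); Gk <- vector("list", 0L)
    drawn <- 0L
    budget <- draw_budget * n
    while (got_cases < n_cases || got_controls < n_controls) {
      need_cases <- n_cases - got_cases
      need_controls <- n_controls - got_controls
      batch <- min(max(2L * (need_cases + need_controls), 200L), budget - drawn)
      if (batch <= 0L) {
        stop(sprintf(paste0("case/control quota not reached within the draw ",
                            "budget (%d draws); acceptance rates: cases %.4f,",
                            " controls %.4f"),
                     drawn, got_cases / drawn, got_controls / drawn),
             call. = FALSE)
      }
      Gb <- sample_correlated_beta(scenario$copula, batch)
      pb <- outcome_probability(Gb, model)
      yb <- stats::rbinom(batch, 1L, pb)
      drawn <- drawn + batch
      ic <- which(yb == 1L); ik <- which(yb == 0L)
      if (length(ic) > need_cases) ic <- ic[seq_len(need_cases)]
      if (length(ik) > need_controls) ik <- ik[seq_len(need_controls)]
      if (length(ic)) Gc[[length(Gc) + 1L]] <- Gb[ic, , drop = FALSE]
      if (length(ik)) Gk[[length(Gk) + 1L]] <- Gb[ik, , drop = FALSE]
      got_cases <- got_cases + length(ic)
      got_controls <- got_controls + length(ik)
    }
    G <- rbind(do.call(rbind, Gc), do.call(rbind, Gk))
    y <- rep(c(1L, 0L), c(n_cases, n_controls))
    ord <- sample.int(n)
    G <- G[ord, , drop = FALSE]
    y <- y[ord]
  }

  colnames(G) <- if (!is.null(scenario$cpg_ids)) scenario$cpg_ids else
    sprintf("cpg%02d", seq_len(ncol(G)))
  rownames(G) <- sprintf("s%04d", seq_len(n))
  list(G = G, y = y, scenario_label = scenario$label)
}

## Scenario files -------------------------------------------------------------

#' Read a scenario from a YAML or JSON file
#'
#' The file needs keys `marginals` (list of `{mean, precision}`),
#' `correlation` (either a dense matrix or `{exchangeable: r, p: p}`),
#' `disease` (`{intercept, causal_indices, effects}`, all optional), and
#' optionally `n_cases`, `n_controls`, `label`. Built-in labels can be
#' instantiated directly with [cpg_scenario()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A [scenario_spec()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("scenario file '%s' not found", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$marginals)) stop("scenario file lacks 'marginals'", call. = FALSE)
  marg <- if (is.data.frame(cfg$marginals)) {
    mapply(beta_marginal, cfg$marginals$mean,
           if (is.null(cfg$marginals$precision)) 10 else cfg$marginals$precision,
           SIMPLIFY = FALSE)
  } else {
    lapply(cfg$marginals, function(m)
      beta_marginal(m$mean, if (is.null(m$precision)) 10 else m$precision))
  }
  p <- length(marg)
  corr <- cfg$correlation
  if (is.list(corr) && !is.null(corr$exchangeable)) {
    corr <- exchangeable_correlation(if (is.null(corr$p)) p else corr$p,
                                     corr$exchangeable)
  } else {
    corr <- as.matrix(corr)
    storage.mode(corr) <- "double"
  }
  dis <- disease_model(
    intercept = cfg$disease$intercept,
    causal_indices = if (is.null(cfg$disease$causal_indices)) integer()
                     else cfg$disease$causal_indices,
    effects = if (is.null(cfg$disease$effects)) numeric() else cfg$disease$effects
  )
  scenario_spec(marg, corr, dis,
                n_cases = if (is.null(cfg$n_cases)) 1000 else cfg$n_cases,
                n_controls = if (is.null(cfg$n_controls)) 1000 else cfg$n_controls,
                label = if (is.null(cfg$label)) basename(path) else cfg$label)
}
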