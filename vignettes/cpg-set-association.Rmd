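---
title: "Set-based association testing for CpG methylation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-based association testing for CpG methylation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgset)
```

## The problem

Epigenome-wide association studies (EWAS) scan DNA methylation markers for
differences between disease groups. Methylation at a CpG site is summarized
by a beta-value in $[0,1]$ (0 unmethylated, 1 fully methylated), and
neighbouring CpGs are often strongly correlated, forming blocks analogous to
linkage-disequilibrium blocks of SNPs. Testing each CpG separately and
Bonferroni-correcting ignores that structure twice over: it pays a
multiplicity price for tests that are nearly redundant, and it cannot pool
evidence spread across a correlated block. `cpgset` implements the joint
alternative: test the association between a binary phenotype $y$ and a whole
CpG *set* $G = (G_{i1},\dots,G_{ip})$ at once, under the logistic model

$$\mathrm{logit}\,P(y_i = 1) = \alpha_0 + \alpha' X_i + \beta' G_i,$$

with $H_0: \beta = 0$ and optional covariates $X_i$.

## The seven tests

Seven set-level tests share this interface (`G`, `y`, optional `X`) and
return a statistic with a p-value:

* **PCA** (`pca_test`): the $p$ CpGs are replaced by the $k$ leading
  principal components explaining at least 80% of total variance (the
  threshold is an argument), and the components are tested jointly by a
  $k$-df likelihood ratio test in the logistic model. Columns are centered
  but not variance-scaled — beta-values already share the $[0,1]$ scale — a
  correlation-based variant is available via `scale = TRUE` in
  `pca_reduce()`.
* **SPCA** (`spca_test`): supervised PCA. CpGs are first screened by their
  univariate logistic score statistics; the screening threshold is chosen
  from a fraction grid $\{0.1,\dots,1.0\}$; the first principal component of
  the surviving CpGs enters a logistic fit, and the statistic is the Wald
  ratio $T = \hat\beta_1/se(\hat\beta_1)$. Because screening looks at the
  outcome, $T$ has no usable closed-form null; the p-value comes from a
  full-procedure permutation null (screening redone on every permuted
  dataset), which accounts for the selection exactly at the cost of being
  Monte Carlo.
* **KPCA** (`kpca_test`): kernel PCA with the radial basis kernel
  $K_{ij} = \exp(-\sigma\|G_i - G_j\|^2)$, $\sigma = 0.01$ by default. Note
  the *inverse-width* convention ($\sigma$ multiplies the squared distance
  directly, as in the kernlab family); it differs from the
  $\exp(-d^2/2\sigma^2)$ bandwidth convention by a factor $2\sigma^2$. The
  kernel is double-centered, eigendecomposed, and the leading kernel
  components (80% of the eigenvalue mass) are tested with the same $k$-df
  LRT as linear PCA. With `kernel = "linear"` the procedure reduces exactly
  to PCA.
* **SKAT** (`skat_test`): the sequence kernel association test. CpG effects
  are modelled as random with variance $w_j \tau$; the score statistic for
  $H_0: \tau = 0$ is $Q = (y-\hat\mu)' G W W G' (y-\hat\mu)$ with
  $\hat\mu$ from the null logistic fit and, for methylation, equal weights
  $w_j = 1$. Under $H_0$, $Q$ is a weighted mixture of $\chi^2_1$ variables
  whose weights are the eigenvalues of $W G' P_0 G W$, with
  $P_0 = V - VX(X'VX)^{-1}X'V$ the projected working variance.
* **SIR** (`sir_test`): sliced inverse regression. $G$ is standardized to
  $Z = \Sigma_{GG}^{-1/2}(G - \bar G)$, the samples are sliced by the
  response (two slices for a binary $y$), and the weighted between-slice
  covariance $\sum_h \hat p_h \hat m_h \hat m_h'$ is eigendecomposed. As a
  significance test we use the classical dimension test of "no directions":
  $n \sum_j \hat\lambda_j \sim \chi^2_{p(H-1)}$.
* **Hotelling's $T^2$** (`hotelling_t2_test`): the classical two-sample
  multivariate mean comparison with pooled covariance and the exact $F$
  reference.
* **min-p t-test** (`minp_bonferroni_t_test`): the single-marker benchmark —
  per-CpG two-sample t-tests, set p-value $= \min(1, p\cdot\min_j p_j)$.
  Pooled variance by default, Welch behind `var_equal = FALSE`.

`run_set_tests()` applies any battery of these to one dataset.

```{r battery}
scenario <- cpg_scenario("PTPRD", mean = 0.5)
dat <- sample_case_control(scenario, seed = 1)
run_set_tests(dat$G, dat$y, methods = c("PCA", "SKAT", "T2", "MINP_T"))
```

## Design choices where the methodology was open

Several components required concrete choices that the general methodology
leaves open; they are collected here.

**SPCA null distribution.** Supervised-PC theory offers an asymptotic
reference distribution for the post-selection Wald statistic, but its exact
form depends on details of the screening rule. We use a full-procedure
permutation null instead: it is exact at any sample size for any selection
rule, at a per-test cost of $B$ refits (default $B = 199$, floor
$p = 1/(B+1)$). The Monte Carlo benchmarks confirm the nominal level.

**SPCA screening-size selection.** The retained screening fraction is the
one whose PC1 carries the strongest association with the phenotype. Three
rules are provided: the logistic *score* statistic of each candidate PC1
(default), the maximized likelihood ratio (`"lrt"`), and $K$-fold
cross-validated held-out log-likelihood (`"cv"`). The score rule is the
default because it is deterministic, asymptotically equivalent to the LRT
rule for this one-degree comparison, and an order of magnitude cheaper
inside the permutation loop; validity is unaffected because the permutation
null re-runs whichever rule is active. PC1 directions of candidate subsets
do not depend on the phenotype labels, so they are cached across
permutations, and the default no-covariate path runs the whole permutation
loop in compiled code (the interpreted and compiled procedures are asserted
equal in the test suite).

**KPCA and SIR p-values.** Neither method prescribes a test for a binary
outcome by itself. For symmetry with PCA, the retained kernel components
enter the same $k$-df logistic LRT; for SIR we adopt the standard
chi-square dimension test. Both hold their level in the null benchmarks
below.

**Numerics of the mixture-of-chi-square tail.** `quadform_pvalue()`
evaluates $P(\sum_m \lambda_m \chi^2_{1,m} > q)$ by characteristic-function
inversion (the Imhof/Davies integral) with adaptive quadrature, split at
$u = 1$ where the integrand changes character. A one-component mixture is
evaluated as an exact scaled chi-square tail. If the inversion fails
numerically or leaves $[0,1]$, the Liu–Tang–Zhang moment-matching
approximation is used and flagged in the result's diagnostics. The inversion
is verified against a $10^6$-draw Monte Carlo tail in the test suite.
Eigenvalues below $10^{-10}\lambda_{max}$ are dropped; SIR's standardization
adds a ridge of $10^{-8}\,\mathrm{tr}(\Sigma)/p$ when the covariance is
near-singular; zero-variance CpG columns are dropped with a warning before
PCA, SPCA and the t-tests (SKAT tolerates them natively — they contribute
zero).

## The synthetic-data generator

`cpgset` ships a generator for the correlated beta-distributed methylation
data used in the benchmarks, because joint calibration claims can only be
checked against data whose dependence structure is known exactly.

Each CpG has a beta marginal parameterized by mean $\mu_j$ and precision
$\phi_j$ (`beta_marginal`). Dependence comes from a Gaussian copula: a
latent multivariate normal row is pushed through $\Phi$ and the beta
quantile functions. The latent correlation needed to induce a desired
*Pearson* correlation between beta-values is found pair by pair
(`calibrate_copula`) by a monotone root search, evaluating the induced
correlation with 48-node Gauss–Hermite quadrature; targets outside the
attainable (Fréchet) range raise an error naming the pair. If the
pairwise-assembled latent matrix is indefinite it is projected to the
nearest positive semidefinite correlation matrix (eigenvalue clipping at
$10^{-8}$, rescaled diagonal) and the induced correlations are re-evaluated
and stored in the spec's diagnostics.

Choices worth knowing:

* **Precision $\phi_j = 10$** by default (configurable). The benchmark
  designs fix only the marginal means (0.2–0.8); $\phi = 10$ gives
  methylation-like spread at every mean without boundary pile-up
  (e.g. mean 0.6 is Beta(6,4), sd $\approx$ 0.15).
* **Gaussian copula.** The simplest family with one monotone dependence
  knob per pair; only distributional reproduction of the published
  benchmarks is possible in any case, since their random streams are not
  recoverable.
* **Template marginals.** The two gene-region templates (PTPRD, MLH1)
  print only correlation matrices; their marginal means default to 0.5,
  $\phi = 10$, configurable. Type-I-error behaviour is driven by the
  correlation structure.
* **Tabulated quantile transform.** Sampling maps latent normals through
  `qbeta(pnorm(z))`; each marginal carries a 16385-knot lookup table with
  linear interpolation (absolute error $< 10^{-7}$ for $|z| < 6.5$,
  verified in the tests), which makes large simulation sweeps several times
  faster. `exact = TRUE` bypasses the tables.

The disease model is prospective logistic:
$\mathrm{logit}\,P(D_i = 1) = \beta_0 + \sum_j \beta_j G_{ij}$ over the
causal CpGs. When $\beta_0$ is not given it defaults to
$-\sum_j \beta_j \mu_j$, centring the linear predictor so the expected
prevalence is about one half — matching the balanced case/control quotas
and keeping rejection sampling efficient. `sample_case_control()` draws
individuals prospectively and keeps them until the case and control quotas
are exactly met (draw budget 1000x the quota, with the acceptance rate
reported on failure). With no causal CpG the disease probability is
constant, so retention cannot alter the methylation distribution; the
sampler then draws exactly the needed rows and assigns a shuffled quota
phenotype — distributionally identical and much faster.

What the generator deliberately does **not** emulate: batch effects,
group-specific variances, cell-type composition, probe artefacts, or any
mean–variance coupling beyond the beta family's own. Passing the null
benchmarks says the tests hold their level under a clean, exactly-known
correlation structure — not that they are robust to those real-data
complications.

## The benchmark scenario library

`cpg_scenario()` instantiates the built-in designs (see
`list_scenarios()`): ten exchangeably correlated CpGs with a common mean
("1.1"–"1.3"; the mean defaults to 0.6 and the published grid also uses
0.2/0.4/0.8), ten CpGs with distinct means 0.2–0.8 ("2.1"–"2.7", causal
CpGs at positions {1}, {5}, {10}, {1,5}, {1,10} or {5,10}), and the two
real-template sets with printed correlation matrices ("PTPRD", 6 CpGs;
"MLH1", 9 CpGs; 50 cases + 50 controls; effect grid {4, 5} on the first
CpG). Exchangeable correlations run over $r \in \{0.2, 0.4, 0.6, 0.8\}$.
Custom scenarios come from `scenario_spec()` or YAML/JSON files
(`read_scenario`).

## The Monte Carlo harness

`estimate_rejection_rate()` draws `n_replications` datasets from a scenario
and reports, per method, the fraction of p-values at or below `alpha` —
the empirical type I error under a null scenario, power otherwise.
Replication $t$ is seeded `base_seed + t`, so any single replication is
reproducible in isolation and results cannot depend on execution order;
all methods see the same dataset within a replication (common random
numbers). Using one `base_seed` across the cells of a correlation grid
pairs the estimates, which sharpens trend comparisons. Method errors are
caught and counted separately — never coerced to non-rejections — and a
summary with more than 1% errored replications is marked invalid.
`type1_table()` and `power_curve()` arrange the sweeps in the layout of the
published tables and figures.

```{r harness}
estimate_rejection_rate(cpg_scenario("PTPRD", mean = 0.5),
                        c("SKAT", "T2", "MINP_T"),
                        n_replications = 200, alpha = 0.05, base_seed = 42)
```

Problem sizes in the shipped test suite: the virtual-design cells are
verified at the published scale (5000 replications, 1000 cases + 1000
controls); the power-ordering comparison uses 500 replications, and the
power-versus-correlation trend 50 replications per grid point with common
random numbers and permutation size $B = 99$ — at those sizes KPCA's
$n \times n$ eigenproblem (handled by a rank-revealing pivoted Cholesky for
$n > 600$) stays the dominant cost. These are the package's choices for a
single-machine reproduction; any of them can be scaled up through the
harness arguments.

## Known limitations

* The SPCA p-value is Monte Carlo with resolution $1/(B+1)$; genome-wide
  use would need larger $B$ or a sequential stopping rule.
* SIR for a binary outcome has only two slices, hence at most one
  direction; its dimension test wastes $p-1$ degrees of freedom, which is
  visible as low power (consistent with the published comparison).
* The Wald statistic used by SPCA is subject to the Hauck–Donner effect
  under near-separation; the permutation null keeps the test valid, but
  power can dip for overwhelming effects.
* Hotelling's $T^2$ assumes multivariate normality that beta-values violate;
  at the benchmark sample sizes the central limit theorem covers this, but
  small-sample behaviour on skewed marginals is not guaranteed.
* The generator's independence shortcut for null scenarios, the quota
  sampler, and the copula calibration are all exercised by the test suite,
  but only for the beta-marginal family; other marginal families would need
  their own quantile tables and Fréchet-bound checks.
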