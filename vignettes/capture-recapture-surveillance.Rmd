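---
title: "Two-source capture-recapture for disease surveillance: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-source capture-recapture for disease surveillance: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualcapture)
```

## The problem

Chronic neurodegenerative conditions such as Alzheimer's disease are
under-ascertained by any single surveillance channel: memory-clinic
registries see patients who seek specialist care, while insurance claims
systems see patients through copayment exemptions and
condition-specific drug reimbursements. Neither list is complete, and
their union is not the population either. Capture-recapture treats the
two lists as two "capture occasions" over a closed population: the
overlap between them carries information about how many cases neither
list saw.

`dualcapture` implements the full chain for exactly two sources: linking
case lists into capture histories, closed-form estimation, a
covariate-stratified estimator, a Bayesian closed-population M~t~ model,
and the derived surveillance quantities (source completeness, prevalence
against a census denominator). Because real case lists of this kind are
confidential, the package also ships a synthetic surveillance generator
with the same statistical structure the analysis assumes, so every stage
is testable end to end.

## Capture histories

Exact-key linkage of the deduplicated lists yields three observed
counts: $m$ (cases in both lists), $a$ (source A only), $b$ (source B
only), with list sizes $n_1 = m + a$, $n_2 = m + b$ and observed union
$u = m + a + b$. Probabilistic name-based linkage is out of scope here:
the package assumes an upstream linkage step has produced a shared
person key, and the synthetic generator emits such keys directly.

Within-source duplicates (repeat visits, repeat claims) are collapsed to
one record per person, keeping the first occurrence's demographics.
Repeat records disagreeing by more than one year of age, or on gender,
trigger a warning (or an error in strict mode): tolerance of a one-year
discrepancy reflects ages recorded in different calendar years of a
two-year window. For persons in both lists whose recorded demographics
disagree across sources, source A's values win by default, on the
rationale that administrative insurance records carry verified
civil-status data; the preference is configurable. How such
discordances should be resolved is genuinely open — registry practice
varies — so the rule is a package decision, exposed as an argument.

## Closed-form estimators

Under source independence and homogeneous catchability, the
Lincoln-Petersen estimator is

$$\hat N = \frac{n_1 n_2}{m}, \qquad
\widehat{\mathrm{Var}} = \frac{n_1 n_2 (n_1 - m)(n_2 - m)}{m^3},$$

with Wald 95% interval $\hat N \pm 1.96\sqrt{\widehat{\mathrm{Var}}}$.
Chapman's nearly unbiased variant,

$$\hat N = \frac{(n_1+1)(n_2+1)}{m+1} - 1, \qquad
\widehat{\mathrm{Var}} =
\frac{(n_1+1)(n_2+1)(n_1-m)(n_2-m)}{(m+1)^2(m+2)},$$

shrinks the estimate slightly, remains defined at $m = 0$, and is the
fallback for zero-overlap strata. Point estimates, interval bounds and
half-widths are rounded half away from zero to integers — the reporting
convention of the surveillance literature — while exact values are kept
on the result object for downstream arithmetic (completeness uses the
unrounded estimate; at these magnitudes the one-decimal results are
identical either way). Intervals are plain Wald on the count scale: no
log-transform or profile likelihood, matching how such studies print
their bounds.

The stratified estimator applies the base estimator within each stratum
and sums; variances add under independence across strata, with no
finite-population correction. Stratification addresses *heterogeneous
catchability*: if capture probabilities vary with age or gender and the
two sources skew differently, the pooled estimator is biased, while
within-stratum homogeneity restores validity stratum by stratum.

## Stratification scheme

The default scheme crosses three age classes with gender, six strata in
all. The age classes are $\le 84$, $85$–$89$, $\ge 90$: class
boundaries follow the covariate coding used in elderly-dementia
surveillance, and the two boundary ages (84, 90) are assigned to the
outer classes so the classes partition all ages — the interior class is
preserved exactly. Ages are age at first capture in the study window;
each person carries a single age.

## The Bayesian M~t~ model

The M~t~ model lets capture probability vary by occasion (here: by
source) but not by individual within a stratum. Per stratum $s$, the
observed persons are augmented to a super-population of $M_s$ potential
persons with latent inclusion indicators:

$$z_i \sim \mathrm{Bernoulli}(\psi_s), \qquad
y_{ij} \mid z_i \sim \mathrm{Bernoulli}(z_i\, p_{s,j}),
\quad j \in \{A, B\},$$

independent across sources given inclusion. The stratum size is
$N_s = \sum_i z_i$ and the total $N = \sum_s N_s$. Priors are flat —
$p_{s,j} \sim \mathrm{Beta}(1,1)$, $\psi_s \sim \mathrm{Uniform}(0,1)$ —
chosen so the posterior mode sits near the maximum-likelihood solution
and the single-stratum posterior median tracks the Lincoln-Petersen
closed form; this anchors the Bayesian machinery against the frequentist
cross-check on the same counts (the package's tests assert agreement
within 1.5%).

Every complete conditional is conjugate, so the sampler is pure Gibbs
with no tuning parameters:

* $p_{s,j} \mid z \sim \mathrm{Beta}(1 + n_j,\; 1 + D - n_j)$ with
  $D = \sum_i z_i$,
* $\psi_s \mid z \sim \mathrm{Beta}(1 + D,\; 1 + M_s - D)$,
* captured persons have $z_i = 1$ deterministically; the never-captured
  are exchangeable, so their inclusion count is one binomial draw with
  success probability
  $\psi(1-p_A)(1-p_B) / \{\psi(1-p_A)(1-p_B) + 1 - \psi\}$.

A Metropolis-Hastings scheme targeting the same posterior would be
equally valid; conjugacy makes it unnecessary and keeps each iteration
$O(1)$ per stratum, so the default budget — two chains, 5,000 burn-in,
25,000 retained draws — runs in about a second per stratum.

**Augmentation size.** $M_s$ defaults to ten times the observed stratum
union. $M_s$ is an upper support bound, not a prior guess: the fit
errors out if the upper 1% of the $N_s$ posterior reaches $M_s$
(posterior pile-up), which is the signature of an augmentation chosen
too small. Tests assert the posterior median moves by less than 1% when
$M_s$ doubles.

**Starting points and seeding.** Chains start from over-dispersed
inclusion fractions (5% and 95% of the augmented pool for two chains).
All randomness descends from one user seed through a deterministic
(seed, chain, stratum) derivation, so multi-stratum, multi-chain runs
are exactly reproducible and chains are independently seeded.

**Summaries and diagnostics.** Draws pooled across post-burn-in chains
are summarized by mean, median and 95% highest-posterior-density
interval. The HPDI is computed as the shortest window of
$\lceil 0.95 n \rceil$ consecutive sorted draws; width ties take the
lowest lower bound, which makes the interval deterministic on discrete
posteriors such as $N_s$. Convergence is monitored by the Gelman-Rubin
potential scale reduction factor (between/within-chain variance ratio);
any parameter above 1.1 flags the fit non-converged (warning, or error
in strict mode). Constant identical chains make the factor undefined
and return `NA` with a warning rather than dividing by zero. Effective
draw counts use the AR-spectral density at frequency zero, capped at the
total draw count.

The total $N$ is accumulated iteration-wise across strata, so every
retained draw satisfies $N = \sum_s N_s$ and
$u_s \le N_s \le M_s$ exactly — both are asserted as invariants in the
tests.

## Completeness, prevalence, age restriction

Completeness of a source is $100\, n_j / \hat N$; prevalence is
$100\, \hat N / P$ for a census denominator $P$. Both are rounded half
up to one decimal, the convention that reproduces all published
surveillance figures this package's tests check. The shipped
denominators (1,078,729 persons; 234,459 aged 65 and over) are the 2010
census counts for the Alpes-Maritimes department whose surveillance
structure the reference scenario emulates.

An age-restricted total (e.g. 65 and over) is the sum of stratum
estimates whose age class lies entirely above the cutoff. The default
scheme's lowest class ($\le 84$) straddles 65, so a 65 cutoff is
refused with an error rather than silently approximated; published 65+
totals derived from unpublished stratum data can be passed to the
pipeline as given inputs, and their prevalence arithmetic is then exact.

## The synthetic generator

The generator draws a closed population of `true_N` persons with
integer ages from a truncated normal on $[40, 110]$ and a global female
fraction; age and gender determine the stratum, and capture depends on
demographics *only through the stratum* — exactly the covariate
structure the stratified and M~t~ analyses assume. Per stratum, the
capture pattern (both / A only / B only / neither) is drawn from the two
capture probabilities and a dependence parameter `delta`: the joint
probability solves the 2×2 cell system with odds ratio $1 + \delta$ at
fixed marginals (a Plackett-type coupling). `delta = 0` gives exact
independence; `delta > 0` inflates joint capture without moving either
marginal, so dependence studies are not confounded with catchability
changes — and any `delta ≥ 0` is feasible by construction. Positive
dependence inflates the overlap and biases Lincoln-Petersen downward;
the tests assert that direction on simulated replicates.

`reference_scenario()` packages a calibrated instance: expected list
sizes ≈ 3,824 (insurance-like source A) and ≈ 2,594 (clinic-like source
B), expected overlap ≈ 856, A-list mean age near 86.1 with F/M near
3.2, B-list mean age near 82.2 with about 71% female. The calibration
fixes the latent population at $N = 11{,}528$, ages TN(82.2, 6.5), 72.1%
female, with insurance-source capture rising steeply after age 84 and
clinic-source capture nearly flat in age — the mechanism that
age-separates the two lists as observed. These latent values were fitted
once by penalized least squares to the nine observed marginals and then
frozen; they are a modelling choice, not an estimate of any real
population, and the real latent truth is precisely what the method
exists to estimate.

What the generator does *not* emulate: the captured lists' age
standard deviations are wider than the observed ones (about 6.0 vs 4.5
years for the insurance list) — class-constant capture probabilities
cannot compress a list's age spread below the within-class spread; the
joint age×gender×source cross-tabulation of the real data was never
published, so only marginals are matched; and the population is closed —
no entry, death or diagnostic misclassification over the window.
Passing tests therefore demonstrate correctness of the estimators under
the model's own assumptions, not robustness to the ways real
surveillance data violate them.

`reference_fixture()` is the deterministic companion: two lists that
link to exactly the reference capture-history counts (856/2,968/1,738),
with ages from per-list normal quantiles and genders at fixed fractions,
both decorrelated from the person-key order by coprime-stride
permutations so that all six strata contain every capture pattern. It
drives the exact-reproduction tests and the acceptance script.

## Numerical and design choices

* Rounding: half away from zero, integers for population sizes, one
  decimal for percentages. Validated against every published figure the
  package reproduces.
* The published Chapman point estimate for the reference counts (11,595)
  is inconsistent with the standard Chapman formula, which gives
  ≈ 11,581.1 — the printed formula string lost its divisor. The package
  implements and tests the standard closed form; the published
  half-width 559 is consistent with the standard variance and is
  asserted as printed.
* Degenerate inputs: zero-overlap tables route Lincoln-Petersen users to
  Chapman; empty tables are rejected for overlap proportions; empty
  stratum tables are dropped from the M~t~ fit; a zero within-chain
  variance returns a flagged `NA` diagnostic.
* Determinism: one seed drives simulation and sampling; identical
  configurations yield byte-identical reports and data files (output
  paths are excluded from the provenance hash for that reason).
* Problem sizes in the test suite — 500 replicates for the
  Lincoln-Petersen bias check at $N = 10{,}000$, 50 replicates of the
  M~t~ recovery study at $N = 1{,}000$ with halved burn-in/retention,
  60 seeds for the generator calibration check — were chosen as the
  smallest runs whose Monte-Carlo error is comfortably below the
  tolerances they assert.

## Worked example

```{r example, eval = FALSE}
fx <- reference_fixture()
tab <- link_sources(dedupe_cases(fx$A), dedupe_cases(fx$B))
lincoln_petersen(tab)
chapman(tab)
fit <- fit_mt(tab, mcmc_config(seed = 42))
fit$summary["N_total", ]
completeness(tab$n1, lincoln_petersen(tab)$n_hat_exact)
prevalence(lincoln_petersen(tab)$n_hat, 1078729)
```

`run_pipeline(default_config(seed = 42))` composes every stage on the
stochastic reference scenario and emits a consolidated JSON report with
provenance (seed, config hash, package version).

## Limitations

Two lists identify population size only under assumptions that cannot be
tested from the two lists alone: closure, perfect linkage, source
independence (or dependence fully captured by the strata), and
within-stratum homogeneity. The stratified and M~t~ estimates correct
for demographic catchability differences but not for residual
dependence; log-linear models for three or more lists, behavioral or
individual-heterogeneity models (M~b~, M~h~), and open-population
dynamics are out of scope.
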