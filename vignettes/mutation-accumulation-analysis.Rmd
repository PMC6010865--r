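---
title: "Estimating mutation parameters from MA line field experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation parameters from MA line field experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutaccum)
```

## The problem

Mutation accumulation (MA) lines are inbred lineages propagated by
single-seed descent from a common founder, so that spontaneous mutations
fix in different lines with minimal selection. After $t$ generations, the
variance among line means for a phenotype estimates the genetic variance
contributed by accumulated mutations, and three standard quantities
summarize it:

* **Mutational variance** $V_m = V_l / (2t)$, the per-generation input of
  genetic variance, where $V_l$ is the among-line variance.
* **Mutational heritability** $h^2_m = V_m / V_e$, the per-generation rate
  of increase in heritability, with $V_e$ the residual (environmental)
  variance.
* **Mutational coefficient of variation**
  $CV_m = 100\sqrt{V_m}/\bar{x}$ for traits on the measurement scale, or
  $100\sqrt{e^{V_m}-1}$ for traits modelled on the log scale.

`mutaccum` implements the full analysis chain for a multi-season field
assay of *Arabidopsis thaliana* MA lines: a synthetic-data generator with
the assay's hierarchical design, variance-component model fitting by
maximum likelihood and by MCMC, parametric-bootstrap selection of random
effects, posterior transformation into mutation parameters, and
founder-versus-MA mean comparisons.

## The model

For one trait in one season, the observation model is a generalized
linear mixed model with random intercepts,

$$\eta_{ijkl} = \mu + b_j + a_k + s_{kl}, \qquad
  b_j \sim N(0, V_B),\; a_k \sim N(0, V_l),\; s_{kl} \sim N(0, V_S),$$

with block $j$, MA line $k$, and field subline $l$ nested in line. The
response family follows the trait type:

* Gaussian (biomass g, fruit length mm): $y = \eta + e$,
  $e \sim N(0, V_e)$, identity link.
* Poisson (flower, fruit, aborted-fruit counts, composite fitness):
  $y \sim \text{Pois}(e^{\eta + e})$ with an observation-level
  (lognormal) deviate $e \sim N(0, V_e)$ serving as the count-scale
  residual. This overdispersion component is what enters $h^2_m$ for
  count traits; the alternative mean-dependent observation variance is
  deliberately not used.
* Binomial (germination, survival, flowering): $y \sim
  \text{Bern}(\text{logit}^{-1}(\eta + e))$. The latent residual variance
  is not identifiable for Bernoulli data and is fixed at $V_e = 1$, which
  is why $h^2_m$ equals $V_m$ numerically for every binary trait.

Each season is analyzed separately, on MA rows only: unequal replication
of the founder makes a joint fit unattractive, and cross-season genetic
covariances are out of scope.

Conditioning rules decide which plants contribute: germination is scored
on everything planted, survival and composite fitness on everything
transplanted to the field, and all remaining traits on survivors only.
Composite fitness is survival × filled fruits with dead plants counted as
zero, computed at load time when absent.

## Random-effect selection by parametric bootstrap

Whether block and subline variances belong in the final model is decided
by a parametric bootstrap on likelihood-ratio statistics
(`parametric_bootstrap()`, `select_model()`): fit the full and reduced
model by (Laplace-approximate) maximum likelihood, simulate $B$ datasets
from the fitted reduced model, refit both models on each, and report
$p = \#\{LR^* \ge LR_{obs}\}/B$ — ties count toward the null, and the
$(1+\#)/(B+1)$ correction is available behind a flag. The among-line term
is exempt from removal (it is the estimand) but is itself bootstrap-tested
to produce the per-trait, per-season p-values of the significance grid.
Terms are tested marginally against the full model by default; a
sequential mode (testing against the shrinking model) is provided, since
either reading of "a series of model pairs" is defensible.

ML fits use `lme4` (`lmer` with ML, `glmer` with the Laplace
approximation) so that nested deviances are on a common objective;
a model with no random terms falls back to `lm`/`glm` on the same
likelihood. REML is available for Gaussian estimation but never used in
likelihood-ratio comparisons.

Two numerical notes. First, boundary variance estimates make $LR = 0$
about half the time under the null, so null p-values have an atom at 1:
their distribution is uniform below $\sim 0.5$ and conservative above.
Calibration checks therefore test the rejection rate two-sided and the
KS uniformity one-sided (against anti-conservatism); two-sided uniformity
is false by construction for boundary tests. Second, replicates whose
refits fail to converge are dropped and counted; more than 10% failures
aborts the test rather than silently biasing it.

## Bayesian estimation

Final estimates come from an MCMC fit (`fit_mcmc()`), because posterior
means and quantile intervals behave better than Laplace point estimates
for non-Gaussian traits with small variance components. The sampler is:

* Gaussian: fully conjugate blocked Gibbs — normal updates for the
  intercept (improper flat prior by default) and each random-effect
  vector, inverse-gamma updates for each variance.
* Poisson/binomial: a latent linear predictor per observation updated by
  vectorized random-walk Metropolis (step size adapted to ~44%
  acceptance during burn-in); conditional on the latent values every
  remaining update is the Gaussian one.

Priors are inverse-gamma$(\nu/2, \nu V/2)$ with $V = 1$, $\nu = 0.002$
per variance component, **parameter-expanded** by a $N(0, 625)$ working
scale on the random-effect terms. The expansion matters: the plain
IG$(0.001, 0.001)$ prior spikes at zero and visibly shrinks weakly
identified variances (we observed one-sided interval misses for a true
binary-trait $V_l$ of 0.05 before enabling it); the expanded prior has a
scaled-F shoulder and also mixes better. The plain prior remains
available (`alpha_v = NULL`) for sensitivity analysis. Intervals are
equal-tailed posterior quantiles; the original analysis did not state its
priors, chain settings, or interval convention, so these are package
decisions, flagged as such.

Default chains are 50,000 iterations, 10,000 burn-in, thinning 10, with
effective sample size (Geyer initial positive sequence) and split-chain
$\hat{R}$ reported on every fit and a `low_ess` flag rather than a hard
failure. Desk-scale analyses in the tests use 1,200–12,000 iterations,
which those diagnostics show is adequate for the small fits involved.

All derived parameters are computed **per posterior draw** and then
summarized (`summarize_mutation_params()`), so the $V_m$ interval
endpoints are exactly the $V_l$ endpoints divided by $2t$. $CV_m$ is not
reported for binary traits, whose latent-scale mean can be non-positive.
The rendered $CV_m$ formulas in the source material are typographically
ambiguous about the radical; the standard Houle-style forms with the
square root are the default and the no-radical Poisson variant is
switchable.

## What the generator emulates

`generate_design()` reproduces the assay layout: 14 randomized blocks,
100 MA lines × 5 plants per block spread as evenly as possible over 3–5
field sublines per line, six progenitor sublines × 6 plants per block
(one per field subline), 7,504 plants in total, and an optional
reference accession (Col-0) in the two seasons that included it.
`simulate_experiment()` adds the response layer per season:

* Season-specific intercepts, block variances, residual variances, and
  *expressed* among-line variances. Under the default `shared_scaled`
  model one standard-normal deviate per line per trait is drawn once and
  rescaled by $\sqrt{V_l^{(season)}}$ — the lines carry identical
  mutations everywhere and only their expression changes (variance
  G×E with cross-season correlation 1). An `independent` mode redraws
  effects per season for contrast.
* Founder and Col-0 rows carry zero line effect (mutations are what
  distinguish MA lines); Col-0 can take a configurable intercept offset,
  used to emulate its depressed spring survival.
* Binary traits include the latent logit-scale residual of variance 1,
  so generated and estimated $V_l$ live on the same latent scale.
* Defaults for the four seasons use the published intercepts and
  among-line variances for the binary traits, the published seasonal
  mortality (21/59/39/73%) and germination rates, and means matching the
  published untransformed trait means. Variances for count and
  continuous traits are not printed in the source tables; they were
  chosen once so that $h^2_m$ lands in the reported $10^{-4}$–$4\times
  10^{-4}$ band and never revisited. Subline variance defaults to zero
  (the bootstrap rarely retained it). Poisson overdispersion defaults on
  for count traits at desk-realistic magnitudes (0.8–1.5 on the log
  scale).

What the generator does **not** emulate: spatial layout and
autocorrelation within blocks, the greenhouse-to-field transplant filter
(germination is simulated as a per-row binary, not as a gate on the other
traits), per-generation mutation events (line effects are Gaussian
aggregates, consistent with the founder-centred means observed), seed
banks, weather covariates, and the exact pattern of subline imbalance
across seasons (a `redraw_sublines` switch re-randomizes assignments, but
the true imbalance level is unreported). Gaussian traits are clamped at
zero to respect the physical non-negativity of measurements, which
negligibly truncates the smallest-mean season. Passing tests therefore
demonstrate correctness of the estimators under the assumed model, not
robustness to field realities the model omits.

## Mean comparisons

`compare_all()` runs paired t tests between MA, founder, and Col-0 for
each trait within each season and pooled. The pairing unit is the block:
within a block the MA value is the mean of line means, the founder value
the mean of its subline means. The original description ("paired t tests
between the MA line means and the founder") is ambiguous about the
pairing unit; the block is the only replicated unit shared by all
genotype classes within a season, so block-pairing is the default, and a
line-level one-sample mode is deliberately not asserted as *the*
published procedure. Group means are always reported untransformed with
$\bar{x} \pm 1.96\,SE$; the square-root fitness transform changes the
test, never the reported means. Raw p-values are reported to match the
original analysis, with a Benjamini–Hochberg column as supplementary
output.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(
    design = experiment_design(n_blocks = 4, n_ma_lines = 25),
    seasons = default_seasons()[c("spring_2004", "fall_2005")],
    seed = 1),
  analyze_traits = c("germination", "survival"),
  mcmc = mcmc_settings(6000, 1000, 5),
  boot_B = 199, seed = 1, outdir = "ma_run")
res <- run_pipeline(cfg)
res$report
```

## Problem sizes and reproducibility

Every stochastic stage derives per-task seeds from one master seed, so
identical configurations reproduce identical numbers, and the run
manifest records the configuration hash. The test suite exercises the
published design at full size where cheap (7,504-row skeletons; 7,000-row
Gaussian MCMC fits for interval coverage, 20 replicates) and scales down
where the full bootstrap would dominate runtime (B = 49–199 with 30–100
lines for selection and calibration studies, against the study's
B = 1,000 default, which remains the package default for real analyses).

## Known limitations

* Each trait × season is univariate; no multi-trait or cross-season
  covariance models.
* No fixed-effect covariates beyond the intercept (weather is out of
  scope).
* The Poisson $V_e$ convention (lognormal observation-level variance) is
  one of several defensible choices and is switchable but not
  benchmarked against alternatives.
* The MH latent-variable sampler mixes slowly for very unbalanced binary
  data; watch the reported ESS and lengthen chains when flagged.
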