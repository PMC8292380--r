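---
title: "Methods: linking early social experience to DNA methylation and stress physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking early social experience to DNA methylation and stress physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Long-term field studies of social mammals (the motivating system is a wild
spotted hyena population) ask whether natural variation in early social
experience — how much care a cub receives from its mother, and how socially
connected a juvenile is during two developmental windows — leaves a lasting
mark on physiology. Two molecular/physiological readouts anchor the
analysis: fecal glucocorticoid metabolites (fGCMs, ng/g), a non-invasive
baseline stress measure collected repeatedly per animal, and DNA
methylation, measured both genome-wide on average (%CCGG from a
LUMA-style assay) and per CpG site as methylated/total bisulfite read
counts. `socmethyl` implements the full analysis chain in four parts —
exposure construction, global-methylation models, mediation, and a
site-level EWAS with a meet-in-the-middle screen — plus a synthetic-data
generator that makes every stage testable against known truth.

# Exposures

**Maternal care.** Focal-animal surveys record, minute by minute, whether a
mother and cub are within 1 m (close proximity), whether the cub is nursing,
and whether the mother grooms it; nursing and grooming occur within close
proximity, so those minutes are logically nested. Sessions qualify only when
the pair was co-observed for at least 5 minutes, the cub was under
13 months, and the mother was lactating. Care variables are the pooled
proportions (behavior minutes over co-observed minutes) across qualifying
sessions. Cubs with no qualifying time are excluded and logged — analytical
sample sizes legitimately vary across exposures, as in any field dataset.

**Developmental windows.** Each individual has a communal-den (CD) window
starting at birth and a den-independent (DI) window that begins the day
after the CD window closes and is duration-matched to it, day for day.
Duration matching means CD/DI contrasts reflect timing, not observation
effort.

**Social networks.** Co-occurrence sessions within a window define an
association network: edge weights are simple ratio indices
\(x / (x + y_a + y_b)\) (sessions together over sessions where either was
seen), in \([0, 1]\). From each individual's own window network we extract
degree (count of associates), strength (summed weights), and weighted
betweenness with edge distance \(1/w\) — a stronger association is a shorter
path — normalized by \((n-1)(n-2)/2\). The normalization and the even
splitting of tied shortest paths are verified in the test suite against
exhaustive path enumeration on all small graphs.

# Mixed models and inference

All association models are linear mixed models with a single random
intercept: hyena ID for repeated fGCM outcomes, maternal ID for
%CCGG outcomes (siblings share a mother and hence both genes and
environment). Exposures enter standardized (per 1 SD), and log-scale fGCM
coefficients are reported as percent changes, \(100(e^\beta - 1)\), rounded
to integer percent.

The engine profiles the variance ratio
\(\lambda = \sigma_b^2/\sigma_e^2\) in one dimension; at fixed \(\lambda\)
all REML quantities reduce to per-cluster sufficient statistics. Two
consequences matter. First, the fit is exact REML — estimates, Wald
standard errors, variance components and the REML log-likelihood agree with
`lme4::lmer` to numerical precision (tested). Second, a cluster-bootstrap
refit is a re-aggregation of precomputed per-cluster statistics, making
percentile intervals with 2000 resamples routine; that throughput is why the
engine exists rather than delegating each refit to a general mixed-model
optimizer.

**Bootstrap.** Confidence intervals are percentile intervals from resampling
clusters — the random-intercept unit — with replacement (2000 resamples,
95% level by default). Resampling clusters rather than rows preserves the
within-individual dependence the random intercept models; whether the
original analyses resampled rows or clusters is not documented, so the
cluster choice is our design decision. Refits whose resampled design
collapses are skipped and counted; more than 10% failures is an error.
Coverage is verified by simulation (93–97% over 300 datasets in the test
suite).

**BLUPs.** For the EWAS, repeated log-fGCM measurements are consolidated to
one number per animal: the best linear unbiased predictor of its random
intercept from an intercept-only model. In a balanced design the BLUP is the
raw deviation from the population mean shrunk by
\(n_i\sigma_b^2 / (n_i\sigma_b^2 + \sigma_e^2)\); individuals measured more
often are shrunk less. The implementation reproduces this closed form to
\(10^{-6}\).

**Interactions and multiplicity.** Maternal-rank effect modification is
screened with Wald tests at \(\alpha = 0.10\) (strict inequality).
Site-level multiplicity uses Benjamini–Hochberg step-up FDR at 5% via
`stats::p.adjust`, checked against an independent step-up oracle.

# The count-based EWAS

**Filtering.** Sites are filtered in a fixed order: (1) coverage — a site
must have ≥ 10 total reads in *every* analyzed individual (the strictest
reading; it avoids per-cell missingness in the site model); (2) mean
bounds — sites with mean methylation fraction below 10% or above 90% are
removed; (3) the 5% of surviving sites with the lowest interindividual
variance of methylation fractions are dropped, ties broken by site order.
"Interindividual variation" is defined here as the variance of
methylated/total fractions, and the variance step is count-based
(`floor(0.05 n)` sites removed), which makes it deliberately
*non*-idempotent: re-filtering a filtered panel trims another 5%. A
quantile-threshold variant would be idempotent but could not remove an
exact count under ties, and the exact-count behavior is the contract we
adopted; the coverage and mean-bounds stages are idempotent and tested as
such.

**Site model.** Each CpG is modeled on the logit scale:
\(\mathrm{logit}(p_i) = \beta_0 + \beta_1 x_i + \beta_2 \mathrm{age}_i +
u_i\), methylated reads \(\sim\) Binomial(total, \(p_i\)), with
\(u \sim N(0, \tau K)\) and \(K\) the additive relationship matrix from the
maternal pedigree. Estimation is penalized quasi-likelihood with \(\tau\)
profiled in one dimension at each outer iteration — a deterministic,
per-site-milliseconds alternative to MCMC samplers for the same model
family. Its correctness anchor: with \(\tau\) fixed at 0 the PQL iteration
*is* Fisher scoring for logistic regression, and the test suite requires
agreement with `glm` to \(10^{-4}\). When the profiled \(\tau\) hits the
zero boundary, the model falls back to a beta-binomial maximum-likelihood
fit without kinship (flagged), so residual overdispersion is still absorbed
rather than silently inflating test statistics.

**Empirical-null correction.** Unmeasured confounding and model
misspecification inflate and shift site-level z-scores. We estimate the
null's bias and inflation with a three-component normal mixture fit by EM:
a central null \(N(\mathrm{bias}, \mathrm{inflation}^2)\) flanked by one
left and one right alternative component. Three constraints keep the null
honest: the null must carry the largest weight, alternative means stay at
least `delta_min = 2` z-units from the null mean, and alternative SDs are
at least the null SD — so with no signal the side components cannot eat the
null's tails. Initialization is method-of-moments (median/MAD) plus 10
jittered restarts, deterministic given a seed; EM near a weight boundary
converges geometrically slowly, so the stop rule is an absolute
per-iteration log-likelihood increment (10⁻³) with a 2000-iteration cap.
Corrected statistics are \(z' = (z - \mathrm{bias})/\mathrm{inflation}\)
with two-sided normal p-values and the consistent coefficient rescaling
\(\beta' = \beta - \mathrm{bias}\cdot se\), \(se' = se \cdot
\mathrm{inflation}\). Calibration (planted bias 0.3, inflation 1.2,
recovered within ±0.05; corrected p-values uniform) is part of the test
suite.

**Meet-in-the-middle.** DMSs (FDR ≤ 5% after correction) are screened
against maternal care and rank with per-site count models: methylated reads
as outcome, `log(total)` as offset, age as covariate, Poisson by default
and negative binomial when the Pearson \(\chi^2/df\) exceeds its 5%
critical value (strict exceedance). A site "matches prediction" when its
care association is nominally significant (p < 0.1) *and* opposite in sign
to its fGCM association — a protective exposure and an adverse outcome
should pull methylation in opposite directions. Sign comparison uses the
raw care-model coefficients against the corrected fGCM-model coefficients,
since the two model families are fit separately.

# Mediation

The three-step procedure: (1) exposure → outcome; (2) exposure → mediator
and mediator → outcome; (3) only if all three percentile-bootstrap CIs
exclude zero, refit step 1 with the mediator added and compute the
attenuation \(100(|\beta_{unadj}| - |\beta_{adj}|)/|\beta_{unadj}|\);
mediation is declared above 10% attenuation. Pass/fail uses the bootstrap
CI — the same inferential currency as the headline models — rather than
Wald p-values. The exposure is standardized inside the procedure, so
attenuation is invariant to its scale (tested); whether attenuation should
be computed on raw or standardized coefficients was an open choice, and the
standardized scale was adopted because it makes exposures comparable.

# The synthetic-data generator

The generator produces a full study with known truth: a maternal pedigree
(founder mothers, litters of 1–2 separated by realistic interbirth
intervals; additive kinship with unknown sires — unit diagonal,
mother–offspring 0.5, maternal sibs 0.25), latent maternal care quality and
individual gregariousness, per-minute care counts respecting the
nursing/grooming ⊆ proximity nesting, co-occurrence sessions spanning every
individual's CD and DI windows, repeated fGCMs (1–18 occasions per animal)
with an individual random intercept, sibling-clustered %CCGG, and per-CpG
counts with kinship-correlated logit-scale random effects
(\(u \sim MVN(0, \tau K)\)) and coverage \(1 + \mathrm{Poisson}(\bar c -
1)\) (zero totals never arise by default but are accepted by the container
and removed by the coverage filter). Site intercepts come from a
low/intermediate/high mixture so the mean-bounds filter has realistic work.

Default effect sizes are the study conditions the package targets: a
−0.12 log-fGCM slope per SD of DI-period connectedness (≈ −11%), no
maternal-care effect on fGCMs, +1.36 %CCGG per SD of close proximity, an
individual log-fGCM intercept SD of 0.45 with residual 0.55, maternal
%CCGG intercept SD 1.5 with residual 2.5, kinship variance 0.3 on the
methylation logit scale, and 2.5% of sites carrying a ±1.0 logit effect.
Covariate coefficients default to the qualitative directions expected in
this system (human disturbance lowers care and raises stress hormones and
lowers global methylation) and are fully configurable. Outcomes are
generated from the *realized* standardized exposures (computed with the
package's own behavior module), so recovery tests measure the estimator,
not exposure measurement error; individuals with unobservable exposures
contribute at the exposure mean and carry `NA` for analysis, reproducing
the varying n of field data. All randomness flows from one seed through
named per-component sub-streams, so editing one block of the config leaves
the other streams untouched and a fixed config is byte-identical across
runs.

What the generator does *not* emulate: raw sequencing reads, observation
session time-of-day structure beyond an am/pm label, den locations or
movement, overdispersed (beyond-Poisson) coverage, and cell-type
heterogeneity of blood. Passing tests therefore demonstrate correctness of
the estimators under the stated generative model, not robustness to every
pathology of real bisulfite data.

# Numerical choices and degenerate inputs

* REML profile optimized on \(\log\lambda \in [-10, 10]\) with an explicit
  boundary evaluation at \(\lambda = 0\); boundary fits return variance 0
  with a warning. Rank-deficient designs error with the collinear columns
  named. Zero-residual data returns exact OLS coefficients.
* PQL: 3 inner IRLS sweeps per outer round, at most 4 outer rounds,
  \(\tau\) profiled on \(\log\tau \in [-8, 3]\) plus the 0 boundary;
  working weights floored at \(10^{-8}\); linear predictors clamped at
  ±30. Constant exposures are an explicit identifiability error;
  non-converged sites are excluded from null estimation and flagged.
* BH ties: `p.adjust` handles ties; equal adjusted p-values are called
  together, and site order is preserved in all outputs for
  reproducibility.
* Candidate-region screen: when every site's mean and range of percent
  methylation fall below 1%, the region is declared invariant and
  downstream candidate-gene analysis is skipped with a notice.
* Coordinates are 0-based internally; Bismark-coverage input (1-based) is
  converted on read. Annotation precedence: island > shore > open sea;
  promoter > exon > intron > intergenic.

# Problem sizes used in validation

The shipped test suite validates at sizes chosen to make the statistical
checks sharp yet quick to re-run: bootstrap coverage over 300 simulated
datasets of 80 clusters × 3 repeats at 500 resamples; EWAS calibration over
20 seeded null panels of 2,000 sites × 25 individuals (mean false DMS count
below 1) and a seeded planted-effect panel (50 true sites, logit effect
1.0, 30× coverage, ≥ 50% recall — the ceiling is set by the filters, which
legitimately remove some planted sites); mediation over 100 planted and 100
null chains; network metrics against brute force on 200 random graphs of up
to 6 nodes; and the empirical null on 10,000 statistics.

# Known limitations

* The site model is PQL, which carries the usual mild attenuation of
  logit-scale effects at low coverage; the recovery tests bound it (±0.1 at
  30× coverage) but very low-coverage panels will attenuate more.
* The empirical-null mixture assumes alternatives are separated from the
  null by ~2 z-units; signals weaker than that leak into the null component
  and are absorbed as inflation (conservative, not anti-conservative).
* One random intercept per model: no random slopes, no crossed random
  effects, no small-sample degrees-of-freedom corrections.
* Mediation is the classic three-step attenuation procedure, not a causal
  effect decomposition; it inherits that procedure's assumptions.
* Annotation is interval-based on user-supplied tracks; no cross-species
  sequence mapping or gene naming is attempted.
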