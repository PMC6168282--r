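---
title: "Models and methods behind camtrapgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind camtrapgrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(camtrapgrad)
```

camtrapgrad implements the statistical chain used to compare mammal
communities across urban–wild development gradients from camera-trap
surveys: deterministic data reduction, Hill-number diversity, Bayesian
Poisson detection-rate models, a multivariate-Bernoulli multispecies
occupancy model, posterior predictive fit checks, and distributional
comparison summaries. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where
the methodology left room.

## From photos to data

A camera produces bursts of photos per animal passage. Two reductions
make these usable:

* **Independent sequences.** Consecutive photos of one species at one
  site are merged while the inter-photo gap is *strictly* less than
  `gap_seconds` (default 60 s); a gap of exactly 60 s starts a new
  sequence. The sequence inherits the first photo's timestamp, and its
  `animal_count` is the **maximum simultaneous count** over its photos.
  The maximum was chosen over the sum because the same individuals
  re-trigger the camera repeatedly within a sequence; summing would
  double-count them. Collapsing is idempotent: sequence start times are
  at least one gap apart by construction.
* **Daily detection histories.** Sequences collapse to a binary
  species × site × day array cut at local midnight, with an effort mask
  derived from each site's deployment window. A camera-night is a
  calendar day with the camera deployed; partial first/last days count
  as full nights. Records outside a deployment window are dropped with
  a warning rather than silently extending effort.

**Gradient classification.** The published housing-density bins do not
tile the positive line (0.5–0.51 and 147.047–147.048 fall between
bins, and 1000 belongs to suburban while urban is "> 1000"). The
package closes the gaps with a half-open convention — wild [0, 0.5),
rural [0.5, 12.64), exurban [12.64, 147.048), suburban [147.048, 1000],
urban (1000, ∞) — which reproduces every published bin and assigns each
boundary point to exactly one level.

**Detection rate** is sequences per camera-night, a relative-abundance
index. Multi-animal sequences count once by default; a `per_animal`
flag weights by the sequence's animal count instead, since the
convention is not fixed by the method itself.

## The synthetic survey generator

Every downstream model is tested against surveys generated with known
truth, emulating the stratified design the analyses assume: two cities,
five development levels, four plot types with the real availability
gaps (no yards in urban or wild strata; urban unsampled in the second
city, open plots unsampled in the first), and 21-day deployments —
three weeks at ~20 sites per stratum is the standard precision target
for detection-rate estimation in this literature. Housing densities are
drawn inside each level's classification bin so stratum labels
round-trip exactly.

Occupancy surveys draw latent presence per site from the multivariate
Bernoulli implied by species-level logit-linear models (plus optional
pairwise interactions), then daily detections as Bernoulli given
presence. Default intercepts give occupancy 0.30–0.50 and daily
detection 0.10–0.25 for the four focal carnivores (bobcat, coyote,
gray fox, red fox), with modest responses of either sign to an
urbanization axis — values typical of mesocarnivores on temperate
camera grids. Count surveys draw photo events as Poisson with
intensity `rate × camera-nights` (defaults 0.02–0.30 events/day by
species), each expanded into a photo burst with intra-burst gaps under
60 s and inter-event gaps over 60 s, so the sequence-collapsing rule
recovers event counts *exactly* — this exactness is asserted in the
tests. Continuous covariates are standard normal with an optional
correlated pair (default ρ = 0.85 when enabled) to exercise the
restrictive-prior rule.

What the generator does **not** emulate: spatial autocorrelation,
animal movement, seasonal detection trends, photo misidentification.
Passing tests therefore demonstrate the estimators' correctness under
the models' own assumptions, not robustness to these violations.

## Hill-number diversity

Diversity uses incidence (detection/non-detection across T sites per
stratum), not abundance, because daily detections of the same
individuals are not independent counts of animals.

* **Richness (q = 0).** Interpolation uses the exact hypergeometric
  expectation `S_obs − Σ_i C(T − Y_i, t)/C(T, t)`; extrapolation uses
  the Chao2 estimate of undetected richness
  `Q̂₀ = ((T−1)/T) Q₁²/(2Q₂)` (bias-corrected form when Q₂ = 0).
* **Shannon (q = 1).** At the observed size, `exp(−Σ p̂_i log p̂_i)`
  with `p̂_i = Y_i / ΣY`. Below the observed size the estimate is
  rarefied by seeded Monte-Carlo subsampling of sites (200 subsamples
  by default), because the incidence entropy of a hypergeometric
  subsample has no separable closed form — the relative-incidence
  denominator couples species. Extrapolation beyond T is not supported
  for q = 1 and errors rather than guessing.

Confidence intervals come from a seeded bootstrap over sampling units
(sites resampled with replacement, B ≥ 50, default 200), reported as
percentile intervals expanded if necessary to contain the point
estimate. A simulation study in the test suite (300 replicate
communities of six species at T = 50) verifies near-nominal coverage
for the q = 1 interval.

The "trend across the gradient" is a weighted quadratic fit through the
five ordered level estimates (weights inverse to the CI-implied
variance). A full GAM is unidentifiable with five support points; the
quadratic reproduces any genuinely quadratic pattern exactly and is
used for display and peak location only.

## Poisson detection-rate models

Counts of independent sequences per site are modeled as Poisson with a
log link and `log(camera-nights)` offset, so coefficients act on the
count/day (rate) scale. Priors are normal(0, 10) on coefficients —
effectively flat at this data scale; sampling uses three chains by
default. Overdispersion is deliberately *not* modeled: the posterior
predictive check is the arbiter of adequacy, and the test suite
verifies that a negative-binomial truth is flagged. All-zero strata are
fitted but flagged (their intercept is weakly identified by the prior).
The per-stratum rate is `exp(linear predictor)` at that stratum's
design row; the same quadratic smoother as for diversity locates the
gradient peak.

## The multispecies occupancy model

The latent occupancy state of S species at a site is multivariate
Bernoulli: one probability per joint presence state; for two species
`Z ~ MVB(ψ₁₁, ψ₁₀, ψ₀₁, ψ₀₀)`. The cells are parameterized
log-linearly: state energy = Σ first-order natural parameters f_s of
the species present + Σ pairwise f_st of pairs jointly present, with a
softmax over the 2^S states. This construction guarantees valid,
normalized cells for any parameter values, reduces exactly to
independent Bernoullis with marginal `plogis(f_s)` when all f_st = 0,
and is computed on the log scale so extreme parameters never produce
NaN. Covariates enter f_s logit-linearly through a mean-centered design
matrix.

Detection is a daily Bernoulli given presence, with site-level
detection covariates (so p is constant over occasions within a site and
the likelihood uses binomial sufficient statistics; occasion-varying p
remains representable in `site_likelihood()` itself). The site
likelihood sums over latent states: a species absent in a state
contributes 1 for an all-zero history and 0 otherwise. The
implementation carries an optimized factorized path for the
independence case and is verified against brute-force 2^S enumeration
to < 1e-12 in the acceptance tests.

**Priors.** Logistic(0, √10) on every coefficient, switched to the
restrictive logistic(0, 1) for any design column whose absolute Pearson
correlation with another column exceeds 0.60 — shrinkage in the spirit
of ridge regression for collinear predictors (e.g. road density vs
housing density).

**Random detection effect.** A per-species site-level normal intercept
on detection (motivated by species like coyote whose initial fit checks
fail without it) with a half-normal(0, 1) prior on its SD. It is
marginalized by 15-node Gauss–Hermite quadrature rather than by
sampling site effects: with binomial sufficient statistics the integral
is one-dimensional per site, and quadrature is faster and exact to
quadrature error.

**Sampling.** An adaptive random-walk Metropolis sampler (covariance
learned during warmup, step size tuned to ~23% acceptance, adaptation
frozen after warmup). Two chains with split-chain R-hat per parameter,
gated at ≤ 1.1; parameters above the gate are reported but their
significance is withheld. When interactions are fixed at zero the joint
posterior factorizes across species, so each species' block is sampled
independently and the draws assembled — exact, and far better mixing
than a joint random walk over all species' parameters. Species are
fitted jointly (single sampler) only when interaction terms are freed.

**Marginal occupancy** per stratum is the sum of cell probabilities
over states containing the species (ψ₁ = ψ₁₁ + ψ₁₀ for pairs),
evaluated at the stratum's design row. Strata whose categorical
covariate combination was never sampled (yards in wild, for instance)
are flagged absent, never extrapolated.

## Posterior predictive checks

The discrepancy is the sum of squared Pearson residuals; the Bayesian
p-value is `p_B = Pr(T(y_sim) > T(y))` over posterior draws, with
adequacy declared when 0.1 < p_B < 0.9.

* Counts: `T = Σ (y − μ)²/μ` with μ the per-draw fitted mean.
* Occupancy: residuals are defined on the daily Bernoulli margins,
  `T = Σ (y − μ)²/(μ(1−μ))`. Two conditionings are implemented, since
  the derivation for occupancy models is not settled: the default
  conditions μ = z·p on a latent state z drawn from its posterior full
  conditional given the history (z = 1 where the species was detected);
  the alternative uses the unconditional margin μ = ψ·p. Occasions with
  degenerate μ ∈ {0, 1} are skipped. Replicate data simulate both
  latent states and detections per draw and are processed identically
  to the observed data.

A calibration property worth knowing: for the count model, p_B under
the true model is nearly uniform, so the expected fraction of
replicates inside the 0.1–0.9 window is exactly 80%; the
latent-conditional occupancy statistic is conservative (p_B
concentrates toward 0.5), and its adequacy rate in replicate
experiments is essentially 100%. The calibration suite therefore uses
the occupancy model for the "true model accepted" property (50
replicate surveys of 100 sites × 14 days at ψ = 0.6, p = 0.4) and the
count model for the "overdispersed truth rejected" property (50
replicates of 200 sites with negative-binomial truth, size 0.5).

## Comparison summaries

Marginal occupancy distributions (four carnivores per city × level, or
a reference community) are summarized by Tukey hinges — the
median-inclusive quartile convention under which {0.1, 0.2, 0.3, 0.4}
has hinges 0.15 and 0.35 — with whiskers at 1.5 IQR. Two distributions
differ "significantly" under the overlap heuristic iff their closed
[q1, q3] intervals are disjoint; boxes touching at a point count as
overlapping. External cross-study tables (schema:
`species, study, occupancy, diet_class`) are averaged over duplicate
studies per species, with omnivores removable via the diet-class
column; the bundled reference table is a synthetic stand-in, clearly
labelled, with the same schema as a real global dataset.

## Numerical choices and problem sizes

MCMC defaults follow the two-chain, 1000-warmup / 3000-iteration
pattern for occupancy and three chains for counts; the test and
demonstration runs use shorter chains (300–1000 warmup, 500–3000 kept)
and survey sizes of 100–1000 sites, which the recovery experiments show
are ample for intercept-only and single-covariate designs: posterior
means land within 3 posterior SDs of truth with logit-scale bias below
0.05 averaged over 10 replicate surveys of 500 sites × 21 days.
Degenerate inputs are handled explicitly: empty strata error, all-zero
strata are flagged, unparseable timestamps and out-of-window records
are dropped with warnings, and likelihood underflow is prevented by
log-scale computation throughout.

## Known limitations

Single-season (static) occupancy only; interactions are limited to
pairwise second-order terms; no spatial or temporal autocorrelation in
either occupancy or detection; Shannon diversity is not extrapolated
beyond the observed number of sites; the IQR-overlap rule is a
heuristic, not a formal test, and is reported as such.
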