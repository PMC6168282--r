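# camtrapgrad

Statistical machinery for analysing camera-trap surveys of mammal
communities along urban–wild development gradients, with a synthetic
survey generator so every stage of the chain can be exercised and
verified without field data.

The package is aimed at ecologists working with stratified camera-trap
designs: sites classified by housing density into five development
levels (urban > 1000 houses/km², suburban 147.048–1000,
exurban 12.64–147.047, rural 0.51–12.63, wild < 0.5) and four local
plot types (large forest, small forest fragment, open area, residential
yard), with cameras deployed for ~3-week sessions.

## What it computes

**Data reduction.** Consecutive photos of a species at a site less than
60 s apart are collapsed into one independent sequence (one detection
event); sequences are collapsed again into daily detection/non-detection
histories. From these: naive occupancy, detection rates
(detections/camera-night, the relative-abundance index), and
effort-weighted detection profiles across the gradient.

**Diversity.** Incidence-based Hill numbers: richness (q = 0, with exact
hypergeometric rarefaction and Chao2 extrapolation,
`S + ((T−1)/T)·Q₁²/(2Q₂)`) and Shannon diversity (q = 1, the exponential
of incidence entropy), with bootstrap-over-sites confidence intervals
and a weighted quadratic trend across the ordered gradient.

**Detection-rate models.** Bayesian Poisson regression of per-site
counts with a log(camera-nights) offset, so coefficients act on the
count/day scale; per-stratum rate posteriors, trend curve, and
fully-parameterized per-species covariate models with 95%
credible-interval significance.

**Occupancy.** A multispecies occupancy model whose latent states follow
a multivariate Bernoulli distribution: for two species
`Z ~ MVB(ψ₁₁, ψ₁₀, ψ₀₁, ψ₀₀)`, constructed log-linearly from natural
parameters so the 2^S cell probabilities always sum to 1 and pairwise
interactions are a switch (zero = independence, the default). Detection
is imperfect (daily Bernoulli given presence); a site-level random
detection intercept is available per species (e.g. for coyote).
Sampling is by adaptive random-walk Metropolis with split-chain R-hat
gated at 1.1.

**Diagnostics.** Posterior predictive checks with the sum of squared
Pearson residuals, `p_B = Pr(T(y_sim) > T(y))`, adequacy declared when
0.1 < p_B < 0.9.

**Comparison.** Marginal occupancy distributions summarized by Tukey
hinges; two distributions differ "significantly" under the
interquartile-overlap heuristic iff their [q1, q3] boxes are disjoint.

## Worked example

```r
library(camtrapgrad)

cfg   <- scenario_config(n_per_cell = 6)          # 2 cities x gradient x plots
sites <- simulate_sites(cfg, seed = 1)
svy   <- simulate_occupancy_survey(cfg, sites, seed = 2)

spec <- occupancy_model_spec(c("bobcat", "coyote", "gray_fox", "red_fox"),
                             occ_formula = ~ development_level,
                             chains = 2, warmup = 800, iter = 1500)
fit <- fit_occupancy(spec, svy$history, sites, seed = 3)
subset(marginal_occupancy(fit), species == "bobcat")
```

```
  development_level species       mean      lower     upper absent
1             urban  bobcat 0.21860165 0.04100141 0.4895144  FALSE
2          suburban  bobcat 0.08459428 0.02110115 0.2082957  FALSE
3           exurban  bobcat 0.25944508 0.13800755 0.4396711  FALSE
4             rural  bobcat 0.45689703 0.27522917 0.6313626  FALSE
5              wild  bobcat 0.63656479 0.44609845 0.8184501  FALSE
```

Each row is the posterior mean and 95% credible interval of bobcat
marginal occupancy at one development level: under the simulated truth
(bobcat avoids development) occupancy falls from wild (0.64) toward
suburban/urban, exactly the gradient pattern the model is meant to
expose. `ppc_occupancy(fit)` then reports a Bayesian p-value inside the
0.1–0.9 adequacy window when the model fits.

The `analysis/` directory holds the full demo workflow as numbered
drivers (simulation → reduction → diversity → count models → occupancy →
PPC calibration → cross-study comparison), each writing its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R 42
Rscript analysis/02_reduce.R   42
# ... through analysis/07_compare.R
```

The bundled cross-study reference table
(`inst/extdata/synthetic_reference_occupancy.csv`) is a synthetic
stand-in with the schema `species, study, occupancy, diet_class`; a real
global dataset can be substituted file-for-file.

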