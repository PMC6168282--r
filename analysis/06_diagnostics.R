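#!/usr/bin/env Rscript
# Stage 6 - posterior predictive calibration study.
#
# Checks that the squared-Pearson-residual PPC accepts the generating
# model and rejects an overdispersed (negative-binomial) truth, across
# seeded replicate surveys - the behaviour a useful adequacy check must
# have before its verdicts on real data mean anything.

library(camtrapgrad)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 42L
dir.create("results/diagnostics", showWarnings = FALSE, recursive = TRUE)

n <- 200; rate <- 0.15; nights <- 21L
fit_pb <- function(counts, s) {
  d <- data.frame(count = counts, camera_nights = nights)
  fit <- fit_count_model(count ~ 1, d, chains = 2, warmup = 300, iter = 600,
                         seed = s)
  ppc_count(fit, max_draws = 300, seed = s + 1L)$p_B
}
pb_true <- vapply(1:50, function(r) {
  set.seed(seed + 1000 + r); fit_pb(rpois(n, rate * nights), seed + 1100 + r)
}, numeric(1))
pb_nb <- vapply(1:50, function(r) {
  set.seed(seed + 1200 + r)
  fit_pb(rnbinom(n, size = 0.5, mu = rate * nights), seed + 1300 + r)
}, numeric(1))

out <- data.frame(truth = rep(c("poisson", "negative_binomial"), each = 50),
                  replicate = rep(1:50, 2), p_B = c(pb_true, pb_nb),
                  adequate = c(pb_true, pb_nb) > 0.1 & c(pb_true, pb_nb) < 0.9)
write.csv(out, "results/diagnostics/ppc_calibration.csv", row.names = FALSE)

cat(sprintf("true Poisson model: %.0f%% of replicates inside 0.1 < p_B < 0.9\n",
            100 * mean(out$adequate[out$truth == "poisson"])))
cat(sprintf("NB-overdispersed truth: %.0f%% of replicates flagged inadequate\n",
            100 * mean(!out$adequate[out$truth == "negative_binomial"])))
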