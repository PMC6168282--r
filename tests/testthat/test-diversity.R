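make_incidence <- function(freq, T) {
  # unit x species binary matrix realizing the given incidence frequencies
  m <- sapply(freq, function(f) c(rep(1L, f), rep(0L, T - f)))
  incidence_data(m)
}

test_that("richness interpolation/extrapolation hits its closed forms", {
  inc <- make_incidence(c(8, 2, 1, 2), T = 10)   # Q1 = 1, Q2 = 2
  # interpolation endpoint: estimate at T equals observed richness
  expect_equal(hill_richness(inc)$estimate, 4)

  # Chao2 asymptote with Q1 = 2 singletons, Q2 = 1 doubleton: S + 1.8
  inc2 <- make_incidence(c(5, 1, 1, 2), T = 10)
  expect_equal(hill_richness(inc2, Inf)$estimate, 4 + 1.8, tolerance = 1e-12)

  # no rarity: all species everywhere -> S at every size
  inc3 <- make_incidence(c(10, 10, 10), T = 10)
  for (t in c(2, 5, 10, 20, Inf))
    expect_equal(hill_richness(inc3, t)$estimate, 3, tolerance = 1e-12)

  # rarefied richness matches a Monte-Carlo subsample oracle
  set.seed(30)
  inc4 <- make_incidence(c(9, 6, 3, 1, 1), T = 12)
  mc <- mean(replicate(4000, {
    sub <- inc4$matrix[sample.int(12, 6), , drop = FALSE]
    sum(colSums(sub) > 0)
  }))
  expect_equal(hill_richness(inc4, 6)$estimate, mc, tolerance = 0.02)

  expect_error(hill_richness(inc, 0), "target_size")
})

test_that("Hill-Shannon diversity is the exponential of incidence entropy", {
  # equal incidence -> maximal evenness: estimate = S exactly
  expect_equal(hill_shannon(make_incidence(c(4, 4), T = 8))$estimate, 2)
  expect_equal(hill_shannon(make_incidence(c(3, 3, 3, 3), T = 6))$estimate, 4)
  # single species -> 1
  expect_equal(hill_shannon(make_incidence(5, T = 6))$estimate, 1)
  # frequencies (8, 2): exp(-0.8 log 0.8 - 0.2 log 0.2)
  est <- hill_shannon(make_incidence(c(8, 2), T = 10))$estimate
  expect_equal(est, exp(-(0.8 * log(0.8) + 0.2 * log(0.2))), tolerance = 1e-12)
  expect_equal(round(est, 3), 1.649)
  expect_error(hill_shannon(make_incidence(c(3, 2), T = 5), target_size = 9),
               "not supported")
})

test_that("Hill numbers are monotone in q and invariant to labels and scaling", {
  set.seed(31)
  for (i in 1:20) {
    freq <- sample(1:12, 5, replace = TRUE)
    inc <- make_incidence(freq, T = 12)
    q0 <- hill_richness(inc)$estimate
    q1 <- hill_shannon(inc)$estimate
    expect_gte(q0 + 1e-12, q1)
    # species order / site order irrelevant
    perm <- incidence_data(inc$matrix[sample.int(12), sample.int(5)])
    expect_equal(hill_shannon(perm)$estimate, q1, tolerance = 1e-12)
    # doubling every frequency and T leaves q = 1 at observed size unchanged
    dbl <- make_incidence(2 * freq, T = 24)
    expect_equal(hill_shannon(dbl)$estimate, q1, tolerance = 1e-12)
  }
})

test_that("bootstrap rarefaction intervals behave sensibly", {
  # degenerate community: one species everywhere -> zero-width interval at 1
  inc <- make_incidence(8, T = 8)
  ci <- rarefaction_ci(inc, q = 1, B = 60, seed = 5)
  expect_equal(ci$ci_low, 1); expect_equal(ci$ci_high, 1)
  expect_error(rarefaction_ci(incidence_data(matrix(1, 1, 2)), q = 0),
               "T = 1")

  # intervals widen (on average) as the number of units shrinks
  set.seed(32)
  pi_s <- c(0.7, 0.5, 0.35, 0.2, 0.1)
  widths <- sapply(c(60, 20), function(T) {
    mean(replicate(15, {
      m <- sapply(pi_s, function(q) rbinom(T, 1, q))
      inc <- incidence_data(m)
      est <- rarefaction_ci(inc, q = 1, B = 100, seed = sample.int(1e6, 1))
      est$ci_high - est$ci_low
    }))
  })
  expect_gt(widths[2], widths[1])
})

test_that("bootstrap intervals achieve near-nominal coverage", {
  set.seed(33)
  pi_s <- c(0.8, 0.6, 0.5, 0.4, 0.3, 0.2)
  p_true <- pi_s / sum(pi_s)
  true_q1 <- exp(-sum(p_true * log(p_true)))
  hits <- replicate(300, {
    m <- sapply(pi_s, function(q) rbinom(50, 1, q))
    est <- rarefaction_ci(incidence_data(m), q = 1, B = 120,
                          seed = sample.int(1e6, 1))
    est$ci_low <= true_q1 && true_q1 <= est$ci_high
  })
  expect_gt(mean(hits), 0.85)
  expect_lte(mean(hits), 1)
})

test_that("the gradient trend curve reproduces quadratic structure", {
  # inputs already quadratic in the level index come back exactly
  idx <- 1:5
  y <- 2 + 1.5 * idx - 0.3 * idx^2
  tr <- gradient_trend(y)
  expect_equal(tr$fitted, y, tolerance = 1e-8)

  # symmetric hump peaks at the middle level
  hump <- c(1, 3, 4, 3, 1)
  expect_equal(gradient_trend(hump)$peak_level, "exurban")

  # constructed peak at suburban is found
  y2 <- c(2.2, 3.6, 3.0, 2.0, 1.0)
  tr2 <- gradient_trend(y2, ci_low = y2 - 0.4, ci_high = y2 + 0.4)
  expect_equal(tr2$peak_level, "suburban")

  expect_error(gradient_trend(c(1, 2)), "3 gradient levels")
})

test_that("per-stratum diversity table compares strata at common size", {
  cfg <- scenario_config(n_per_cell = 2L)
  st <- simulate_sites(cfg, seed = 41)
  sv <- simulate_occupancy_survey(cfg, st, seed = 42)
  div <- diversity_by_stratum(sv$history, st$development_level, B = 60, seed = 43)
  expect_true(all(div$q %in% c(0, 1)))
  expect_true(all(div$ci_low <= div$estimate + 1e-9))
  expect_true(all(div$estimate <= div$ci_high + 1e-9))
  expect_true(all(div$target_size <= div$T))
})
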