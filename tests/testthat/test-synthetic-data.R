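test_that("site simulation respects the stratified design", {
  cfg <- scenario_config(n_per_cell = 3L)
  st <- simulate_sites(cfg, seed = 1)

  # densities always classify back to the stratum they were drawn for
  expect_equal(as.character(classify_development(st$housing_density)),
               as.character(st$development_level))
  # stratum availability rules
  expect_false(any(st$plot_type == "yard" &
                     st$development_level %in% c("urban", "wild")))
  expect_false(any(st$city == "Raleigh" & st$development_level == "urban"))
  expect_false(any(st$city == "DC" & st$plot_type == "open"))
  # exact cell counts
  tab <- table(st$city, st$development_level, st$plot_type)
  expect_true(all(tab %in% c(0L, 3L)))
  # wild sites all below the wild threshold
  expect_true(all(st$housing_density[st$development_level == "wild"] < 0.5))
  expect_true(all(st$hunting %in% 0:1) && all(st$yard %in% 0:1))
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- scenario_config(n_per_cell = 2L)
  a <- simulate_sites(cfg, seed = 7); b <- simulate_sites(cfg, seed = 7)
  expect_identical(a, b)
  sa <- simulate_occupancy_survey(cfg, a, seed = 8)
  sb <- simulate_occupancy_survey(cfg, b, seed = 8)
  expect_identical(sa, sb)
  ca <- simulate_count_survey(cfg, a, seed = 9)
  cb <- simulate_count_survey(cfg, b, seed = 9)
  expect_identical(ca, cb)
})

test_that("degenerate occupancy parameters saturate the history", {
  cfg <- scenario_config(
    species = list(sp1 = list(psi_intercept = 30, p_intercept = 30,
                              psi_beta = numeric(0), p_beta = numeric(0))),
    n_per_cell = 1L, n_days = 5L)
  st <- simulate_sites(cfg, seed = 2)
  sv <- simulate_occupancy_survey(cfg, st, seed = 3)
  expect_true(all(sv$history$Y == 1L))
})

test_that("independent species co-occur at the product rate", {
  cfg <- scenario_config(
    species = list(
      a = list(psi_intercept = 0, p_intercept = 0, psi_beta = numeric(0),
               p_beta = numeric(0)),
      b = list(psi_intercept = 0, p_intercept = 0, psi_beta = numeric(0),
               p_beta = numeric(0))),
    n_days = 3L)
  st <- make_sites(10000)
  sv <- simulate_occupancy_survey(cfg, st, seed = 4)
  co <- mean(sv$truth$Z[, 1] * sv$truth$Z[, 2])
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(co - 0.25), 3 * se)
  # empirical marginals recover the intercept-implied psi = 0.5
  expect_lt(abs(mean(sv$truth$Z[, 1]) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("a positive pairwise interaction raises co-occurrence above independence", {
  inter <- matrix(c(0, 1.2, 1.2, 0), 2)
  cfg <- scenario_config(
    species = list(
      a = list(psi_intercept = 0, p_intercept = 0, psi_beta = numeric(0),
               p_beta = numeric(0)),
      b = list(psi_intercept = 0, p_intercept = 0, psi_beta = numeric(0),
               p_beta = numeric(0))),
    interactions = inter, n_days = 3L)
  st <- make_sites(6000)
  sv <- simulate_occupancy_survey(cfg, st, seed = 5)
  co <- mean(sv$truth$Z[, 1] * sv$truth$Z[, 2])
  indep <- mean(sv$truth$Z[, 1]) * mean(sv$truth$Z[, 2])
  expect_gt(co, indep)
  # and the cell construction itself shows the same ordering
  cells <- natural_to_cell(c(0, 0), 1.2)
  expect_gt(cells[1, "psi11"],
            (cells[1, "psi11"] + cells[1, "psi10"]) *
              (cells[1, "psi11"] + cells[1, "psi01"]))
})

test_that("photo events are Poisson with the configured intensity", {
  cfg <- scenario_config(count_rates = c(total = 0.1), n_days = 21L)
  st <- make_sites(1000)
  cs <- simulate_count_survey(cfg, st, seed = 6)
  n_ev <- cs$truth$n_events
  expect_lt(abs(mean(n_ev) - 2.1), 3 * sqrt(2.1 / 1000))
  expect_lt(abs(var(n_ev) / mean(n_ev) - 1), 0.15)  # equidispersion
  # zero intensity -> no records
  cfg0 <- scenario_config(count_rates = c(total = 0))
  expect_equal(nrow(simulate_count_survey(cfg0, st[1:20, ], seed = 7)$records), 0L)
})

test_that("sequence collapsing recovers simulated event counts exactly", {
  cfg <- scenario_config(count_rates = c(deer = 0.3, coyote = 0.05))
  st <- make_sites(150)
  cs <- simulate_count_survey(cfg, st, seed = 8)
  seqs <- collapse_sequences(cs$records)
  got <- detection_rates(seqs, st, species = c("deer", "coyote"))
  key <- paste(got$species, got$site_id)
  tkey <- paste(cs$truth$species, cs$truth$site_id)
  expect_equal(got$detections[order(key)],
               as.numeric(cs$truth$n_events[order(tkey)]))
})

test_that("generated histories satisfy the detection-history invariants", {
  cfg <- scenario_config(n_per_cell = 2L)
  st <- simulate_sites(cfg, seed = 9)
  sv <- simulate_occupancy_survey(cfg, st, seed = 10)
  h <- sv$history
  expect_true(all(h$Y %in% c(0L, 1L)))
  expect_true(all(h$effort == 1L))  # full deployments: every day has effort
  # detections only where the latent state is present
  for (s in seq_along(h$species)) {
    det_sites <- rowSums(h$Y[s, , ]) > 0
    expect_true(all(sv$truth$Z[det_sites, s] == 1))
  }
  # cell probabilities sum to one everywhere
  expect_equal(rowSums(sv$truth$cells), rep(1, nrow(st)), tolerance = 1e-9)
})

test_that("covariate correlation knob induces the requested correlation", {
  cfg <- scenario_config(n_per_cell = 8L,
                         cov_correlation = list(pair = c("core_forest_5km",
                                                         "forest_100m"),
                                                rho = 0.85))
  st <- simulate_sites(cfg, seed = 11)
  expect_gt(cor(st$core_forest_5km, st$forest_100m), 0.6)
  # which is exactly the situation the restrictive-prior rule watches for
  sc <- assign_prior_scales(cbind(1, x1 = st$core_forest_5km,
                                  x2 = st$forest_100m, x3 = rnorm(nrow(st))))
  expect_equal(unname(sc[2:3]), c(1, 1))
  expect_equal(unname(sc[4]), sqrt(10))
})
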