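test_that("design building centers covariates and applies the prior rule", {
  set.seed(20)
  st <- make_sites(60)
  st$x1 <- rnorm(60); st$x2 <- 0.9 * st$x1 + sqrt(1 - 0.81) * rnorm(60)
  d <- camtrapgrad:::build_design(~ x1 + x2, st)
  varying <- apply(d$X, 2, sd) > 0
  expect_lt(max(abs(colMeans(d$X)[varying])), 1e-10)
  sc <- assign_prior_scales(d$X)
  expect_equal(unname(sc[c("x1", "x2")]), c(1, 1))  # restrictive under r > 0.6
  st$x2 <- rnorm(60)
  expect_equal(unname(assign_prior_scales(
    camtrapgrad:::build_design(~ x1 + x2, st)$X)[c("x1", "x2")]),
    rep(sqrt(10), 2))
  st$dup <- st$x1
  expect_error(camtrapgrad:::build_design(~ x1 + dup, st), "rank deficient")
})

test_that("an intercept-only fit recovers the generating parameters", {
  psi <- 0.6; p <- 0.4
  cfg <- single_species_config(psi, p)
  st <- make_sites(300)
  sv <- simulate_occupancy_survey(cfg, st, seed = 21)
  spec <- occupancy_model_spec("sp1", chains = 2, warmup = 500, iter = 1000)
  fit <- fit_occupancy(spec, sv$history, st, seed = 22)
  rep <- significance_report(fit)
  expect_true(all(rep$rhat <= 1.1))
  expect_lt(abs(rep$mean[1] - qlogis(psi)), 3 * rep$sd[1])
  expect_lt(abs(rep$mean[2] - qlogis(p)), 3 * rep$sd[2])
})

test_that("no detections anywhere pulls occupancy below the prior center", {
  st <- make_sites(80)
  h <- build_detection_history(
    data.frame(site_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
               species = character(), animal_count = integer()),
    st, species = "ghost")
  spec <- occupancy_model_spec("ghost", chains = 2, warmup = 400, iter = 800)
  fit <- fit_occupancy(spec, h, st, seed = 23)
  psi_draws <- plogis(camtrapgrad:::stack_chains(fit$mcmc)[, 1])
  expect_lt(mean(psi_draws), 0.5)  # prior median is psi = 0.5
})

test_that("posterior means are stable when iterations double", {
  cfg <- single_species_config(0.5, 0.3)
  st <- make_sites(150)
  sv <- simulate_occupancy_survey(cfg, st, seed = 24)
  f1 <- fit_occupancy(occupancy_model_spec("sp1", chains = 2, warmup = 500,
                                           iter = 1000),
                      sv$history, st, seed = 25)
  f2 <- fit_occupancy(occupancy_model_spec("sp1", chains = 2, warmup = 500,
                                           iter = 2000),
                      sv$history, st, seed = 26)
  m1 <- colMeans(camtrapgrad:::stack_chains(f1$mcmc))
  m2 <- colMeans(camtrapgrad:::stack_chains(f2$mcmc))
  expect_lt(max(abs(m1 - m2)), 0.1)  # well within Monte-Carlo error here
})

test_that("marginal occupancy reduces to the logit-inverse linear predictor", {
  cfg <- scenario_config(n_per_cell = 3L, species = default_species_params()[1:2])
  st <- simulate_sites(cfg, seed = 27)
  sv <- simulate_occupancy_survey(cfg, st, seed = 28)
  spec <- occupancy_model_spec(c("bobcat", "coyote"),
                               occ_formula = ~ urbanization,
                               chains = 2, warmup = 500, iter = 800)
  fit <- fit_occupancy(spec, sv$history, st, seed = 29)
  th <- camtrapgrad:::stack_chains(fit$mcmc)
  # independence: psi_s = plogis(f_s), and cells sum to 1 per draw/site
  for (d in c(1, 50, 100)) {
    pr <- camtrapgrad:::occu_draw_probs(fit, th[d, ])
    f <- fit$occ_design$X %*%
      cbind(th[d, fit$layout$occ[[1]]], th[d, fit$layout$occ[[2]]])
    expect_equal(unname(pr$psi), unname(plogis(f)), tolerance = 1e-12)
    expect_equal(unname(rowSums(pr$cells)), rep(1, nrow(st)), tolerance = 1e-12)
  }
  mo <- marginal_occupancy(fit, newdata = data.frame(urbanization = c(-1, 0, 1)))
  expect_true(all(mo$mean > 0 & mo$mean < 1))
  expect_true(all(mo$lower <= mo$mean & mo$mean <= mo$upper))
})

test_that("unsampled strata are flagged absent, not extrapolated", {
  cfg <- scenario_config(n_per_cell = 2L, species = default_species_params()[1])
  st <- simulate_sites(cfg, seed = 30)
  st_f <- st[st$plot_type != "yard", ]
  st_f$plot_type <- droplevels(st_f$plot_type)
  sv <- simulate_occupancy_survey(cfg, st_f, seed = 31)
  spec <- occupancy_model_spec("bobcat", occ_formula = ~ development_level,
                               chains = 2, warmup = 300, iter = 500)
  fit <- fit_occupancy(spec, sv$history, st_f, seed = 32)
  nd <- data.frame(development_level = factor(c("urban", "wild"),
                                              levels = development_levels()))
  # every level was sampled here, so none flagged
  mo <- marginal_occupancy(fit, newdata = nd)
  expect_false(any(mo$absent))
  # a level never sampled gets flagged and NA estimates
  st_sub <- st_f[st_f$development_level != "wild", ]
  st_sub$development_level <- droplevels(st_sub$development_level)
  sv2 <- simulate_occupancy_survey(cfg, st_sub, seed = 33)
  fit2 <- fit_occupancy(spec, sv2$history, st_sub, seed = 34)
  mo2 <- marginal_occupancy(fit2, newdata = nd)
  expect_true(mo2$absent[mo2$development_level == "wild"])
  expect_true(is.na(mo2$mean[mo2$development_level == "wild"]))
})

test_that("credible-interval significance flags behave as specified", {
  set.seed(35)
  pos <- matrix(abs(rnorm(2000)) + 0.1, ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  rep1 <- significance_report(pos)
  expect_true(all(rep1$significant))
  sym <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_false(any(significance_report(sym)$significant))
})

test_that("a strong simulated covariate effect is detected as significant", {
  beta <- 1.5
  hits <- vapply(1:10, function(r) {
    cfg <- scenario_config(
      species = list(sp1 = list(psi_intercept = 0, p_intercept = qlogis(0.3),
                                psi_beta = c(core_forest_5km = beta),
                                p_beta = numeric(0))),
      n_days = 14L)
    st <- make_sites(400)
    set.seed(400 + r)
    st$core_forest_5km <- rnorm(400)
    sv <- simulate_occupancy_survey(cfg, st, seed = 500 + r)
    spec <- occupancy_model_spec("sp1", occ_formula = ~ core_forest_5km,
                                 chains = 2, warmup = 500, iter = 800)
    fit <- fit_occupancy(spec, sv$history, st, seed = 600 + r)
    rep <- significance_report(fit)
    row <- rep[rep$parameter == "psi_sp1_core_forest_5km", ]
    isTRUE(row$significant) && row$mean > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the coyote-style random detection effect is estimable", {
  # simulate extra site-level detection heterogeneity for one species
  set.seed(36)
  n <- 200; J <- 14
  z <- rbinom(n, 1, 0.6)
  eps <- rnorm(n, 0, 1)
  p_site <- plogis(qlogis(0.3) + eps)
  y <- rbinom(n, J, z * p_site)
  st <- make_sites(n, n_days = J)
  Y <- array(0L, dim = c(1, n, J))
  for (i in seq_len(n)) if (y[i] > 0) Y[1, i, sample.int(J, y[i])] <- 1L
  h <- structure(list(Y = Y, effort = matrix(1L, n, J), species = "coyote",
                      site_id = st$site_id, nights = rep(J, n)),
                 class = "detection_history")
  spec <- occupancy_model_spec("coyote", random_detection = "coyote",
                               chains = 2, warmup = 600, iter = 1000)
  fit <- fit_occupancy(spec, h, st, seed = 37)
  rep <- significance_report(fit)
  sig_hat <- exp(rep$mean[rep$parameter == "log_sigma_p_coyote"])
  expect_gt(sig_hat, 0.3)   # heterogeneity detected
  expect_lt(sig_hat, 2.5)
  psi_hat <- plogis(rep$mean[rep$parameter == "psi_coyote_(Intercept)"])
  expect_lt(abs(psi_hat - 0.6), 0.15)
})
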