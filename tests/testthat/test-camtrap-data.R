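test_that("sequence collapsing applies the strict 60-s rule", {
  # gap of exactly 60 s starts a new sequence
  s <- collapse_sequences(make_records(c(0, 30, 90), counts = c(1, 2, 1)))
  expect_equal(nrow(s), 2L)
  expect_equal(s$animal_count, c(2L, 1L))   # max simultaneous, not sum
  expect_equal(s$timestamp[1], t_base)      # first photo stamps the sequence

  # chained merging: successive 59-s gaps stay one sequence
  expect_equal(nrow(collapse_sequences(make_records(c(0, 59, 118)))), 1L)

  # species and sites are collapsed separately
  two <- rbind(make_records(c(0, 30)), make_records(c(0, 30), species = "bobcat"))
  expect_equal(nrow(collapse_sequences(two)), 2L)
})

test_that("collapsing recovers a known burst structure and is idempotent", {
  set.seed(71)
  # 40 bursts, intra-burst gaps < 60 s, inter-burst gaps > 60 s
  gaps <- numeric(0)
  sizes <- sample(3:20, 40, replace = TRUE)
  for (b in seq_len(40)) {
    gaps <- c(gaps, if (b > 1) runif(1, 61, 600), runif(sizes[b] - 1, 0.5, 59))
  }
  times <- cumsum(c(0, gaps))
  rec <- make_records(times)

  # oracle: independent interval-union scan over the simulated gap structure
  n_oracle <- 1L + sum(diff(times) >= 60)
  expect_equal(n_oracle, 40L)

  s <- collapse_sequences(rec)
  expect_equal(nrow(s), 40L)
  expect_equal(s$n_photos, sizes)
  expect_identical(collapse_sequences(s)[, c("site_id", "species", "timestamp")],
                   s[, c("site_id", "species", "timestamp")])  # idempotent
})

test_that("unparseable timestamps are dropped with a warning", {
  rec <- make_records(c(0, 30))
  rec$timestamp <- c(as.character(rec$timestamp[1]), "not a time")
  expect_warning(s <- collapse_sequences(rec), "unparseable")
  expect_equal(nrow(s), 1L)
})

test_that("housing density maps to gradient levels with documented bounds", {
  expect_equal(as.character(classify_development(1500)), "urban")
  expect_equal(as.character(classify_development(0.4)), "wild")
  # inside the printed gap between exurban and suburban bins
  expect_equal(as.character(classify_development(147.0475)), "exurban")
  expect_equal(as.character(classify_development(c(0.5, 12.64, 147.048, 1000, 1000.001))),
               c("rural", "exurban", "suburban", "suburban", "urban"))
  expect_error(classify_development(-1), "non-negative")
})

test_that("daily detection histories binarize and mask effort correctly", {
  sites <- make_sites(2)
  # three sequences of one species on one day -> single 1
  rec <- make_records(c(0, 3600, 7200), site = "S001")
  h <- build_detection_history(rec, sites)
  expect_equal(sum(h$Y), 1L)
  expect_equal(dim(h$Y), c(1L, 2L, 21L))
  # undetected site: all zeros over 21 effort days
  expect_equal(sum(h$Y[1, 2, ]), 0L)
  expect_equal(sum(h$effort[2, ]), 21L)

  # unequal deployments: short site padded with zero effort and zero Y
  sites2 <- make_sites(2)
  sites2$deploy_end[2] <- sites2$deploy_start[2] + 9  # 10 nights
  h2 <- build_detection_history(rec, sites2)
  expect_equal(sum(h2$effort[2, ]), 10L)
  expect_true(all(h2$Y[, 2, h2$effort[2, ] == 0] == 0))
  expect_equal(h2$nights, c(21L, 10L))
})

test_that("records outside the deployment window are dropped with a warning", {
  sites <- make_sites(1)
  rec <- make_records(c(0, 86400 * 40), site = "S001")  # after retrieval
  expect_warning(h <- build_detection_history(rec, sites), "outside deployment")
  expect_equal(sum(h$Y), 1L)
})

test_that("a simulated survey's history matches the generator truth bit-for-bit", {
  cfg <- single_species_config(0.7, 0.3, n_days = 10L)
  st <- simulate_sites(scenario_config(n_per_cell = 1L), seed = 3)[1:20, ]
  st$deploy_end <- st$deploy_start + 9L
  sv <- simulate_occupancy_survey(cfg, st, seed = 4)
  # rebuild records from the simulated history and round-trip them
  idx <- which(sv$history$Y[1, , ] == 1L, arr.ind = TRUE)
  rec <- data.frame(site_id = st$site_id[idx[, 1]],
                    timestamp = as.POSIXct(paste(st$deploy_start[idx[, 1]] +
                                                   (idx[, 2] - 1L), "12:00:00"),
                                           tz = "UTC"),
                    species = "sp1", animal_count = 1L)
  h2 <- build_detection_history(rec, st, species = "sp1")
  expect_identical(unname(h2$Y), unname(sv$history$Y))
})

test_that("detection rates are detections per camera-night and additive", {
  sites <- make_sites(1)
  rec <- make_records(seq(0, by = 7200, length.out = 6), site = "S001")
  r <- detection_rates(collapse_sequences(rec), sites)
  expect_equal(round(r$rate, 4), 0.2857)
  expect_equal(r$camera_nights, 21L)

  # zero detections -> rate 0
  r0 <- detection_rates(collapse_sequences(rec), sites, species = "bobcat")
  expect_equal(r0$rate, 0)

  # pooled rate over species on equal effort equals sum of per-species rates
  multi <- rbind(make_records(c(0, 7200), site = "S001"),
                 make_records(14400, site = "S001", species = "deer"),
                 make_records(c(30000, 40000), site = "S001", species = "bobcat"))
  seqs <- collapse_sequences(multi)
  per <- detection_rates(seqs, sites)
  pooled <- detection_rates(seqs, sites, species = "all")
  expect_equal(pooled$rate, sum(per$rate))

  # per-animal weighting counts animals, not sequences
  rec2 <- make_records(c(0, 7200), site = "S001", counts = c(3, 2))
  ra <- detection_rates(collapse_sequences(rec2), sites, per_animal = TRUE)
  expect_equal(ra$detections, 5)

  bad <- make_sites(1)
  bad$deploy_end <- bad$deploy_start - 1
  expect_error(detection_rates(seqs, bad), "S001")
})

test_that("naive occupancy counts sites with any detection", {
  sites <- make_sites(10)
  rec <- do.call(rbind, lapply(c("S001", "S004", "S009"), function(s)
    make_records(c(0, 7200), site = s)))
  h <- build_detection_history(rec, sites)
  no <- naive_occupancy(h)
  expect_equal(unname(no$per_species), 0.3)
  # never-detected species floors at zero
  h2 <- build_detection_history(rec, sites, species = c("coyote", "bobcat"))
  expect_equal(unname(naive_occupancy(h2)$min), 0)
  expect_error(naive_occupancy(structure(list(site_id = character(0)),
                                         class = "detection_history")),
               "empty")
})

test_that("naive occupancy matches its closed-form expectation", {
  psi <- 0.6; p <- 0.4; J <- 21L; n <- 500L
  cfg <- single_species_config(psi, p)
  st <- make_sites(n)
  sv <- simulate_occupancy_survey(cfg, st, seed = 99)
  h <- sv$history
  expected <- psi * (1 - (1 - p)^J)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(naive_occupancy(h)$per_species[[1]] - expected), 3 * se)
})

test_that("effort-weighted profiles normalize within species to 100%", {
  sites <- make_sites(4)
  sites$housing_density <- c(0.1, 0.1, 5, 5)
  sites$development_level <- classify_development(sites$housing_density)
  # rate 0.3/day in wild (2 sites x 21 nights), 0.1/day in rural
  mk <- function(site, n) make_records(seq(0, by = 6000, length.out = n), site = site)
  rec <- rbind(mk("S001", 7), mk("S002", 6), mk("S003", 2), mk("S004", 2))
  wild_rate <- 13 / 42; rural_rate <- 4 / 42
  prof <- effort_weighted_detection_profile(collapse_sequences(rec), sites)
  expect_equal(sum(prof$percent), 100, tolerance = 1e-9)
  expect_equal(prof$percent[prof$development_level == "wild"],
               100 * wild_rate / (wild_rate + rural_rate))

  # doubled effort with equal detection counts halves that level's rate
  sites2 <- make_sites(3)
  sites2$housing_density <- c(0.1, 0.1, 5)
  sites2$development_level <- classify_development(sites2$housing_density)
  rec2 <- rbind(mk("S001", 2), mk("S002", 2), mk("S003", 4))
  prof2 <- effort_weighted_detection_profile(collapse_sequences(rec2), sites2)
  # wild: 4 detections / 42 nights; rural: 4 / 21 -> wild gets 1/3
  expect_equal(prof2$percent[prof2$development_level == "wild"], 100 / 3)

  # undetected species flagged with NA profile
  prof3 <- effort_weighted_detection_profile(collapse_sequences(rec2), sites2,
                                             species = c("coyote", "bobcat"))
  expect_true("bobcat" %in% attr(prof3, "flagged"))
  expect_true(all(is.na(prof3$percent[prof3$species == "bobcat"])))
})

test_that("reductions are invariant to record order and conserve totals", {
  set.seed(8)
  sites <- make_sites(6)
  sites$housing_density <- rep(c(0.2, 30, 600), each = 2)
  sites$development_level <- classify_development(sites$housing_density)
  rec <- do.call(rbind, lapply(seq_len(60), function(i)
    make_records(runif(1, 0, 8 * 86400),
                 site = sample(sites$site_id, 1),
                 species = sample(c("coyote", "deer", "bobcat"), 1))))
  shuf <- rec[sample.int(nrow(rec)), ]
  s1 <- collapse_sequences(rec); s2 <- collapse_sequences(shuf)
  expect_equal(s1, s2)

  r_all <- detection_rates(s1, sites, species = "all")
  r_sp <- detection_rates(s1, sites)
  prof <- effort_weighted_detection_profile(s1, sites)
  # conservation across groupings
  expect_equal(sum(r_all$detections), nrow(s1))
  expect_equal(sum(r_sp$detections), nrow(s1))
  expect_equal(sum(prof$detections), nrow(s1))
  h1 <- build_detection_history(s1, sites)
  h2 <- build_detection_history(s2, sites)
  expect_equal(naive_occupancy(h1)$per_species, naive_occupancy(h2)$per_species)
})
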