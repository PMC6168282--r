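#' Default species parameters for the synthetic community
#'
#' Four focal carnivores with occupancy and detection intercepts on the
#' logit scale, plus optional logit-linear coefficients on site
#' covariates. Intercepts are set to occupancy probabilities typical of
#' mesocarnivores on temperate camera grids (0.3-0.5) and daily detection
#' probabilities of 0.1-0.25 given presence; each species also responds
#' to the urbanization axis with a modest slope of either sign.
#'
#' @return named list, one entry per species, each with `psi_intercept`,
#'   `p_intercept` (logit scale), and named coefficient vectors
#'   `psi_beta`, `p_beta` over site covariates.
#' @export
default_species_params <- function() {
  sp <- function(psi, p, psi_beta = c(urbanization = 0), p_beta = NULL)
    list(psi_intercept = stats::qlogis(psi), p_intercept = stats::qlogis(p),
         psi_beta = psi_beta, p_beta = p_beta %||% numeric(0))
  list(
    bobcat   = sp(0.30, 0.10, c(urbanization = -0.9)),
    coyote   = sp(0.50, 0.20, c(urbanization = -0.3)),
    gray_fox = sp(0.35, 0.15, c(urbanization = -0.5)),
    red_fox  = sp(0.40, 0.15, c(urbanization = 0.6))
  )
}

#' Scenario configuration for the synthetic generator
#'
#' Describes a stratified camera-trap survey: two cities, five
#' development levels, four plot types (yards unavailable in urban and
#' wild strata; urban not sampled in the second city, open plots not
#' sampled in the first, mirroring the sampling frame the downstream
#' analyses expect), 21-day deployments, species-specific logit-linear
#' occupancy/detection models, optional pairwise co-occurrence
#' interactions, and Poisson photo-event intensities with burst
#' structure.
#'
#' @param cities character vector of city labels.
#' @param n_per_cell sites per sampled (city x level x plot) cell.
#' @param n_days deployment length in days.
#' @param species list of species parameter sets
#'   (see [default_species_params()]).
#' @param interactions optional S x S symmetric matrix of pairwise
#'   natural-parameter interaction strengths (0 = independence).
#' @param count_rates named vector of photo-event intensities
#'   (independent events per camera-night) for the count-model pathway.
#' @param burst list: `mean_extra_photos` (Poisson mean of photos beyond
#'   the first per event) and `max_gap` (max intra-burst gap, seconds,
#'   must be < 60).
#' @param cov_correlation optional list `(pair = c(name1, name2), rho)`
#'   inducing correlation between two continuous covariates, to exercise
#'   the restrictive-prior rule.
#' @param start_date first possible deployment date.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(cities = c("DC", "Raleigh"),
                            n_per_cell = 6L,
                            n_days = 21L,
                            species = default_species_params(),
                            interactions = NULL,
                            count_rates = c(deer = 0.30, raccoon = 0.20,
                                            coyote = 0.06, gray_fox = 0.04,
                                            red_fox = 0.05, bobcat = 0.02),
                            burst = list(mean_extra_photos = 2, max_gap = 45),
                            cov_correlation = NULL,
                            start_date = as.Date("2015-06-01")) {
  stopifnot(n_per_cell >= 1L, n_days >= 1L, length(species) >= 1L,
            burst$max_gap < 60, all(count_rates >= 0))
  S <- length(species)
  if (is.null(interactions)) interactions <- matrix(0, S, S)
  stopifnot(nrow(interactions) == S, isTRUE(all.equal(interactions, t(interactions))))
  structure(list(cities = cities, n_per_cell = as.integer(n_per_cell),
                 n_days = as.integer(n_days), species = species,
                 interactions = interactions, count_rates = count_rates,
                 burst = burst, cov_correlation = cov_correlation,
                 start_date = start_date),
            class = "scenario_config")
}

density_bin_bounds <- function() {
  # draw bounds chosen inside the half-open classification bins
  list(wild = c(0, 0.499), rural = c(0.51, 12.63),
       exurban = c(12.64, 147.047), suburban = c(147.048, 1000),
       urban = c(1000.1, 4500))
}

#' Simulate a stratified site table
#'
#' Draws housing densities within each development level's bin (so
#' [classify_development()] recovers the stratum exactly), assigns plot
#' types respecting stratum availability, and attaches covariates:
#' standard-normal continuous covariates (`core_forest_5km`,
#' `forest_100m`, `deer_rate`, `rodent_rate`, `detection_distance`,
#' `temperature`, `ndvi`), Bernoulli indicators (`hunting`,
#' `camera_reconyx`, `yard`), a derived `urbanization` axis
#' (standardized log10 housing density), and staggered 21-day deployment
#' windows.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed (optional; fixed seed gives identical tables).
#' @return site table data.frame.
#' @export
simulate_sites <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    plan <- expand.grid(city = config$cities,
                        development_level = development_levels(),
                        plot_type = plot_types(),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # stratum availability, as in the sampling frame being emulated
    plan <- plan[!(plan$plot_type == "yard" &
                     plan$development_level %in% c("urban", "wild")), ]
    if (length(config$cities) >= 2L) {
      plan <- plan[!(plan$city == config$cities[2L] &
                       plan$development_level == "urban"), ]
      plan <- plan[!(plan$city == config$cities[1L] & plan$plot_type == "open"), ]
    }
    if (nrow(plan) == 0L) stop("empty stratum plan")
    plan <- plan[rep(seq_len(nrow(plan)), each = config$n_per_cell), ]
    n <- nrow(plan)
    bounds <- density_bin_bounds()
    dens <- vapply(plan$development_level, function(l)
      stats::runif(1L, bounds[[l]][1L], bounds[[l]][2L]), numeric(1))

    start <- config$start_date + sample.int(300L, n, replace = TRUE) - 1L
    sites <- data.frame(
      site_id = sprintf("site_%04d", seq_len(n)),
      city = plan$city,
      housing_density = dens,
      development_level = factor(plan$development_level,
                                 levels = development_levels()),
      plot_type = factor(plan$plot_type, levels = plot_types()),
      deploy_start = start,
      deploy_end = start + config$n_days - 1L,
      stringsAsFactors = FALSE
    )
    cont <- c("core_forest_5km", "forest_100m", "deer_rate", "rodent_rate",
              "detection_distance", "temperature", "ndvi")
    for (v in cont) sites[[v]] <- stats::rnorm(n)
    cc <- config$cov_correlation
    if (!is.null(cc)) {
      a <- cc$pair[1L]; b <- cc$pair[2L]
      sites[[b]] <- cc$rho * sites[[a]] + sqrt(1 - cc$rho^2) * stats::rnorm(n)
    }
    sites$hunting <- stats::rbinom(n, 1L,
      ifelse(sites$development_level %in% c("rural", "wild"), 0.5, 0.1))
    sites$camera_reconyx <- ifelse(sites$city == config$cities[1L], 1L,
                                   stats::rbinom(n, 1L, 0.5))
    sites$yard <- as.integer(sites$plot_type == "yard")
    lg <- log10(sites$housing_density + 1)
    sites$urbanization <- as.numeric(scale(lg))
    sites
  })
}

linpred_covs <- function(sites, beta) {
  if (length(beta) == 0L) return(rep(0, nrow(sites)))
  as.numeric(as.matrix(sites[, names(beta), drop = FALSE]) %*% beta)
}

mvb_cells_from_params <- function(config, sites) {
  S <- length(config$species)
  covs <- function(beta) linpred_covs(sites, beta)
  f <- sapply(config$species, function(sp) sp$psi_intercept + covs(sp$psi_beta))
  f <- matrix(f, nrow = nrow(sites), ncol = S)
  natural_to_cell(f, config$interactions)
}

#' Simulate a daily occupancy survey with known truth
#'
#' Draws latent presence states per site from the multivariate-Bernoulli
#' joint distribution implied by the species' logit-linear occupancy
#' models and the pairwise interaction matrix (independent Bernoullis
#' when interactions are zero), then daily Bernoulli detections where the
#' species is present. The latent truth is returned for recovery tests.
#'
#' @param config a [scenario_config()].
#' @param sites site table from [simulate_sites()].
#' @param seed integer seed.
#' @return list: `history` (a `detection_history`), `truth` (list with
#'   `Z` sites x species presence matrix, `cells` site-level joint state
#'   probabilities, `psi` marginal occupancy, `p` detection probability
#'   per site x species).
#' @export
simulate_occupancy_survey <- function(config, sites, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    S <- length(config$species)
    n <- nrow(sites)
    cells <- mvb_cells_from_params(config, sites)
    states <- attr(cells, "states")
    if (max(abs(rowSums(cells) - 1)) > 1e-8)
      stop("cell probabilities do not sum to 1")
    ix <- apply(cells, 1L, function(pr) sample.int(nrow(states), 1L, prob = pr))
    Z <- states[ix, , drop = FALSE]
    colnames(Z) <- names(config$species)

    p <- sapply(config$species, function(sp)
      stats::plogis(sp$p_intercept + linpred_covs(sites, sp$p_beta)))
    p <- matrix(p, nrow = n, ncol = S, dimnames = list(NULL, names(config$species)))

    D <- config$n_days
    Y <- array(0L, dim = c(S, n, D),
               dimnames = list(species = names(config$species),
                               site = sites$site_id, day = NULL))
    for (s in seq_len(S)) {
      occ <- which(Z[, s] == 1L)
      if (length(occ))
        Y[s, occ, ] <- stats::rbinom(length(occ) * D, 1L, rep(p[occ, s], D))
    }
    effort <- matrix(1L, n, D)
    history <- structure(list(Y = Y, effort = effort,
                              species = names(config$species),
                              site_id = sites$site_id,
                              nights = rep(D, n)),
                         class = "detection_history")
    psi <- marginal_from_cells(cells)
    colnames(psi) <- names(config$species)
    list(history = history,
         truth = list(Z = Z, cells = cells, psi = psi, p = p))
  })
}

#' Simulate timestamped photo records with burst structure
#'
#' Independent photo events per site and species are Poisson with mean
#' `rate x camera-nights`; each event becomes a burst of photos with
#' intra-burst gaps strictly under 60 s and inter-event gaps strictly
#' over 60 s, so the 60-s sequence-collapsing rule recovers the simulated
#' event counts exactly. The realized event count per site and species is
#' returned as truth.
#'
#' @param config a [scenario_config()] (uses `count_rates` and `burst`).
#' @param sites site table.
#' @param seed integer seed.
#' @return list: `records` (photo-level data.frame: `site_id`,
#'   `timestamp`, `species`, `animal_count`), `truth` (data.frame of
#'   realized event counts per site x species).
#' @export
simulate_count_survey <- function(config, sites, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    nights <- site_nights(sites)
    rates <- config$count_rates
    out <- vector("list", nrow(sites) * length(rates))
    truth <- expand.grid(site_id = sites$site_id, species = names(rates),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$n_events <- 0L
    k <- 0L
    for (i in seq_len(nrow(sites))) {
      t0 <- as.POSIXct(paste(sites$deploy_start[i], "00:00:00"), tz = "UTC")
      horizon <- nights[i] * 86400
      for (sp in names(rates)) {
        k <- k + 1L
        n_ev <- stats::rpois(1L, rates[[sp]] * nights[i])
        if (n_ev == 0L) next
        starts <- sort(stats::runif(n_ev, 0, horizon - 600))
        prev_end <- -Inf
        times <- numeric(0); counts <- integer(0); kept <- 0L
        for (e in seq_len(n_ev)) {
          st <- max(starts[e], prev_end + 61)
          n_ph <- 1L + stats::rpois(1L, config$burst$mean_extra_photos)
          gaps <- stats::runif(n_ph - 1L, 1, config$burst$max_gap)
          tt <- st + cumsum(c(0, gaps))
          if (max(tt) > horizon - 1) next  # event would spill past retrieval
          times <- c(times, tt)
          counts <- c(counts, rep(1L + stats::rpois(1L, 0.3), n_ph))
          prev_end <- max(tt)
          kept <- kept + 1L
        }
        if (kept == 0L) next
        truth$n_events[truth$site_id == sites$site_id[i] &
                         truth$species == sp] <- kept
        out[[k]] <- data.frame(site_id = sites$site_id[i],
                               timestamp = t0 + times,
                               species = sp,
                               animal_count = counts,
                               stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(records))
      records <- data.frame(site_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                            species = character(), animal_count = integer())
    rownames(records) <- NULL
    list(records = records, truth = truth)
  })
}
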