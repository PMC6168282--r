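#' Validate detections and sites input files
#'
#' Schema and consistency checks ahead of any computation: required
#' columns, parseable timestamps, unique site ids (fatal); stratum
#' labels inconsistent with [classify_development()] of the recorded
#' housing density, or records outside deployment windows (warnings).
#'
#' @param detections_path,sites_path CSV paths.
#' @return `validation_report` list: `errors`, `warnings`, `ok`.
#' @export
validate_inputs <- function(detections_path, sites_path) {
  errors <- character(0); warnings <- character(0)
  sites <- NULL; dets <- NULL
  tryCatch(sites <- read_sites(sites_path),
           error = function(e) errors <<- c(errors, conditionMessage(e)))
  tryCatch(dets <- read_detections(detections_path),
           error = function(e) errors <<- c(errors, conditionMessage(e)))
  if (!is.null(sites)) {
    lab <- as.character(sites$development_level)
    derived <- as.character(classify_development(sites$housing_density))
    bad <- lab != derived
    if (any(bad))
      warnings <- c(warnings, paste0("development_level inconsistent with ",
                                     "housing density at site(s): ",
                                     paste(sites$site_id[bad], collapse = ", ")))
  }
  if (!is.null(dets)) {
    ts <- suppressWarnings(parse_timestamps(dets$timestamp))
    if (any(is.na(ts)))
      warnings <- c(warnings, paste0(sum(is.na(ts)),
                                     " unparseable timestamp(s)"))
    if (!is.null(sites)) {
      unknown <- setdiff(unique(dets$site_id), sites$site_id)
      if (length(unknown))
        errors <- c(errors, paste0("detections at unknown site(s): ",
                                   paste(unknown, collapse = ", ")))
    }
  }
  structure(list(errors = errors, warnings = warnings,
                 ok = length(errors) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Input validation:", if (x$ok) "OK" else "FAILED", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it, so stages are independently reproducible.
#' @param scenario a [scenario_config()] used to synthesize the survey
#'   (ignored when `detections`/`sites` paths are given).
#' @param detections,sites optional CSV paths with real survey data.
#' @param focal_species species for the occupancy and per-species count
#'   models (must be in the data).
#' @param occ_formula occupancy formula for the stratum model.
#' @param mcmc list of MCMC sizes
#'   (`chains`, `warmup`, `iter` for occupancy; `count_*` for counts).
#' @param comparison_table optional external occupancy table (CSV path
#'   or data.frame) for the cross-study comparison stage.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed,
                            scenario = scenario_config(),
                            detections = NULL, sites = NULL,
                            focal_species = c("bobcat", "coyote",
                                              "gray_fox", "red_fox"),
                            occ_formula = ~ development_level,
                            mcmc = list(chains = 2L, warmup = 600L,
                                        iter = 1200L, count_chains = 3L,
                                        count_warmup = 600L,
                                        count_iter = 1200L),
                            comparison_table = NULL) {
  stopifnot(!missing(out_dir), !missing(seed))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 scenario = scenario, detections = detections, sites = sites,
                 focal_species = focal_species, occ_formula = occ_formula,
                 mcmc = mcmc, comparison_table = comparison_table),
            class = "pipeline_config")
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain on either synthetic or supplied survey data:
#' sequence collapsing, daily detection histories, naive occupancy,
#' detection rates and effort-weighted profiles, Hill-number diversity
#' per gradient level, the Poisson detection-rate model with its trend
#' curve and PPC, the multispecies occupancy model with marginal
#' occupancy per stratum and its PPC, and (optionally) the cross-study
#' occupancy comparison. All tables are written as CSV under
#' `config$out_dir` together with a manifest (seed, config hash, file
#' checksums) that makes the run byte-reproducible.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of all stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log_msg <- function(...) message(sprintf("[%s] %s",
                                           format(Sys.time(), "%H:%M:%S"),
                                           sprintf(...)))
  if (!is.null(config$detections)) {
    if (!file.exists(config$detections) || !file.exists(config$sites))
      stop("input file missing: ",
           if (!file.exists(config$detections)) config$detections else config$sites)
    vr <- validate_inputs(config$detections, config$sites)
    if (!vr$ok) stop("input validation failed: ",
                     paste(vr$errors, collapse = "; "))
    sites <- read_sites(config$sites)
    records <- read_detections(config$detections)
    occ_survey <- NULL
    log_msg("loaded %d sites, %d photo records", nrow(sites), nrow(records))
  } else {
    log_msg("stage simulate: synthesizing survey (seed %d)", seed)
    sites <- simulate_sites(config$scenario, seed = seed + 1L)
    cnt <- simulate_count_survey(config$scenario, sites, seed = seed + 2L)
    records <- cnt$records
    occ_survey <- simulate_occupancy_survey(config$scenario, sites,
                                            seed = seed + 3L)
    log_msg("simulated %d sites, %d photo records", nrow(sites), nrow(records))
  }

  files <- character(0)
  files["sites"] <- write_stage_csv(sites, config$out_dir, "sites.csv")

  log_msg("stage collapse: 60-s sequence rule")
  seqs <- collapse_sequences(records)
  files["sequences"] <- write_stage_csv(seqs, config$out_dir, "sequences.csv")

  log_msg("stage histories: daily detection/non-detection")
  history <- build_detection_history(seqs, sites)
  nocc <- naive_occupancy(history)
  files["naive_occupancy"] <- write_stage_csv(
    data.frame(species = names(nocc$per_species),
               naive_occupancy = unname(nocc$per_species)),
    config$out_dir, "naive_occupancy.csv")

  log_msg("stage rates: detection rates and effort-weighted profile")
  rates <- detection_rates(seqs, sites)
  total_rates <- detection_rates(seqs, sites, species = "all")
  profile <- effort_weighted_detection_profile(seqs, sites)
  files["rates"] <- write_stage_csv(rates, config$out_dir, "rates.csv")
  files["profile"] <- write_stage_csv(profile, config$out_dir, "profile.csv")

  log_msg("stage diversity: Hill numbers per gradient level")
  diversity <- diversity_by_stratum(history, sites$development_level,
                                    seed = seed + 4L)
  files["diversity"] <- write_stage_csv(diversity, config$out_dir,
                                        "diversity.csv")
  div_trend <- NULL
  d1 <- diversity[diversity$q == 1, ]
  d1 <- d1[match(intersect(development_levels(), d1$stratum), d1$stratum), ]
  if (nrow(d1) >= 3L)
    div_trend <- gradient_trend(d1$estimate, d1$stratum, d1$ci_low, d1$ci_high)

  log_msg("stage count model: total-mammal Poisson rate model")
  cdat <- total_rates
  cdat$count <- as.integer(cdat$detections)
  cdat <- merge(cdat, sites[, c("site_id", "development_level", "plot_type")],
                by = "site_id", sort = FALSE)
  count_fit <- fit_count_model(count ~ development_level, cdat,
                               chains = config$mcmc$count_chains,
                               warmup = config$mcmc$count_warmup,
                               iter = config$mcmc$count_iter,
                               seed = seed + 5L)
  count_rates_by_level <- rate_by_stratum(count_fit)
  ord <- match(intersect(development_levels(),
                         as.character(count_rates_by_level$development_level)),
               as.character(count_rates_by_level$development_level))
  crl <- count_rates_by_level[ord, ]
  rate_trend <- if (nrow(crl) >= 3L)
    gradient_trend(crl$mean, as.character(crl$development_level),
                   crl$lower, crl$upper) else NULL
  count_ppc <- ppc_count(count_fit, seed = seed + 6L)
  files["count_rates"] <- write_stage_csv(count_rates_by_level,
                                          config$out_dir,
                                          "count_rates_by_level.csv")
  files["count_summary"] <- write_stage_csv(significance_report(count_fit),
                                            config$out_dir,
                                            "count_model_summary.csv")

  log_msg("stage occupancy: multispecies MVB model")
  focal <- intersect(config$focal_species, history$species)
  occ_fit <- occ_ppc <- occ_marginal <- NULL
  if (!is.null(occ_survey)) {
    occ_history <- occ_survey$history
    focal <- intersect(config$focal_species, occ_history$species)
  } else occ_history <- history
  if (length(focal) >= 1L) {
    ospec <- occupancy_model_spec(focal, occ_formula = config$occ_formula,
                                  chains = config$mcmc$chains,
                                  warmup = config$mcmc$warmup,
                                  iter = config$mcmc$iter)
    occ_fit <- fit_occupancy(ospec, subset_history(occ_history, focal),
                             sites, seed = seed + 7L)
    occ_marginal <- marginal_occupancy(occ_fit)
    occ_ppc <- ppc_occupancy(occ_fit, seed = seed + 8L)
    files["occupancy_summary"] <- write_stage_csv(
      significance_report(occ_fit), config$out_dir, "occupancy_summary.csv")
    files["marginal_occupancy"] <- write_stage_csv(
      occ_marginal, config$out_dir, "marginal_occupancy.csv")
  }

  log_msg("stage diagnostics: R-hat and PPC")
  fits <- list(count = count_fit)
  ppcs <- list(count = count_ppc)
  if (!is.null(occ_fit)) { fits$occupancy <- occ_fit; ppcs$occupancy <- occ_ppc }
  diag <- diagnostics_report(fits, ppcs)
  files["rhat"] <- write_stage_csv(diag$rhat, config$out_dir, "rhat.csv")
  files["ppc"] <- write_stage_csv(diag$ppc, config$out_dir, "ppc.csv")

  comparison <- NULL
  if (!is.null(config$comparison_table) && !is.null(occ_marginal)) {
    log_msg("stage compare: cross-study IQR overlap")
    ext <- config$comparison_table
    if (is.character(ext)) ext <- utils::read.csv(ext, stringsAsFactors = FALSE)
    ext_avg <- average_duplicate_studies(ext, exclude_omnivores =
                                           !is.null(ext$diet_class))
    dists <- list(reference = summarize_distribution(ext_avg$occupancy,
                                                     "reference"))
    om <- occ_marginal[!occ_marginal$absent, ]
    for (lev in unique(as.character(om$development_level))) {
      v <- om$mean[as.character(om$development_level) == lev]
      if (length(v) >= 2L)
        dists[[lev]] <- summarize_distribution(v, lev)
    }
    comparison <- compare_distributions(dists)
    files["comparison"] <- write_stage_csv(comparison, config$out_dir,
                                           "comparison.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("camtrapgrad")),
    seed = seed,
    config_hash = unname(tools::md5sum(
      write_stage_csv(data.frame(field = "seed", value = seed),
                      config$out_dir, "config_echo.csv"))),
    files = as.list(unname(tools::md5sum(unlist(files)))),
    file_names = as.list(basename(unlist(files))),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  jsonlite::write_json(manifest[c("seed", "config_hash", "file_names", "files")],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("pipeline complete in %.1f s", manifest$elapsed_s)
  invisible(list(sites = sites, sequences = seqs, history = history,
                 naive_occupancy = nocc, rates = rates, profile = profile,
                 diversity = diversity, diversity_trend = div_trend,
                 count_fit = count_fit, count_rates = count_rates_by_level,
                 rate_trend = rate_trend, count_ppc = count_ppc,
                 occupancy_fit = occ_fit, marginal_occupancy = occ_marginal,
                 occupancy_ppc = occ_ppc, diagnostics = diag,
                 comparison = comparison, manifest = manifest,
                 files = files))
}

#' Restrict a detection history to a species subset
#'
#' @param history a `detection_history`.
#' @param species species to keep.
#' @return a `detection_history` over the subset.
#' @export
subset_history <- function(history, species) {
  ix <- match(species, history$species)
  if (anyNA(ix)) stop("species not in history: ",
                      paste(species[is.na(ix)], collapse = ", "))
  structure(list(Y = history$Y[ix, , , drop = FALSE], effort = history$effort,
                 species = species, site_id = history$site_id,
                 nights = history$nights),
            class = "detection_history")
}
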