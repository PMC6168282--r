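#' Fit a Bayesian Poisson detection-count model
#'
#' Log-link Poisson regression of per-site independent detection counts
#' with log(camera-nights) as offset, so coefficients act on the
#' detection rate (count/day) scale: the expected count at a site is
#' `nights * exp(X beta)`. Sampled with the adaptive random-walk
#' Metropolis sampler, three chains by default, normal(0, 10) priors on
#' coefficients; split-chain R-hat attached.
#'
#' @param formula model formula whose response is the count column,
#'   e.g. `count ~ development_level + plot_type`. Continuous covariates
#'   should be mean-centered (use `center = TRUE`).
#' @param data data.frame with the response, covariates, and a
#'   camera-nights column.
#' @param nights name of the camera-nights column (default
#'   `"camera_nights"`).
#' @param center mean-center non-intercept design columns?
#' @param prior_sd normal prior SD for coefficients.
#' @param chains,warmup,iter,thin MCMC settings.
#' @param seed integer seed.
#' @return object of class `count_fit`: `mcmc` draws over coefficients,
#'   design, offsets, data, `rhat`.
#' @export
fit_count_model <- function(formula, data, nights = "camera_nights",
                            center = TRUE, prior_sd = 10,
                            chains = 3L, warmup = 1000L, iter = 3000L,
                            thin = 1L, seed = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  tt <- stats::terms(mf)
  X <- stats::model.matrix(tt, mf)
  if (qr(X)$rank < ncol(X))
    stop("design is rank deficient; collinear columns among: ",
         paste(colnames(X), collapse = ", "))
  centers <- NULL
  if (center) { X <- center_design(X); centers <- attr(X, "centers") }
  off <- log(data[[nights]])
  if (any(!is.finite(off))) stop("camera-nights must be positive and finite")

  zero_strata <- NULL
  if (ncol(X) > 1L) {
    # flag factor levels whose sites are all-zero (weakly identified)
    fac <- names(Filter(is.factor, mf[-1L]))
    for (v in fac) {
      tot <- tapply(y, mf[[v]], sum)
      if (any(tot == 0)) zero_strata <- c(zero_strata, paste0(v, "=", names(tot)[tot == 0]))
    }
    if (length(zero_strata))
      warning("all-zero stratum(s), intercept weakly identified: ",
              paste(zero_strata, collapse = ", "))
  }

  log_post <- function(beta) {
    mu <- off + X %*% beta
    sum(stats::dpois(y, exp(mu), log = TRUE)) +
      sum(stats::dnorm(beta, 0, prior_sd, log = TRUE))
  }
  init <- numeric(ncol(X))
  names(init) <- colnames(X)
  init[1L] <- log(max(sum(y), 0.5) / sum(exp(off)))
  mcmc <- run_mcmc(log_post, init, chains = chains, warmup = warmup,
                   iter = iter, thin = thin, seed = seed)
  structure(list(mcmc = mcmc, X = X, terms = tt, centers = centers,
                 y = y, offset = off, data = data, rhat = mcmc$rhat,
                 zero_strata = zero_strata),
            class = "count_fit")
}

#' @export
print.count_fit <- function(x, ...) {
  cat("Poisson count model:", length(x$y), "sites;",
      dim(x$mcmc$draws)[1L], "draws x", dim(x$mcmc$draws)[3L],
      "chains; max R-hat", round(max(x$rhat), 3), "\n")
  invisible(x)
}

#' Per-stratum detection-rate posteriors from a count fit
#'
#' Evaluates `exp(linear predictor)` (detections per camera-night) at the
#' design rows of the supplied strata, returning posterior mean and 95%
#' credible interval per stratum.
#'
#' @param fit a `count_fit`.
#' @param newdata data.frame of stratum covariate rows; defaults to the
#'   distinct sampled combinations of the model's factor covariates.
#' @param keep_draws attach the rate draws matrix?
#' @return data.frame: stratum columns plus `mean`, `lower`, `upper`.
#' @export
rate_by_stratum <- function(fit, newdata = NULL, keep_draws = FALSE) {
  stopifnot(inherits(fit, "count_fit"))
  vars <- attr(fit$terms, "term.labels")
  vars <- all.vars(stats::delete.response(fit$terms))
  if (is.null(newdata)) {
    newdata <- unique(fit$data[, vars, drop = FALSE])
    rownames(newdata) <- NULL
  }
  mfo <- stats::model.frame(stats::delete.response(fit$terms), newdata)
  Xn <- stats::model.matrix(stats::delete.response(fit$terms), mfo)
  if (!is.null(fit$centers)) Xn <- center_design(Xn, fit$centers)
  th <- stack_chains(fit$mcmc)
  rates <- exp(th %*% t(Xn))                   # draws x strata
  out <- cbind(newdata,
               data.frame(mean = colMeans(rates),
                          lower = apply(rates, 2L, stats::quantile, 0.025),
                          upper = apply(rates, 2L, stats::quantile, 0.975)))
  rownames(out) <- NULL
  if (keep_draws) attr(out, "draws") <- rates
  out
}

#' Smooth trend of estimates across ordered gradient levels
#'
#' Weighted quadratic curve through per-level estimates ordered from
#' urban to wild, weighting each level by the inverse variance implied
#' by its interval; returns fitted values at the levels, a fine fitted
#' curve, and the level where the curve peaks. This is the display
#' smoother used for both diversity and detection-rate gradients.
#'
#' @param estimates numeric vector of per-level estimates, ordered.
#' @param levels level labels (default urban -> wild).
#' @param ci_low,ci_high optional 95% bounds supplying weights.
#' @return list: `fitted` (at the levels), `curve` (data.frame `x`,
#'   `y`), `peak_level`, `coefficients`.
#' @export
gradient_trend <- function(estimates, levels = development_levels(),
                           ci_low = NULL, ci_high = NULL) {
  L <- length(estimates)
  if (L < 3L) stop("need at least 3 gradient levels for a trend")
  stopifnot(length(levels) == L)
  idx <- seq_len(L)
  w <- rep(1, L)
  if (!is.null(ci_low) && !is.null(ci_high)) {
    se <- (ci_high - ci_low) / (2 * 1.96)
    se[se <= 0] <- min(se[se > 0], 1e-3)
    w <- 1 / se^2
  }
  dfit <- data.frame(y = estimates, x = idx)
  fit <- stats::lm(y ~ x + I(x^2), data = dfit, weights = w)
  grid <- seq(1, L, by = 0.01)
  curve <- stats::predict(fit, newdata = data.frame(x = grid))
  peak <- levels[round(grid[which.max(curve)])]
  list(fitted = unname(stats::predict(fit, newdata = data.frame(x = idx))),
       curve = data.frame(x = grid, y = unname(curve)),
       peak_level = peak,
       coefficients = stats::coef(fit))
}

#' Fully parameterized per-species detection-rate model
#'
#' Fits the Poisson count model of one species' detections on a full
#' covariate design (mean-centered) with the effort offset, and returns
#' the fit together with the credible-interval significance report.
#'
#' @param species species name (filters `rates`).
#' @param rates per species x site detection table from
#'   [detection_rates()].
#' @param sites site table supplying covariates.
#' @param covariates character vector of site covariate columns.
#' @param ... passed to [fit_count_model()].
#' @return list: `fit` (a `count_fit`), `report` (significance table).
#' @export
species_covariate_model <- function(species, rates, sites, covariates, ...) {
  r <- rates[rates$species == species, ]
  if (nrow(r) == 0L) stop("no rate rows for species ", species)
  d <- merge(r, sites, by = "site_id", sort = FALSE)
  d$count <- as.integer(d$detections)
  fml <- stats::reformulate(covariates, response = "count")
  fit <- fit_count_model(fml, d, ...)
  list(fit = fit, report = significance_report(fit))
}
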