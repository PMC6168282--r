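#' Sum of squared Pearson residuals for Poisson counts
#'
#' T = sum over sites of (y - mu)^2 / mu, using the Poisson
#' variance-equals-mean relation. A zero mean with a positive count
#' yields an infinite contribution and a warning.
#'
#' @param y observed counts.
#' @param mu fitted Poisson means (same length).
#' @return scalar discrepancy T.
#' @export
pearson_T_counts <- function(y, mu) {
  stopifnot(length(y) == length(mu))
  if (any(mu < 0)) stop("fitted means must be non-negative")
  if (any(mu == 0 & y > 0)) warning("mu = 0 with y > 0: infinite contribution")
  contrib <- (y - mu)^2 / mu
  contrib[mu == 0 & y == 0] <- 0
  sum(contrib)
}

#' Bayesian p-value from discrepancy draws
#'
#' p_B = Pr(T(y_sim) > T(y)), the fraction of posterior draws whose
#' simulated-data discrepancy exceeds the observed-data discrepancy.
#' Fit is deemed adequate when 0.1 < p_B < 0.9.
#'
#' @param T_obs,T_sim equal-length vectors of discrepancies per draw.
#' @return list: `p_B`, `adequate`, `T_obs`, `T_sim`.
#' @export
bayes_p <- function(T_obs, T_sim) {
  stopifnot(length(T_obs) == length(T_sim))
  if (length(T_obs) < 100L)
    warning("fewer than 100 draws: p_B has coarse resolution")
  p <- mean(T_sim > T_obs)
  list(p_B = p, adequate = p > 0.1 && p < 0.9,
       T_obs = T_obs, T_sim = T_sim)
}

#' Posterior predictive check for a Poisson count model
#'
#' Per posterior draw, computes the squared-Pearson-residual discrepancy
#' on the observed counts and on counts simulated from that draw's
#' fitted means, then the Bayesian p-value.
#'
#' @param fit a `count_fit`.
#' @param max_draws subsample of posterior draws to use.
#' @param seed integer seed for the simulated datasets.
#' @return `ppc_result` list: `p_B`, `adequate`, `T_obs`, `T_sim`.
#' @export
ppc_count <- function(fit, max_draws = 500L, seed = NULL) {
  stopifnot(inherits(fit, "count_fit"))
  th <- stack_chains(fit$mcmc)
  keep <- if (nrow(th) > max_draws)
    round(seq(1L, nrow(th), length.out = max_draws)) else seq_len(nrow(th))
  th <- th[keep, , drop = FALSE]
  with_seed(seed, {
    To <- Ts <- numeric(nrow(th))
    for (d in seq_len(nrow(th))) {
      mu <- exp(fit$offset + as.numeric(fit$X %*% th[d, ]))
      To[d] <- pearson_T_counts(fit$y, mu)
      Ts[d] <- pearson_T_counts(stats::rpois(length(mu), mu), mu)
    }
    out <- bayes_p(To, Ts)
    class(out) <- "ppc_result"
    out
  })
}

# Bernoulli squared-Pearson discrepancy for one species' history given
# per-site detection counts y (out of J occasions) and cell mean mu
# (probability a single occasion records the species). Degenerate cells
# (mu 0 or 1) are skipped.
bernoulli_T <- function(y, J, mu) {
  ok <- mu > 0 & mu < 1
  y <- y[ok]; J <- J[ok]; mu <- mu[ok]
  v <- mu * (1 - mu)
  sum(y * (1 - mu)^2 / v + (J - y) * mu^2 / v)
}

#' Posterior predictive check for an occupancy model
#'
#' Discrepancy: sum over species, sites and occasions of squared Pearson
#' residuals of the daily detection indicators,
#' (y - mu)^2 / (mu (1 - mu)). With `conditional = TRUE` (default) the
#' occasion mean is mu = z * p with the latent state z drawn from its
#' posterior full conditional given the observed history (z = 1 when the
#' species was detected; otherwise Bernoulli with the no-detection
#' posterior probability); occasions with degenerate mu (0 or 1) are
#' skipped. With `conditional = FALSE` the unconditional margin
#' mu = psi * p is used. Replicate data are simulated per draw from the
#' fitted model (latent states and detections) and treated identically.
#'
#' @param fit an `occu_fit`.
#' @param conditional condition the residual mean on the sampled latent
#'   state (the default) or use the unconditional margin?
#' @param max_draws subsample of posterior draws.
#' @param seed integer seed.
#' @return `ppc_result` list: `p_B`, `adequate`, `T_obs`, `T_sim`.
#' @export
ppc_occupancy <- function(fit, conditional = TRUE, max_draws = 400L,
                          seed = NULL) {
  stopifnot(inherits(fit, "occu_fit"))
  th <- stack_chains(fit$mcmc)
  keep <- if (nrow(th) > max_draws)
    round(seq(1L, nrow(th), length.out = max_draws)) else seq_len(nrow(th))
  th <- th[keep, , drop = FALSE]
  Y <- fit$Y; J <- fit$J
  S <- ncol(Y); n <- nrow(Y)
  with_seed(seed, {
    To <- Ts <- numeric(nrow(th))
    for (d in seq_len(nrow(th))) {
      pr <- occu_draw_probs(fit, th[d, ])
      tobs <- tsim <- 0
      for (s in seq_len(S)) {
        psi <- pr$psi[, s]; p <- pr$p[, s]
        # observed data
        cz <- ifelse(Y[, s] > 0, 1,
                     psi * (1 - p)^J / (psi * (1 - p)^J + (1 - psi)))
        z <- stats::rbinom(n, 1L, cz)
        mu_o <- if (conditional) z * p else psi * p
        tobs <- tobs + bernoulli_T(Y[, s], J, mu_o)
        # replicate data from this draw
        z_sim <- stats::rbinom(n, 1L, psi)
        y_sim <- stats::rbinom(n, J, z_sim * p)
        cz_sim <- ifelse(y_sim > 0, 1,
                         psi * (1 - p)^J / (psi * (1 - p)^J + (1 - psi)))
        z_rep <- stats::rbinom(n, 1L, cz_sim)
        mu_s <- if (conditional) z_rep * p else psi * p
        tsim <- tsim + bernoulli_T(y_sim, J, mu_s)
      }
      To[d] <- tobs; Ts[d] <- tsim
    }
    out <- bayes_p(To, Ts)
    class(out) <- "ppc_result"
    out
  })
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("Posterior predictive check: p_B =", round(x$p_B, 3),
      if (x$adequate) "(adequate fit: 0.1 < p_B < 0.9)" else
        "(INADEQUATE fit)", "\n")
  invisible(x)
}

#' Convergence and fit diagnostics report
#'
#' Gathers the per-parameter R-hat table and, when PPC results are
#' supplied, the Bayesian p-values with adequacy flags.
#'
#' @param fits named list of `occu_fit` / `count_fit` objects.
#' @param ppcs optional named list of `ppc_result` objects.
#' @return list with `rhat` (data.frame) and `ppc` (data.frame or NULL).
#' @export
diagnostics_report <- function(fits, ppcs = NULL) {
  rh <- do.call(rbind, lapply(names(fits), function(nm) {
    data.frame(model = nm, parameter = names(fits[[nm]]$rhat),
               rhat = unname(fits[[nm]]$rhat),
               converged = unname(fits[[nm]]$rhat) <= 1.1,
               row.names = NULL)
  }))
  pp <- NULL
  if (!is.null(ppcs))
    pp <- do.call(rbind, lapply(names(ppcs), function(nm)
      data.frame(model = nm, p_B = ppcs[[nm]]$p_B,
                 adequate = ppcs[[nm]]$adequate, row.names = NULL)))
  list(rhat = rh, ppc = pp)
}
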