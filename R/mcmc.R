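#' Adaptive random-walk Metropolis sampler
#'
#' Generic MCMC over an arbitrary log-posterior: multivariate normal
#' random-walk proposals whose covariance is learned from the chain
#' during warmup (Haario-style adaptation) and whose global step size is
#' tuned toward a 23% acceptance rate by Robbins-Monro updates. Warmup
#' draws are discarded; adaptation is frozen after warmup so the kept
#' draws target the exact posterior.
#'
#' @param log_post function(theta) returning the (unnormalized) log
#'   posterior density; may return `-Inf`.
#' @param init numeric vector of starting values (finite log posterior
#'   required); each chain is started from a jittered copy.
#' @param chains number of chains.
#' @param warmup warmup (burn-in) iterations per chain, discarded.
#' @param iter post-warmup iterations kept per chain.
#' @param thin keep every `thin`-th draw.
#' @param seed integer seed.
#' @return object of class `mcmc_draws`: list with `draws` (array
#'   kept-iterations x parameters x chains), `accept` per chain, `rhat`
#'   per parameter (split-chain potential scale reduction).
#' @export
run_mcmc <- function(log_post, init, chains = 2L, warmup = 1000L,
                     iter = 2000L, thin = 1L, seed = NULL) {
  d <- length(init)
  lp0 <- log_post(init)
  if (!is.finite(lp0)) stop("log posterior not finite at init")
  with_seed(seed, {
    keep <- floor(iter / thin)
    draws <- array(NA_real_, dim = c(keep, d, chains),
                   dimnames = list(NULL, names(init), NULL))
    accept <- numeric(chains)
    for (ch in seq_len(chains)) {
      theta <- init + stats::rnorm(d, 0, 0.1 * pmax(abs(init), 0.5))
      lp <- log_post(theta)
      tries <- 0L
      while (!is.finite(lp) && tries < 50L) {
        theta <- init + stats::rnorm(d, 0, 0.02)
        lp <- log_post(theta)
        tries <- tries + 1L
      }
      if (!is.finite(lp)) { theta <- init; lp <- lp0 }

      ls <- log(2.38 / sqrt(d))
      L <- diag(d)
      hist_mat <- matrix(NA_real_, warmup, d)
      nacc <- 0L
      total <- warmup + iter
      for (t in seq_len(total)) {
        prop <- theta + exp(ls) * as.numeric(L %*% stats::rnorm(d))
        lpp <- log_post(prop)
        if (is.nan(lpp)) stop("NaN posterior density at proposal; check model")
        if (log(stats::runif(1L)) < lpp - lp) {
          theta <- prop; lp <- lpp
          if (t > warmup) nacc <- nacc + 1L
          acc <- 1
        } else acc <- 0
        if (t <= warmup) {
          hist_mat[t, ] <- theta
          ls <- ls + (acc - 0.234) / sqrt(t)          # step-size tuning
          if (t %% 200L == 0L && t >= 200L) {         # covariance refresh
            cv <- stats::cov(hist_mat[max(1L, t - 999L):t, , drop = FALSE])
            cv <- cv + diag(1e-6, d)
            L <- tryCatch(t(chol(cv)), error = function(e) diag(sqrt(diag(cv))))
          }
        } else {
          k <- t - warmup
          if (k %% thin == 0L) draws[k / thin, , ch] <- theta
        }
      }
      accept[ch] <- nacc / iter
    }
    structure(list(draws = draws, accept = accept,
                   rhat = apply(draws, 2L, rhat_matrix)),
              class = "mcmc_draws")
  })
}

rhat_matrix <- function(x) rhat(x, split = TRUE)

#' Potential scale reduction (R-hat)
#'
#' Gelman-Rubin potential scale reduction factor across chains; by
#' default each chain is split in half first (split-R-hat), which also
#' flags within-chain non-stationarity. Values at or below 1.1 are
#' treated as adequate convergence throughout the package.
#'
#' @param x draws x chains matrix (or a list of equal-length chains).
#' @param split split each chain in half before computing?
#' @return scalar R-hat.
#' @export
rhat <- function(x, split = TRUE) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("rhat needs at least two chains")
  if (split) {
    n2 <- floor(nrow(x) / 2L)
    x <- cbind(x[seq_len(n2), , drop = FALSE],
               x[nrow(x) - n2 + seq_len(n2), , drop = FALSE])
  }
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2L, stats::var))
  B <- n * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary with credible-interval significance
#'
#' Per-parameter posterior mean, SD and central 95% credible interval,
#' with a predictor flagged significant when its interval excludes zero.
#' Parameters whose R-hat exceeds 1.1 are reported but their
#' significance is set to `NA` (not converged, not claimed).
#'
#' @param fit an `mcmc_draws` object (or a draws x parameters matrix).
#' @param level credible level (default 0.95).
#' @return data.frame: `parameter`, `mean`, `sd`, `lower`, `upper`,
#'   `rhat`, `significant`.
#' @export
significance_report <- function(fit, level = 0.95) {
  if (inherits(fit, "occu_fit") || inherits(fit, "count_fit")) fit <- fit$mcmc
  if (inherits(fit, "mcmc_draws")) {
    m <- stack_chains(fit)
    rh <- fit$rhat
  } else {
    m <- as.matrix(fit)
    rh <- rep(NA_real_, ncol(m))
  }
  a <- (1 - level) / 2
  lo <- apply(m, 2L, stats::quantile, probs = a)
  hi <- apply(m, 2L, stats::quantile, probs = 1 - a)
  sig <- lo > 0 | hi < 0
  sig[!is.na(rh) & rh > 1.1] <- NA
  data.frame(parameter = colnames(m) %||% paste0("theta", seq_len(ncol(m))),
             mean = colMeans(m), sd = apply(m, 2L, stats::sd),
             lower = lo, upper = hi, rhat = rh, significant = sig,
             row.names = NULL)
}

# stack chains into one draws x parameters matrix
stack_chains <- function(fit) {
  stopifnot(inherits(fit, "mcmc_draws"))
  a <- fit$draws
  m <- matrix(aperm(a, c(1L, 3L, 2L)), ncol = dim(a)[2L])
  colnames(m) <- dimnames(a)[[2L]]
  m
}
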