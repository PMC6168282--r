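#' Incidence data for diversity estimation
#'
#' Wraps detection/non-detection data for one stratum as incidence
#' frequencies: T sampling units (camera sites) and, per species, the
#' number of units with at least one detection. Species with zero
#' incidence are excluded.
#'
#' @param x a sites x species binary (0/1) matrix, or a
#'   `detection_history` (any detection at a site counts as incidence).
#' @param sites optional site index subset (rows of the history) to
#'   restrict to one stratum.
#' @return object of class `incidence_data`: `T`, `freq` (named, > 0),
#'   `matrix` (unit x species incidence, kept for unit bootstrap).
#' @export
incidence_data <- function(x, sites = NULL) {
  if (inherits(x, "detection_history")) {
    m <- t(apply(x$Y, c(1L, 2L), max))       # sites x species
    colnames(m) <- x$species
  } else m <- as.matrix(x)
  if (!is.null(sites)) m <- m[sites, , drop = FALSE]
  if (nrow(m) < 1L) stop("empty stratum: no sampling units")
  storage.mode(m) <- "integer"
  if (any(m < 0L | m > 1L)) stop("incidence matrix must be binary")
  freq <- colSums(m)
  keep <- freq > 0L
  structure(list(T = nrow(m), freq = freq[keep],
                 matrix = m[, keep, drop = FALSE]),
            class = "incidence_data")
}

chao2_q0 <- function(Tn, freq) {
  Q1 <- sum(freq == 1L); Q2 <- sum(freq == 2L)
  if (Q1 == 0L) return(0)
  if (Q2 > 0L) ((Tn - 1) / Tn) * Q1^2 / (2 * Q2)
  else ((Tn - 1) / Tn) * Q1 * (Q1 - 1) / 2
}

#' Hill richness (q = 0) with incidence rarefaction/extrapolation
#'
#' Species richness as a Hill number of order 0 from incidence data.
#' Interpolation below the observed number of units uses the exact
#' expectation of richness in a hypergeometric subsample of units;
#' at the observed size the estimate is the observed richness;
#' extrapolation uses the Chao2 estimate of undetected richness
#' (`target_size = Inf` gives the Chao2 asymptote S_obs + Q0_hat, with
#' Q0_hat = ((T-1)/T) Q1^2 / (2 Q2), or the bias-corrected form when
#' Q2 = 0).
#'
#' @param inc an [incidence_data()] object.
#' @param target_size number of sampling units at which to evaluate
#'   (default: observed T); `Inf` for the asymptote.
#' @return `diversity_estimate` list: `q = 0`, `estimate`,
#'   `target_size`, `T`, `ci_low`/`ci_high` (NA until
#'   [rarefaction_ci()]).
#' @export
hill_richness <- function(inc, target_size = inc$T) {
  stopifnot(inherits(inc, "incidence_data"))
  if (target_size < 1) stop("target_size must be >= 1")
  Tn <- inc$T; freq <- inc$freq; S <- length(freq)
  if (target_size <= Tn) {
    t <- target_size
    # E[S(t)] = S - sum_i C(T - Y_i, t) / C(T, t)
    est <- S - sum(exp(lchoose(Tn - freq, t) - lchoose(Tn, t)))
  } else {
    if (Tn < 2L) stop("need T >= 2 units to extrapolate")
    Q0 <- chao2_q0(Tn, freq)
    Q1 <- sum(freq == 1L)
    est <- if (Q0 == 0) S
    else if (is.infinite(target_size)) S + Q0
    else S + Q0 * (1 - (1 - Q1 / (Q1 + Tn * Q0))^(target_size - Tn))
  }
  structure(list(q = 0, estimate = est, target_size = target_size, T = Tn,
                 ci_low = NA_real_, ci_high = NA_real_),
            class = "diversity_estimate")
}

#' Hill-Shannon diversity (q = 1) from incidence data
#'
#' Effective number of species of order 1: the exponential of Shannon
#' entropy of the relative incidence frequencies. At the observed size
#' the estimate is exp(-sum p_i log p_i) with p_i = Q_i / sum(Q).
#' Below the observed size the estimate is rarefied by seeded
#' Monte-Carlo subsampling of units (the incidence entropy of a
#' subsample has no separable closed form); extrapolation beyond the
#' observed size is not supported.
#'
#' @param inc an [incidence_data()] object.
#' @param target_size units at which to evaluate (<= observed T).
#' @param nrep Monte-Carlo subsamples used when interpolating.
#' @param seed integer seed for the interpolation subsampling.
#' @return `diversity_estimate` list (`q = 1`).
#' @export
hill_shannon <- function(inc, target_size = inc$T, nrep = 200L, seed = 1L) {
  stopifnot(inherits(inc, "incidence_data"))
  if (length(inc$freq) < 1L) stop("empty stratum: no species")
  if (target_size < 1) stop("target_size must be >= 1")
  if (target_size > inc$T)
    stop("q = 1 extrapolation beyond the observed number of units is not supported")
  shannon_hill <- function(freq) {
    p <- freq / sum(freq)
    exp(-sum(p * log(p)))
  }
  if (target_size == inc$T) {
    est <- shannon_hill(inc$freq)
  } else {
    m <- inc$matrix
    est <- with_seed(seed, mean(vapply(seq_len(nrep), function(b) {
      sub <- m[sample.int(nrow(m), target_size), , drop = FALSE]
      f <- colSums(sub); f <- f[f > 0L]
      if (length(f) == 0L) 1 else shannon_hill(f)
    }, numeric(1))))
  }
  structure(list(q = 1, estimate = est, target_size = target_size, T = inc$T,
                 ci_low = NA_real_, ci_high = NA_real_),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("Hill q=%d diversity: %.4f at %s units (T=%d)",
              x$q, x$estimate,
              if (is.infinite(x$target_size)) "asymptotic" else x$target_size,
              x$T))
  if (!is.na(x$ci_low)) cat(sprintf(" [%.4f, %.4f]", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' Bootstrap rarefaction confidence interval for a Hill number
#'
#' Percentile interval from a seeded bootstrap over sampling units
#' (sites resampled with replacement, the estimator recomputed at the
#' same target size each time). The interval is expanded, if necessary,
#' to contain the point estimate.
#'
#' @param inc an [incidence_data()] object (unit matrix required).
#' @param q Hill order, 0 or 1.
#' @param target_size evaluation size (default observed T).
#' @param B bootstrap replicates (>= 50).
#' @param level confidence level.
#' @param seed integer seed.
#' @return the `diversity_estimate` with `ci_low`/`ci_high` filled in.
#' @export
rarefaction_ci <- function(inc, q, target_size = inc$T, B = 200L,
                           level = 0.95, seed = 1L) {
  stopifnot(inherits(inc, "incidence_data"), q %in% c(0, 1), B >= 50L)
  if (inc$T < 2L) stop("cannot resample units: T = 1")
  point <- if (q == 0) hill_richness(inc, target_size)
           else hill_shannon(inc, target_size, seed = seed)
  ests <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- sample.int(inc$T, inc$T, replace = TRUE)
    bi <- incidence_data(inc$matrix[idx, , drop = FALSE])
    if (length(bi$freq) == 0L) return(if (q == 0) 0 else 1)
    if (q == 0) hill_richness(bi, target_size)$estimate
    else hill_shannon(bi, min(target_size, bi$T), nrep = 50L,
                      seed = b)$estimate
  }, numeric(1)))
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(ests, c(a, 1 - a)))
  point$ci_low <- min(ci[1L], point$estimate)
  point$ci_high <- max(ci[2L], point$estimate)
  point
}

#' Diversity profile per stratum
#'
#' Convenience wrapper computing Hill q = 0 and q = 1 estimates with
#' bootstrap intervals for each stratum of a survey.
#'
#' @param history a `detection_history`.
#' @param strata factor/character vector, one label per site.
#' @param target_size common evaluation size (default: smallest stratum
#'   size, so strata are compared at equal effort).
#' @param B,level,seed bootstrap settings.
#' @return data.frame: `stratum`, `q`, `estimate`, `ci_low`, `ci_high`,
#'   `T`, `target_size`.
#' @export
diversity_by_stratum <- function(history, strata, target_size = NULL,
                                 B = 200L, level = 0.95, seed = 1L) {
  stopifnot(inherits(history, "detection_history"))
  strata <- as.factor(strata)
  stopifnot(length(strata) == length(history$site_id))
  sizes <- table(strata)
  target_size <- target_size %||% min(sizes)
  out <- list()
  for (g in levels(strata)) {
    inc <- incidence_data(history, sites = which(strata == g))
    if (length(inc$freq) == 0L) next
    for (q in c(0, 1)) {
      est <- rarefaction_ci(inc, q, target_size = min(target_size, inc$T),
                            B = B, level = level,
                            seed = seed + q + 13L * match(g, levels(strata)))
      out[[length(out) + 1L]] <- data.frame(
        stratum = g, q = q, estimate = est$estimate,
        ci_low = est$ci_low, ci_high = est$ci_high,
        T = inc$T, target_size = est$target_size)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
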