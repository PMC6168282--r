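#' Specification of a multispecies occupancy model
#'
#' Configures the multivariate-Bernoulli occupancy model: which species
#' to fit jointly, logit-linear formulas for occupancy and detection
#' over site covariates (designs are mean-centered), whether pairwise
#' co-occurrence interactions are free or fixed at zero (independence,
#' the default), which species get a site-level random detection
#' intercept, the prior rule, and MCMC settings.
#'
#' Priors are logistic(0, scale) on every coefficient; any design column
#' correlated above `prior_threshold` (absolute Pearson) with another
#' column receives the restrictive logistic(0, 1) prior instead.
#'
#' @param species character vector of species to fit jointly.
#' @param occ_formula,det_formula one-sided formulas over site columns.
#' @param interactions `TRUE` frees one constant natural-parameter
#'   interaction per species pair; `FALSE` fixes all at 0.
#' @param random_detection species names receiving a site-level normal
#'   random intercept on detection (SD gets a half-normal(0,1) prior,
#'   marginalized by Gauss-Hermite quadrature).
#' @param prior_threshold,prior_scale,restrictive_scale prior rule.
#' @param chains,warmup,iter,thin MCMC settings.
#' @return object of class `occu_spec`.
#' @export
occupancy_model_spec <- function(species, occ_formula = ~1, det_formula = ~1,
                                 interactions = FALSE,
                                 random_detection = character(0),
                                 prior_threshold = 0.60,
                                 prior_scale = sqrt(10),
                                 restrictive_scale = 1,
                                 chains = 2L, warmup = 1000L, iter = 3000L,
                                 thin = 1L) {
  stopifnot(length(species) >= 1L, chains >= 1L)
  structure(list(species = species, occ_formula = occ_formula,
                 det_formula = det_formula, interactions = interactions,
                 random_detection = random_detection,
                 prior_threshold = prior_threshold,
                 prior_scale = prior_scale,
                 restrictive_scale = restrictive_scale,
                 chains = chains, warmup = warmup, iter = iter, thin = thin),
            class = "occu_spec")
}

build_design <- function(formula, data, centers = NULL) {
  mf <- stats::model.frame(formula, data)
  tt <- stats::terms(mf)
  X <- stats::model.matrix(tt, mf)
  if (qr(X)$rank < ncol(X))
    stop("design is rank deficient; drop collinear columns: ",
         paste(colnames(X), collapse = ", "))
  Xc <- center_design(X, centers)
  list(X = Xc, terms = tt, xlev = stats::.getXlevels(tt, mf),
       centers = attr(Xc, "centers"))
}

occu_param_layout <- function(spec, p_occ, p_det, occ_names, det_names) {
  S <- length(spec$species)
  nm <- c()
  idx <- list(occ = list(), det = list(), f = integer(0), lsig = integer(0))
  pos <- 0L
  for (s in seq_len(S)) {
    idx$occ[[s]] <- pos + seq_len(p_occ); pos <- pos + p_occ
    nm <- c(nm, paste0("psi_", spec$species[s], "_", occ_names))
  }
  for (s in seq_len(S)) {
    idx$det[[s]] <- pos + seq_len(p_det); pos <- pos + p_det
    nm <- c(nm, paste0("p_", spec$species[s], "_", det_names))
  }
  if (isTRUE(spec$interactions) && S >= 2L) {
    pairs <- utils::combn(spec$species, 2L)
    idx$f <- pos + seq_len(ncol(pairs)); pos <- pos + ncol(pairs)
    nm <- c(nm, paste0("f_", pairs[1L, ], ":", pairs[2L, ]))
  }
  re <- match(spec$random_detection, spec$species)
  re <- re[!is.na(re)]
  if (length(re)) {
    idx$lsig <- pos + seq_along(re); pos <- pos + length(re)
    nm <- c(nm, paste0("log_sigma_p_", spec$species[re]))
  }
  idx$re_species <- re
  idx$n_par <- pos
  idx$names <- nm
  idx
}

# detection-count sufficient statistics from a detection_history
history_counts <- function(history, species) {
  ix <- match(species, history$species)
  if (anyNA(ix)) stop("species not in history: ",
                      paste(species[is.na(ix)], collapse = ", "))
  Y <- t(apply(history$Y[ix, , , drop = FALSE], c(1L, 2L),
               function(v) sum(v)))          # sites x species
  colnames(Y) <- species
  list(Y = Y, J = rowSums(history$effort))
}

occu_loglik_fn <- function(spec, Y, J, X_occ, X_det, layout, gh = gauss_hermite(15L)) {
  S <- length(spec$species)
  n <- nrow(Y)
  states <- mvb_states(S)
  K <- nrow(states)
  all0 <- Y == 0
  # per state, which species must be all-zero (absent)
  absent_bad <- lapply(seq_len(K), function(k) which(states[k, ] == 0L))
  Fmat <- matrix(0, S, S)
  pairs <- if (S >= 2L) utils::combn(seq_len(S), 2L) else NULL
  lw <- log(gh$weights) - 0.5 * log(pi)

  function(theta) {
    B <- vapply(seq_len(S), function(s) theta[layout$occ[[s]]],
                numeric(ncol(X_occ)))
    A <- vapply(seq_len(S), function(s) theta[layout$det[[s]]],
                numeric(ncol(X_det)))
    f <- X_occ %*% matrix(B, ncol = S)
    eta <- X_det %*% matrix(A, ncol = S)
    if (length(layout$f)) {
      fv <- theta[layout$f]
      for (j in seq_along(fv)) {
        Fmat[pairs[1L, j], pairs[2L, j]] <<- fv[j]
        Fmat[pairs[2L, j], pairs[1L, j]] <<- fv[j]
      }
    }
    cells <- natural_to_cell(f, Fmat)
    lcells <- log(pmax(cells, 1e-300))

    ld1 <- matrix(0, n, S)
    for (s in seq_len(S)) {
      if (s %in% layout$re_species) {
        sigma <- exp(theta[layout$lsig[match(s, layout$re_species)]])
        node_ll <- vapply(seq_along(gh$nodes), function(q) {
          pq <- stats::plogis(eta[, s] + sqrt(2) * sigma * gh$nodes[q])
          Y[, s] * log(pq) + (J - Y[, s]) * log1p(-pq) + lw[q]
        }, numeric(n))
        ld1[, s] <- row_logsumexp(node_ll)
      } else {
        ps <- stats::plogis(eta[, s])
        ld1[, s] <- Y[, s] * log(ps) + (J - Y[, s]) * log1p(-ps)
      }
    }
    lp_states <- vapply(seq_len(K), function(k) {
      z <- states[k, ]
      v <- lcells[, k] + if (any(z == 1L))
        rowSums(ld1[, z == 1L, drop = FALSE]) else 0
      bad <- absent_bad[[k]]
      if (length(bad)) {
        ok <- rowSums(!all0[, bad, drop = FALSE]) == 0L
        v[!ok] <- -Inf
      }
      v
    }, numeric(n))
    sum(row_logsumexp(lp_states))
  }
}

#' Fit the multispecies occupancy model by MCMC
#'
#' Builds mean-centered occupancy and detection designs from the site
#' table, assigns priors by the correlation rule, and samples the
#' posterior of all species' coefficients (plus any free interaction
#' terms and random-effect SDs) with the adaptive random-walk Metropolis
#' sampler. Split-chain R-hat is attached per parameter; convergence is
#' gated at 1.1 downstream.
#'
#' @param spec an [occupancy_model_spec()].
#' @param history a `detection_history` containing the spec's species.
#' @param sites site table aligned with the history's sites.
#' @param seed integer seed.
#' @return object of class `occu_fit`.
#' @export
fit_occupancy <- function(spec, history, sites, seed = NULL) {
  stopifnot(inherits(spec, "occu_spec"), inherits(history, "detection_history"))
  if (!identical(as.character(sites$site_id), as.character(history$site_id)))
    stop("sites and history must list the same sites in the same order")
  occ <- build_design(spec$occ_formula, sites)
  det <- build_design(spec$det_formula, sites)
  varying <- apply(occ$X, 2L, stats::sd) > 0
  if (any(varying) && max(abs(colMeans(occ$X)[varying])) > 1e-10)
    stop("internal error: occupancy design not centered")
  cnt <- history_counts(history, spec$species)
  layout <- occu_param_layout(spec, ncol(occ$X), ncol(det$X),
                              colnames(occ$X), colnames(det$X))

  occ_scales <- assign_prior_scales(occ$X, spec$prior_threshold,
                                    spec$prior_scale, spec$restrictive_scale)
  det_scales <- assign_prior_scales(det$X, spec$prior_threshold,
                                    spec$prior_scale, spec$restrictive_scale)
  prior_sd <- numeric(layout$n_par)
  for (s in seq_along(spec$species)) {
    prior_sd[layout$occ[[s]]] <- occ_scales
    prior_sd[layout$det[[s]]] <- det_scales
  }
  prior_sd[layout$f] <- spec$prior_scale

  make_log_post <- function(sub_spec, Y_sub, sub_layout, sub_prior_sd) {
    loglik <- occu_loglik_fn(sub_spec, Y_sub, cnt$J, occ$X, det$X, sub_layout)
    function(theta) {
      lp <- loglik(theta)
      if (!is.finite(lp)) return(-Inf)
      pr <- sum(stats::dlogis(theta[sub_prior_sd > 0], 0,
                              sub_prior_sd[sub_prior_sd > 0], log = TRUE))
      if (length(sub_layout$lsig)) {
        sig <- exp(theta[sub_layout$lsig])
        pr <- pr + sum(stats::dnorm(sig, 0, 1, log = TRUE) + log(2) +
                         log(sig))  # half-normal on sigma, Jacobian for log scale
      }
      lp + pr
    }
  }
  make_init <- function(sub_layout, Y_sub) {
    init <- numeric(sub_layout$n_par)
    names(init) <- sub_layout$names
    for (s in seq_along(sub_layout$occ)) {
      nv <- mean(Y_sub[, s] > 0)
      init[sub_layout$occ[[s]][1L]] <- stats::qlogis(min(max(nv + 0.05, 0.05), 0.95))
      init[sub_layout$det[[s]][1L]] <- stats::qlogis(0.2)
    }
    if (length(sub_layout$lsig)) init[sub_layout$lsig] <- log(0.5)
    init
  }

  S <- length(spec$species)
  if (S > 1L && !isTRUE(spec$interactions)) {
    # independence: the joint posterior factorizes across species, so each
    # species' block is sampled on its own and the draws are assembled
    keep <- floor(spec$iter / spec$thin)
    full <- array(NA_real_, dim = c(keep, layout$n_par, spec$chains),
                  dimnames = list(NULL, layout$names, NULL))
    accept <- 0
    for (s in seq_len(S)) {
      sspec <- spec
      sspec$species <- spec$species[s]
      sspec$random_detection <- intersect(spec$random_detection,
                                          spec$species[s])
      slay <- occu_param_layout(sspec, ncol(occ$X), ncol(det$X),
                                colnames(occ$X), colnames(det$X))
      spr <- numeric(slay$n_par)
      spr[slay$occ[[1L]]] <- occ_scales
      spr[slay$det[[1L]]] <- det_scales
      Ys <- cnt$Y[, s, drop = FALSE]
      sub <- run_mcmc(make_log_post(sspec, Ys, slay, spr),
                      make_init(slay, Ys),
                      chains = spec$chains, warmup = spec$warmup,
                      iter = spec$iter, thin = spec$thin,
                      seed = if (is.null(seed)) NULL else seed + 101L * s)
      cols <- c(layout$occ[[s]], layout$det[[s]],
                if (s %in% layout$re_species)
                  layout$lsig[match(s, layout$re_species)])
      full[, cols, ] <- sub$draws
      accept <- accept + sub$accept / S
    }
    mcmc <- structure(list(draws = full, accept = accept,
                           rhat = apply(full, 2L, rhat_matrix)),
                      class = "mcmc_draws")
  } else {
    mcmc <- run_mcmc(make_log_post(spec, cnt$Y, layout, prior_sd),
                     make_init(layout, cnt$Y),
                     chains = spec$chains, warmup = spec$warmup,
                     iter = spec$iter, thin = spec$thin, seed = seed)
  }
  structure(list(mcmc = mcmc, spec = spec, layout = layout,
                 occ_design = occ, det_design = det,
                 Y = cnt$Y, J = cnt$J, sites = sites,
                 rhat = mcmc$rhat),
            class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("Multispecies occupancy fit:", paste(x$spec$species, collapse = ", "),
      "\n", nrow(x$Y), "sites;", dim(x$mcmc$draws)[1L], "draws x",
      dim(x$mcmc$draws)[3L], "chains; max R-hat",
      round(max(x$rhat), 3), "\n")
  invisible(x)
}

# per-draw site-level psi (marginal) and p for a fit; newX optional
occu_draw_probs <- function(fit, theta, X_occ = NULL, X_det = NULL) {
  spec <- fit$spec; layout <- fit$layout
  S <- length(spec$species)
  X_occ <- X_occ %||% fit$occ_design$X
  X_det <- X_det %||% fit$det_design$X
  B <- vapply(seq_len(S), function(s) theta[layout$occ[[s]]],
              numeric(ncol(X_occ)))
  A <- vapply(seq_len(S), function(s) theta[layout$det[[s]]],
              numeric(ncol(X_det)))
  f <- X_occ %*% matrix(B, ncol = S)
  Fmat <- matrix(0, S, S)
  if (length(layout$f)) {
    pairs <- utils::combn(seq_len(S), 2L)
    fv <- theta[layout$f]
    for (j in seq_along(fv)) {
      Fmat[pairs[1L, j], pairs[2L, j]] <- fv[j]
      Fmat[pairs[2L, j], pairs[1L, j]] <- fv[j]
    }
  }
  cells <- natural_to_cell(f, Fmat)
  psi <- marginal_from_cells(cells)
  p <- stats::plogis(X_det %*% matrix(A, ncol = S))
  colnames(psi) <- colnames(p) <- spec$species
  list(cells = cells, psi = psi, p = p)
}

#' Marginal occupancy by stratum
#'
#' Posterior distribution of each species' marginal occupancy
#' (for species pairs, psi_1 = psi11 + psi10) evaluated at the covariate
#' values of the supplied strata, summarized as posterior mean and 95%
#' credible interval. Strata whose covariate combination was never
#' sampled are flagged absent rather than extrapolated.
#'
#' @param fit an `occu_fit`.
#' @param newdata data.frame of stratum covariate rows (same columns the
#'   occupancy formula uses); defaults to the distinct sampled
#'   combinations of `development_level`, `plot_type` and `city` when
#'   present.
#' @param keep_draws also return the raw psi draws per stratum/species?
#' @return data.frame of stratum rows x species with `mean`, `lower`,
#'   `upper`, `absent`; draws in attribute `"draws"` when requested.
#' @export
marginal_occupancy <- function(fit, newdata = NULL, keep_draws = FALSE) {
  stopifnot(inherits(fit, "occu_fit"))
  vars <- all.vars(fit$spec$occ_formula)
  if (is.null(newdata)) {
    strat <- intersect(c("development_level", "plot_type", "city"), vars)
    if (length(strat) == 0L) strat <- vars
    newdata <- unique(fit$sites[, strat, drop = FALSE])
    rownames(newdata) <- NULL
  }
  # a stratum counts as sampled when its categorical covariate combination
  # occurs among the fitted sites; continuous covariates are not restricted
  cat_vars <- vars[vapply(vars, function(v)
    is.factor(fit$sites[[v]]) || is.character(fit$sites[[v]]), logical(1))]
  cat_vars <- intersect(cat_vars, names(newdata))
  sampled <- if (length(cat_vars)) {
    combo <- function(d) do.call(paste, c(lapply(d[cat_vars], as.character),
                                          sep = "\r"))
    combo(newdata) %in% combo(fit$sites)
  } else rep(TRUE, nrow(newdata))

  th <- stack_chains(fit$mcmc)
  S <- length(fit$spec$species)
  nd <- nrow(th)
  draws <- array(NA_real_, dim = c(nd, nrow(newdata), S))
  if (any(sampled)) {
    use <- newdata[sampled, , drop = FALSE]
    mfo <- stats::model.frame(fit$occ_design$terms, use,
                              xlev = fit$occ_design$xlev)
    Xo <- center_design(stats::model.matrix(fit$occ_design$terms, mfo),
                        fit$occ_design$centers)
    Xd0 <- matrix(0, nrow(use), ncol(fit$det_design$X))
    Xd0[, 1L] <- if (colnames(fit$det_design$X)[1L] == "(Intercept)") 1 else 0
    for (d in seq_len(nd)) {
      pr <- occu_draw_probs(fit, th[d, ], X_occ = Xo, X_det = Xd0)
      draws[d, sampled, ] <- pr$psi
    }
  }
  out <- expand.grid(row = seq_len(nrow(newdata)),
                     species = fit$spec$species,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  summ <- function(r, s, f) {
    v <- draws[, r, match(s, fit$spec$species)]
    if (all(is.na(v))) NA_real_ else f(v)
  }
  out$mean <- mapply(summ, out$row, out$species, MoreArgs = list(f = mean))
  out$lower <- mapply(summ, out$row, out$species,
                      MoreArgs = list(f = function(v) stats::quantile(v, 0.025)))
  out$upper <- mapply(summ, out$row, out$species,
                      MoreArgs = list(f = function(v) stats::quantile(v, 0.975)))
  out$absent <- !sampled[out$row]
  res <- cbind(newdata[out$row, , drop = FALSE], out[, -1L])
  rownames(res) <- NULL
  if (keep_draws) attr(res, "draws") <- draws
  res
}
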