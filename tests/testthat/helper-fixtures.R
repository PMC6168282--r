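# Shared fixture builders: everything is generated in code at test time.

t_base <- as.POSIXct("2015-06-10 08:00:00", tz = "UTC")

make_records <- function(offsets_s, site = "A", species = "coyote",
                         counts = 1L) {
  data.frame(site_id = site, timestamp = t_base + offsets_s,
             species = species,
             animal_count = rep_len(counts, length(offsets_s)),
             stringsAsFactors = FALSE)
}

make_sites <- function(n, n_days = 21L, density = 5,
                       start = as.Date("2015-06-01")) {
  data.frame(site_id = sprintf("S%03d", seq_len(n)),
             housing_density = rep_len(density, n),
             development_level = classify_development(rep_len(density, n)),
             deploy_start = start,
             deploy_end = start + n_days - 1L,
             stringsAsFactors = FALSE)
}

# single-species scenario with chosen constant psi/p and no covariates
single_species_config <- function(psi, p, n_days = 21L) {
  scenario_config(
    species = list(sp1 = list(psi_intercept = qlogis(psi),
                              p_intercept = qlogis(p),
                              psi_beta = numeric(0), p_beta = numeric(0))),
    n_days = n_days)
}

# brute-force multispecies occupancy likelihood: direct sum over all
# 2^S joint states, plain probability arithmetic (independent oracle)
brute_force_likelihood <- function(y, cells, p) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  S <- nrow(y); J <- ncol(y)
  if (is.null(dim(p))) p <- matrix(rep(p, length.out = S), S, J)
  states <- as.matrix(expand.grid(rep(list(c(1, 0)), S)))[, rev(seq_len(S)),
                                                          drop = FALSE]
  tot <- 0
  for (k in seq_len(nrow(states))) {
    z <- states[k, ]
    contrib <- cells[k]
    for (s in seq_len(S)) {
      obs <- y[s, !is.na(y[s, ])]
      ps <- p[s, !is.na(y[s, ])]
      if (z[s] == 1) {
        contrib <- contrib * prod(ps^obs * (1 - ps)^(1 - obs))
      } else if (any(obs == 1)) contrib <- contrib * 0
    }
    tot <- tot + contrib
  }
  tot
}

# Tukey hinge oracle: median-inclusive halves, computed independently
hinge_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  half <- ceiling(n / 2)
  c(q1 = median(x[1:half]), q3 = median(x[(n - half + 1):n]))
}
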