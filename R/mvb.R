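#' Joint presence states of S species
#'
#' All 2^S presence/absence states, one row per state, species in
#' columns. For two species the row order is (1,1), (1,0), (0,1), (0,0),
#' matching the cell-probability labels psi11, psi10, psi01, psi00.
#'
#' @param S number of species.
#' @return integer matrix (2^S x S).
#' @export
mvb_states <- function(S) {
  g <- as.matrix(expand.grid(rep(list(c(1L, 0L)), S)))
  g <- g[, rev(seq_len(S)), drop = FALSE]
  dimnames(g) <- list(apply(g, 1L, paste, collapse = ""),
                      paste0("sp", seq_len(S)))
  g
}

state_label <- function(states) paste0("psi", rownames(states))

#' Natural (log-linear) parameters to multivariate-Bernoulli cells
#'
#' The joint distribution over the 2^S presence states is log-linear:
#' each state's unnormalized log probability is the sum of first-order
#' terms f_s over the species present plus second-order terms f_st over
#' pairs jointly present, normalized by softmax over states. All
#' pairwise interactions zero reproduces independent Bernoullis with
#' marginal plogis(f_s). Computed on the log scale, so extreme
#' parameters never produce NaN.
#'
#' @param f first-order natural parameters: an n x S matrix (sites in
#'   rows) or a length-S vector for a single site.
#' @param interactions S x S symmetric matrix of pairwise second-order
#'   parameters (upper triangle used), a single number for S = 2, or
#'   `NULL` for independence.
#' @return n x 2^S matrix of cell probabilities, rows summing to 1;
#'   columns labelled `psi11`, `psi10`, ... for S = 2; the state matrix
#'   is attached as attribute `"states"`.
#' @export
#' @examples
#' natural_to_cell(c(0, 0))            # all four cells 0.25
#' natural_to_cell(c(1, -1), 0.5)
natural_to_cell <- function(f, interactions = NULL) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
  f <- as.matrix(f)
  if (!all(is.finite(f))) stop("non-finite natural parameters")
  S <- ncol(f)
  if (is.null(interactions)) interactions <- matrix(0, S, S)
  if (length(interactions) == 1L && S == 2L)
    interactions <- matrix(c(0, interactions, interactions, 0), 2L)
  states <- mvb_states(S)
  K <- nrow(states)
  second <- apply(states, 1L, function(z) {
    zz <- outer(z, z)
    sum(interactions[upper.tri(interactions)] * zz[upper.tri(zz)])
  })
  energy <- f %*% t(states) + matrix(second, nrow(f), K, byrow = TRUE)
  cells <- exp(energy - row_logsumexp(energy))
  cells <- cells / rowSums(cells)
  colnames(cells) <- state_label(states)
  attr(cells, "states") <- states
  cells
}

#' Marginal occupancy from joint cell probabilities
#'
#' Per-species marginal occupancy: the sum of cell probabilities over
#' all states in which the species is present (for two species,
#' psi_1 = psi11 + psi10).
#'
#' @param cells matrix from [natural_to_cell()] (states attribute
#'   required) .
#' @return n x S matrix of marginal occupancy probabilities.
#' @export
marginal_from_cells <- function(cells) {
  states <- attr(cells, "states")
  if (is.null(states)) stop("cells must carry a 'states' attribute")
  as.matrix(cells) %*% states
}

bernoulli_loglik <- function(y, p) {
  # y, p: vectors over occasions (NA y = no effort)
  ok <- !is.na(y)
  sum(y[ok] * log(p[ok]) + (1 - y[ok]) * log1p(-p[ok]))
}

#' Multispecies occupancy likelihood for one site
#'
#' Likelihood of the detection histories of S species at one site,
#' summing over the 2^S latent joint presence states: each state
#' contributes its cell probability times the Bernoulli detection
#' likelihood for every species present; a species absent in a state
#' contributes 1 if its history is all zeros and 0 otherwise. When the
#' cells factorize (all interactions zero) an optimized product of
#' independent single-species likelihoods is used; `method` can force
#' either path.
#'
#' @param y detection history: S x J binary matrix (or a vector for one
#'   species); `NA` marks occasions without effort.
#' @param cells joint state probabilities (length 2^S, ordered as
#'   [mvb_states()]); for a single species, `c(psi, 1 - psi)` or just
#'   `psi`.
#' @param p detection probability: S x J matrix, length-S vector
#'   (constant over occasions) or scalar.
#' @param method `"auto"`, `"factorized"` (valid only under
#'   independence) or `"enumerate"`.
#' @param log return the log likelihood?
#' @return likelihood in (0, 1\] (or its log).
#' @export
#' @examples
#' site_likelihood(c(1, 0), cells = 0.5, p = 0.5)        # 0.125
#' site_likelihood(c(0, 0), cells = 0.5, p = 0.5)        # 0.625
site_likelihood <- function(y, cells, p,
                            method = c("auto", "factorized", "enumerate"),
                            log = FALSE) {
  method <- match.arg(method)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  S <- nrow(y); J <- ncol(y)
  if (S == 1L && length(cells) == 1L) cells <- c(cells, 1 - cells)
  K <- 2^S
  if (length(cells) != K) stop("cells must have length 2^S")
  if (any(cells < 0) || abs(sum(cells) - 1) > 1e-8)
    stop("cells must be a probability vector over the 2^S states")
  if (is.null(dim(p))) {
    p <- matrix(rep(p, length.out = S), S, J)
  }
  if (any(p <= 0 | p >= 1)) stop("detection probabilities must lie in (0,1)")
  states <- mvb_states(S)
  psi <- as.numeric(cells %*% states)           # marginals
  det1 <- vapply(seq_len(S), function(s) bernoulli_loglik(y[s, ], p[s, ]),
                 numeric(1))
  all0 <- vapply(seq_len(S), function(s) all(y[s, ] == 0, na.rm = TRUE),
                 logical(1))

  indep <- isTRUE(all.equal(as.numeric(cells),
                            unname(apply(states, 1L, function(z)
                              prod(ifelse(z == 1L, psi, 1 - psi)))),
                            tolerance = 1e-10))
  use_fact <- switch(method,
                     auto = indep,
                     factorized = if (indep) TRUE else
                       stop("factorized method requires independent cells"),
                     enumerate = FALSE)
  if (use_fact) {
    ll <- sum(log(psi * exp(det1) + (1 - psi) * as.numeric(all0)))
  } else {
    lp <- vapply(seq_len(K), function(k) {
      z <- states[k, ]
      if (any(z == 0L & !all0)) return(-Inf)   # detected but absent
      log(cells[k]) + sum(det1[z == 1L])
    }, numeric(1))
    ll <- logsumexp(lp)
  }
  if (log) ll else exp(ll)
}
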