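#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not perturb the global random stream.
#' A `NULL` seed evaluates `code` with the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# log(sum(exp(x))) for each row of a matrix, guarded against -Inf rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Mean-center the non-intercept columns of a design matrix
#'
#' Centering is applied to every column except an all-ones intercept;
#' the column means are stored in the `"centers"` attribute so new data
#' can be centered identically.
#'
#' @param x numeric design matrix.
#' @param centers optional previously computed centers to reuse.
#' @return Centered matrix with a `"centers"` attribute.
#' @export
center_design <- function(x, centers = NULL) {
  x <- as.matrix(x)
  if (is.null(centers)) {
    centers <- colMeans(x)
    centers[apply(x, 2L, function(col) all(col == col[1L]))] <- 0  # intercept / constants
  }
  out <- sweep(x, 2L, centers, "-")
  attr(out, "centers") <- centers
  out
}

#' Assign prior scales by the covariate-correlation rule
#'
#' Coefficients receive a weakly informative logistic prior scale by
#' default; any design column whose absolute Pearson correlation with
#' another column exceeds `threshold` gets the restrictive logistic(0, 1)
#' scale instead (shrinkage for collinear predictors, in the spirit of
#' ridge regression).
#'
#' @param x design matrix (columns named).
#' @param threshold correlation threshold above which the restrictive
#'   prior applies (default 0.60).
#' @param default_scale scale of the default logistic prior.
#' @param restrictive_scale scale of the restrictive logistic prior.
#' @return named numeric vector of prior scales, one per column.
#' @export
assign_prior_scales <- function(x, threshold = 0.60,
                                default_scale = sqrt(10),
                                restrictive_scale = 1) {
  x <- as.matrix(x)
  scales <- rep(default_scale, ncol(x))
  names(scales) <- colnames(x)
  varying <- apply(x, 2L, function(col) stats::sd(col) > 0)
  if (sum(varying) >= 2L) {
    cm <- suppressWarnings(stats::cor(x[, varying, drop = FALSE]))
    diag(cm) <- 0
    hot <- apply(abs(cm) > threshold, 1L, any)
    scales[varying][hot] <- restrictive_scale
  }
  scales
}

# Gauss-Hermite nodes/weights (physicists' convention: integrates
# exp(-x^2) f(x)); Golub-Welsch via the symmetric Jacobi matrix.
gauss_hermite <- function(n = 15L) {
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  J <- diag(0, n)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1L, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
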