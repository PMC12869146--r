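#' Poisson log-likelihood of the BYM model
#'
#' The outcome model is Y_i ~ Poisson(E_i exp(eta_i)) with offset
#' E_i = population and linear predictor
#' eta_i = beta0 + x_i' beta + u_i + v_i, so the log-likelihood is
#' the sum over areas of Y_i eta_i + Y_i log E_i - E_i exp(eta_i) - log(Y_i!).
#'
#' @param panel an [area_year_panel].
#' @param beta0 scalar intercept.
#' @param beta coefficient vector matching the panel's covariates.
#' @param u,v random-effect vectors (length = number of areas); defaults 0.
#' @return scalar log-likelihood.
#' @export
bym_log_likelihood <- function(panel, beta0, beta = numeric(0),
                               u = NULL, v = NULL) {
  stopifnot(inherits(panel, "area_year_panel"))
  n <- nrow(panel)
  if (is.null(u)) u <- rep(0, n)
  if (is.null(v)) v <- rep(0, n)
  X <- panel_covariates(panel)
  if (length(beta) != ncol(X)) abort("`beta` length does not match covariates")
  pars <- c(beta0, beta, u, v)
  if (any(!is.finite(pars))) abort("non-finite parameter")
  if (length(u) != n || length(v) != n) abort("effect length mismatch")
  eta <- beta0 + as.numeric(X %*% beta) + u + v
  sum(stats::dpois(panel$count, panel$population * exp(eta), log = TRUE))
}

#' ICAR log-prior density (up to an additive constant)
#'
#' log p(u | tau_u) = ((n - c)/2) log tau_u
#'   - (tau_u / 2) * sum over neighbour pairs i ~ j of (u_i - u_j)^2,
#' where n is the number of areas and c the number of connected components
#' (the rank deficiency of the intrinsic prior); each unordered pair is
#' counted once. `u` must satisfy the per-component sum-to-zero constraint.
#'
#' @param u an `effect_vector` (from [simulate_icar_effects]) or a plain
#'   numeric vector.
#' @param tau_u positive precision.
#' @param adjacency an [adjacency_matrix].
#' @param tol tolerance for the sum-to-zero check.
#' @return scalar log-density up to a constant.
#' @export
log_icar_prior <- function(u, tau_u, adjacency, tol = 1e-6) {
  if (inherits(u, "effect_vector")) u <- u$values
  if (!(tau_u > 0)) abort("`tau_u` must be > 0")
  n <- adjacency$n_areas
  if (length(u) != n) abort("`u` length must equal the number of areas")
  comp <- connected_components(adjacency)
  sums <- tapply(u, comp$label, sum)
  if (any(abs(sums) > tol)) {
    abort("`u` violates the per-component sum-to-zero constraint")
  }
  S <- icar_pair_sum(u, adjacency)
  ((n - comp$n_components) / 2) * log(tau_u) - (tau_u / 2) * S
}

icar_pair_sum <- function(u, adjacency) {
  p <- adjacency$pairs
  if (nrow(p) == 0) return(0)
  sum((u[p[, 1]] - u[p[, 2]])^2)
}
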