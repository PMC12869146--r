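#' Brute-force posterior oracle by grid integration
#'
#' Computes posterior means and variances of all free parameters of a tiny
#' BYM Poisson model (at most 3 areas, at most 4 free parameters after the
#' sum-to-zero constraint) by direct numerical integration of the
#' unnormalized posterior on a regular tensor grid, normalized by the
#' trapezoid rule. It shares no code with the MCMC sampler's update logic
#' and serves as its correctness reference on toy problems.
#'
#' Free parameters are beta0, the covariate coefficients, the free
#' coordinates of u (per connected component of size m, the first m - 1
#' areas; the last is minus their sum; singleton components are pinned at
#' 0), and the v_i. Precisions of any included random effect must be fixed
#' via `priors` (`fixed_tau_u` / `fixed_tau_v`): integrating hyperpriors is
#' outside the oracle's remit.
#'
#' @param panel an [area_year_panel] with <= 3 areas.
#' @param adjacency matching [adjacency_matrix].
#' @param priors a [bym_priors] with fixed precisions for included effects.
#' @param spec a [model_spec].
#' @param grid_spec list with `bounds` (named list of c(lower, upper) per
#'   free parameter; omitted parameters get automatic bounds) and
#'   `n_points` (grid points per dimension, default 41).
#' @return list with `means` and `variances` (named over beta0,
#'   coefficients, and the full per-area u and v vectors, names `u1`...,
#'   `v1`...), `free_parameters`, `n_points`. Warns if > 1e-6 of the
#'   posterior mass (by boundary density) sits on the grid boundary.
#' @export
grid_posterior_oracle <- function(panel, adjacency, priors = bym_priors(),
                                  spec = model_spec(include_structured = FALSE,
                                                    include_unstructured = FALSE),
                                  grid_spec = list()) {
  stopifnot(inherits(panel, "area_year_panel"),
            inherits(adjacency, "adjacency_matrix"))
  n <- nrow(panel)
  if (n > 3) abort("the grid oracle only supports panels with <= 3 areas")
  Y <- panel$count; E <- panel$population
  X <- panel_covariates(panel)[, spec$covariate_names, drop = FALSE]
  p <- ncol(X)
  comp <- connected_components(adjacency)

  use_u <- spec$include_structured
  use_v <- spec$include_unstructured
  if (use_u && is.null(priors$fixed_tau_u)) {
    abort("fix `tau_u` in the priors to use the oracle with structured effects")
  }
  if (use_v && is.null(priors$fixed_tau_v)) {
    abort("fix `tau_v` in the priors to use the oracle with unstructured effects")
  }

  # map free u coordinates -> full u vector (per-component sum-to-zero)
  Mu <- NULL
  u_names <- character(0)
  if (use_u) {
    cols <- list()
    for (k in seq_len(comp$n_components)) {
      ix <- which(comp$label == k)
      if (length(ix) < 2) next
      for (j in ix[-length(ix)]) {
        col <- numeric(n); col[j] <- 1; col[ix[length(ix)]] <- -1
        cols[[length(cols) + 1]] <- col
        u_names <- c(u_names, paste0("u", j))
      }
    }
    Mu <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)
  }
  Mv <- if (use_v) diag(n) else NULL
  v_names <- if (use_v) paste0("v", seq_len(n)) else character(0)

  par_names <- c("beta0", spec$covariate_names, u_names, v_names)
  d <- length(par_names)
  if (d > 4) abort("oracle limited to <= 4 free parameters; got %d", d)
  n_points <- grid_spec$n_points %||% 41L
  bounds <- grid_spec$bounds %||% list()

  # automatic bounds centred on a crude rate estimate; the log-rate
  # posterior has a heavier lower tail, so the lower bound gets extra room
  b0_hat <- log((sum(Y) + 0.5) / sum(E))
  hw0 <- 6 / sqrt(sum(Y) + 1) + 0.3
  auto <- c(list(beta0 = c(b0_hat - hw0 - 2, b0_hat + hw0)),
            stats::setNames(rep(list(c(-2, 2)), p), spec$covariate_names),
            stats::setNames(rep(list(c(-3, 3)), length(u_names)), u_names),
            stats::setNames(rep(list(c(-3, 3)), length(v_names)), v_names))
  grids <- lapply(par_names, function(nm) {
    b <- bounds[[nm]] %||% auto[[nm]]
    seq(b[1], b[2], length.out = n_points)
  })
  names(grids) <- par_names
  steps <- vapply(grids, function(g) g[2] - g[1], numeric(1))
  trap <- lapply(grids, function(g) {
    w <- rep(1, length(g)); w[c(1, length(g))] <- 0.5; w
  })

  Theta <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  Wt <- Reduce(`*`, lapply(seq_len(d), function(k) {
    expand.grid(trap, KEEP.OUT.ATTRS = FALSE)[[k]]
  })) * prod(steps)
  on_boundary <- Reduce(`|`, lapply(seq_len(d), function(k) {
    g <- grids[[k]]
    Theta[, k] == g[1] | Theta[, k] == g[length(g)]
  }))

  log_post <- function(Th) {
    beta0 <- Th[, 1]
    eta <- matrix(beta0, nrow(Th), n)
    if (p > 0) eta <- eta + Th[, 1 + seq_len(p), drop = FALSE] %*% t(X)
    lp <- -0.5 * priors$beta_prec * beta0^2
    if (p > 0) {
      lp <- lp - 0.5 * priors$beta_prec *
        rowSums(Th[, 1 + seq_len(p), drop = FALSE]^2)
    }
    if (use_u && length(u_names)) {
      Uz <- Th[, 1 + p + seq_along(u_names), drop = FALSE]
      Ufull <- Uz %*% t(Mu)
      eta <- eta + Ufull
      prs <- adjacency$pairs
      if (nrow(prs)) {
        du2 <- (Ufull[, prs[, 1], drop = FALSE] -
                  Ufull[, prs[, 2], drop = FALSE])^2
        lp <- lp - 0.5 * priors$fixed_tau_u * rowSums(du2)
      }
    }
    if (use_v) {
      Vz <- Th[, 1 + p + length(u_names) + seq_len(n), drop = FALSE]
      eta <- eta + Vz
      lp <- lp - 0.5 * priors$fixed_tau_v * rowSums(Vz^2)
    }
    lp + rowSums(sweep(eta, 2, Y, `*`) - sweep(exp(eta), 2, E, `*`))
  }

  # chunked evaluation keeps memory flat for 4-D grids
  N <- nrow(Theta)
  lp <- numeric(N)
  chunk <- 200000L
  for (start in seq(1L, N, by = chunk)) {
    ix <- start:min(N, start + chunk - 1L)
    lp[ix] <- log_post(Theta[ix, , drop = FALSE])
  }
  mx <- max(lp)
  dens <- exp(lp - mx)
  Z <- sum(Wt * dens)
  if (any(on_boundary) && max(dens[on_boundary]) > 1e-6 * max(dens)) {
    warning("grid bounds may truncate posterior mass; widen `bounds`",
            call. = FALSE)
  }
  wts <- Wt * dens / Z
  means_free <- colSums(wts * Theta)
  second <- t(Theta) %*% (wts * Theta)
  cov_free <- second - outer(means_free, means_free)

  means <- c(means_free[seq_len(1 + p)])
  vars <- diag(cov_free)[seq_len(1 + p)]
  names(means) <- names(vars) <- c("beta0", spec$covariate_names)
  if (use_u) {
    iu <- 1 + p + seq_along(u_names)
    mu_full <- if (length(u_names)) as.numeric(Mu %*% means_free[iu]) else rep(0, n)
    vu_full <- if (length(u_names)) {
      diag(Mu %*% cov_free[iu, iu, drop = FALSE] %*% t(Mu))
    } else rep(0, n)
    means <- c(means, stats::setNames(mu_full, paste0("u", seq_len(n))))
    vars <- c(vars, stats::setNames(vu_full, paste0("u", seq_len(n))))
  }
  if (use_v) {
    iv <- 1 + p + length(u_names) + seq_len(n)
    means <- c(means, stats::setNames(means_free[iv], paste0("v", seq_len(n))))
    vars <- c(vars, stats::setNames(diag(cov_free)[iv], paste0("v", seq_len(n))))
  }
  list(means = means, variances = vars,
       free_parameters = par_names, n_points = n_points)
}
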