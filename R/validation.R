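#' Parameter-recovery study
#'
#' Simulates `n_reps` independent studies from the generative BYM model on
#' a grid lattice, fits each with [fit_bym_poisson], and reports, per
#' coefficient, the posterior-mean error and whether the 95% credible
#' interval covered the simulation truth. This is the package's standing
#' check that the sampler recovers known parameters under the study's data
#' regime.
#'
#' @param n_reps number of replicate simulations.
#' @param n_rows,n_cols lattice dimensions per replicate.
#' @param beta0,beta,tau_u,tau_v simulation truth (see [sim_config]).
#' @param covariate_names covariate labels (length = `length(beta)`).
#' @param mcmc an [mcmc_config]; replicate k runs with seed
#'   `mcmc$seed + 1000 * k`.
#' @param priors a [bym_priors].
#' @param population_range passed to the lattice generator.
#' @param seed seed for the simulation stream.
#' @return list with `errors` (n_reps x p matrix of posterior-mean minus
#'   truth), `covered` (n_reps x p logical), `mean_error`, `coverage`
#'   (counts per coefficient).
#' @export
parameter_recovery_study <- function(n_reps, n_rows = 20, n_cols = 20,
                                     beta0 = log(0.05),
                                     beta = c(0.3, -0.2),
                                     tau_u = 4, tau_v = 4,
                                     covariate_names = c("density", "poverty"),
                                     mcmc = mcmc_config(n_iterations = 20000L,
                                                        n_burnin = 5000L,
                                                        thin = 5L),
                                     priors = bym_priors(),
                                     population_range = c(500L, 5000L),
                                     seed = 1L) {
  p <- length(beta)
  errors <- matrix(NA_real_, n_reps, p,
                   dimnames = list(NULL, covariate_names))
  covered <- matrix(NA, n_reps, p, dimnames = list(NULL, covariate_names))
  for (k in seq_len(n_reps)) {
    cfg <- sim_config(n_rows, n_cols, beta0 = beta0, beta = beta,
                      tau_u = tau_u, tau_v = tau_v,
                      population_range = population_range,
                      seed = stage_seed(seed, k))
    lattice <- generate_grid_lattice(n_rows, n_cols,
                                     seed = stage_seed(seed, 500L + k),
                                     population_range = population_range)
    adjacency <- queen_adjacency(lattice)
    panel <- simulate_area_panel(lattice, cfg, covariate_names,
                                 adjacency = adjacency)
    mk <- mcmc; mk$seed <- mcmc$seed + 1000L * k
    fit <- fit_bym_poisson(panel, adjacency,
                           model_spec(covariate_names), priors, mk)
    for (j in seq_len(p)) {
      b <- fit$beta[, j]
      q <- stats::quantile(b, c(0.025, 0.975), names = FALSE)
      errors[k, j] <- mean(b) - beta[j]
      covered[k, j] <- q[1] <= beta[j] && beta[j] <= q[2]
    }
  }
  list(errors = errors, covered = covered,
       mean_error = colMeans(errors),
       coverage = colSums(covered))
}
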