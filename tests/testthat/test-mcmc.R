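make_sim_fit <- function(n_rows = 8, n_cols = 8, beta = c(0.3, -0.2),
                         sim_seed = 5, fit_seed = 9, n_iter = 4000,
                         burn = 1000, spec = NULL, priors = bym_priors()) {
  lat <- generate_grid_lattice(n_rows, n_cols, seed = sim_seed)
  adj <- queen_adjacency(lat)
  cfg <- sim_config(n_rows, n_cols, beta0 = log(0.05), beta = beta,
                    tau_u = 4, tau_v = 4, seed = sim_seed)
  nm <- paste0("x", seq_along(beta))
  panel <- simulate_area_panel(lat, cfg, nm, adjacency = adj)
  spec <- spec %||% model_spec(nm)
  fit <- fit_bym_poisson(panel, adj, spec, priors,
                         mcmc_config(n_iter, burn, thin = 2, seed = fit_seed))
  list(panel = panel, adj = adj, fit = fit, truth = attr(panel, "truth"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical seeds give bit-identical posterior draws", {
  a <- make_sim_fit(n_rows = 5, n_cols = 5, n_iter = 600, burn = 200)
  b <- make_sim_fit(n_rows = 5, n_cols = 5, n_iter = 600, burn = 200)
  expect_identical(a$fit$beta0, b$fit$beta0)
  expect_identical(a$fit$beta, b$fit$beta)
  expect_identical(a$fit$u, b$fit$u)
  expect_identical(a$fit$tau_u, b$fit$tau_u)
  expect_identical(a$fit$log_likelihood, b$fit$log_likelihood)
  c <- make_sim_fit(n_rows = 5, n_cols = 5, n_iter = 600, burn = 200,
                    fit_seed = 10)
  expect_false(identical(a$fit$beta0, c$fit$beta0))
})

test_that("precision full conditionals match hand computation", {
  adj <- path_adjacency(3)                      # pairs (1,2), (2,3)
  u <- c(0.5, 0.1, -0.6)
  pri <- bym_priors(tau_shape = 1, tau_rate = 5e-4)
  fc <- telespat:::tau_u_full_conditional(u, adj, n_free = 2, priors = pri)
  # pair sum = (0.5-0.1)^2 + (0.1+0.6)^2 = 0.16 + 0.49
  expect_equal(fc$shape, 1 + 2 / 2)
  expect_equal(fc$rate, 5e-4 + (0.16 + 0.49) / 2)

  v <- c(0.3, -0.2, 0.1, 0)
  fcv <- telespat:::tau_v_full_conditional(v, pri)
  expect_equal(fcv$shape, 1 + 4 / 2)
  expect_equal(fcv$rate, 5e-4 + (0.09 + 0.04 + 0.01) / 2)
})

test_that("retained draw bookkeeping and constraints hold", {
  r <- make_sim_fit(n_rows = 5, n_cols = 5, n_iter = 1000, burn = 300)
  fit <- r$fit
  expect_equal(length(fit$beta0), (1000 - 300) %/% 2)
  expect_true(all(fit$tau_u > 0) && all(fit$tau_v > 0))
  # every retained u draw satisfies the sum-to-zero constraint
  expect_lt(max(abs(rowSums(fit$u))), 1e-8)
})

test_that("with effects disabled the posterior matches a Poisson GLM", {
  lat <- generate_grid_lattice(20, 20, seed = 2)
  adj <- queen_adjacency(lat)
  cfg <- sim_config(20, 20, beta0 = log(0.05), beta = c(0.3, -0.2),
                    tau_u = Inf, tau_v = Inf, seed = 12)
  panel <- simulate_area_panel(lat, cfg, c("d", "p"), adjacency = adj)
  spec <- model_spec(c("d", "p"), include_structured = FALSE,
                     include_unstructured = FALSE)
  fit <- fit_bym_poisson(panel, adj, spec, bym_priors(beta_prec = 1e-6),
                         mcmc_config(8000, 2000, thin = 2, seed = 3))
  glm_fit <- stats::glm(count ~ d + p + offset(log(population)),
                        family = stats::poisson(),
                        data = as.data.frame(panel))
  co <- unname(stats::coef(glm_fit))
  expect_equal(mean(fit$beta0), co[1], tolerance = 0.01)
  expect_equal(unname(colMeans(fit$beta)), co[2:3], tolerance = 0.01)
})

test_that("posterior summaries are invariant to area relabelling", {
  # structured-effect-only model with fixed precision: every parameter is
  # well identified, so chains started from permuted data must agree up to
  # Monte-Carlo error
  lat <- generate_grid_lattice(6, 6, seed = 8)
  adj <- queen_adjacency(lat)
  cfg <- sim_config(6, 6, beta0 = log(0.05), beta = 0.3, tau_u = 2,
                    tau_v = Inf, seed = 14)
  panel <- simulate_area_panel(lat, cfg, "d", adjacency = adj)
  mc <- mcmc_config(8000, 2000, thin = 2, seed = 31)
  pri <- bym_priors(fixed_tau_u = 2)
  spec <- model_spec("d", include_unstructured = FALSE)
  fit <- fit_bym_poisson(panel, adj, spec, pri, mc)

  set.seed(3); perm <- sample(36)
  panel_p <- area_year_panel(as.data.frame(panel)[perm, ], "d")
  pos <- match(seq_len(36), perm)
  pairs_p <- cbind(pos[adj$pairs[, 1]], pos[adj$pairs[, 2]])
  adj_p <- adjacency_matrix(36, pairs_p, area_ids = panel_p$area_id)
  fit_p <- fit_bym_poisson(panel_p, adj_p, spec, pri, mc)

  # scalar summaries agree up to Monte-Carlo error
  expect_equal(mean(fit_p$beta0), mean(fit$beta0), tolerance = 0.03)
  expect_equal(mean(fit_p$beta), mean(fit$beta), tolerance = 0.03)
  # area-level posterior means follow the permutation
  expect_equal(colMeans(fit_p$u), colMeans(fit$u)[perm], tolerance = 0.1)
})

test_that("the sampler recovers simulation truth on a moderate lattice", {
  r <- make_sim_fit(n_rows = 12, n_cols = 12, sim_seed = 44, fit_seed = 45,
                    n_iter = 6000, burn = 1500)
  bmean <- colMeans(r$fit$beta)
  q1 <- stats::quantile(r$fit$beta[, 1], c(0.025, 0.975))
  q2 <- stats::quantile(r$fit$beta[, 2], c(0.025, 0.975))
  expect_lt(abs(bmean[1] - 0.3), 0.15)
  expect_lt(abs(bmean[2] + 0.2), 0.15)
  expect_true(q1[1] < 0.3 + 0.2 && q1[2] > 0.3 - 0.2)
  # precision estimates land in a plausible band around 4
  expect_gt(mean(r$fit$tau_v), 1)
  expect_lt(mean(r$fit$tau_v), 20)
})

test_that("degenerate inputs are handled as documented", {
  pan <- toy_panel(c(0, 0, 0), c(10, 10, 10))
  adj <- path_adjacency(3)
  expect_warning(
    fit_bym_poisson(pan, adj, model_spec(), bym_priors(),
                    mcmc_config(300, 100, seed = 1)),
    "no telehealth outcomes")
  # mismatched area sets
  adj_bad <- adjacency_matrix(3, rbind(c(1, 2)), area_ids = c("X", "Y", "Z"))
  expect_error(
    fit_bym_poisson(pan, adj_bad, model_spec(), bym_priors(),
                    mcmc_config(300, 100, seed = 1)),
    "identical areas|same order")
  expect_error(mcmc_config(n_iterations = 100, n_burnin = 200), "n_burnin")
  expect_error(mcmc_config(thin = 0), "thin")
})
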