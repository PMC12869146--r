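# a synthetic bym_fit with fully controlled draws
fake_fit <- function(beta_draws, u = NULL, v = NULL, beta0 = NULL,
                     loglik = NULL, covariates = colnames(beta_draws)) {
  n_draw <- nrow(beta_draws)
  n_area <- if (!is.null(u)) ncol(u) else 2L
  structure(list(
    beta0 = beta0 %||% rep(0, n_draw),
    beta = beta_draws,
    u = u %||% matrix(0, n_draw, n_area),
    v = v %||% matrix(0, n_draw, n_area),
    tau_u = rep(1, n_draw), tau_v = rep(1, n_draw),
    log_likelihood = loglik,
    spec = model_spec(covariates),
    n_areas = n_area,
    area_id = sprintf("T%02d", seq_len(n_area))),
    class = "bym_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("RR summaries transform degenerate and simulated draws correctly", {
  z <- matrix(0, 200, 1, dimnames = list(NULL, "d"))
  rr0 <- summarize_rr(fake_fit(z))
  expect_equal(rr0$rr, 1)
  expect_equal(rr0$lower, 1)
  expect_equal(rr0$upper, 1)

  rr2 <- summarize_rr(fake_fit(matrix(log(2), 200, 1,
                                      dimnames = list(NULL, "d"))))
  expect_equal(rr2$rr, 2)

  set.seed(6)
  b <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "d"))
  rrn <- summarize_rr(fake_fit(b))
  expect_equal(rrn$rr, exp(mean(b)), tolerance = 1e-12)
  # quantile oracle on the simulated draws
  expect_equal(rrn$lower, exp(quantile(b, 0.025, names = FALSE)))
  expect_equal(rrn$upper, exp(quantile(b, 0.975, names = FALSE)))
  # sample-quantile Monte-Carlo error on the exp scale is ~0.2 at the top end
  expect_lt(abs(rrn$lower - exp(-1.96)), 0.05)
  expect_lt(abs(rrn$upper - exp(1.96)), 0.3)

  expect_error(summarize_rr(fake_fit(matrix(0, 50, 1,
                                            dimnames = list(NULL, "d")))),
               "100")
})

test_that("DIC identities hold exactly, including the point-mass case", {
  pan <- toy_panel(c(3, 7), c(10, 20))
  # point-mass posterior: every draw identical -> pD = 0, DIC = Dhat
  ll <- bym_log_likelihood(pan, beta0 = -1)
  fit <- fake_fit(matrix(numeric(0), 150, 0), beta0 = rep(-1, 150),
                  loglik = rep(ll, 150), covariates = character(0))
  d <- compute_dic(fit, pan)
  expect_equal(d$p_d, 0)
  expect_equal(d$dic, d$d_hat)

  # spread posterior: the identity dic = dbar + p_d holds exactly
  set.seed(8)
  b0 <- rnorm(300, -1, 0.1)
  lls <- vapply(b0, function(b) bym_log_likelihood(pan, b), numeric(1))
  fit2 <- fake_fit(matrix(numeric(0), 300, 0), beta0 = b0, loglik = lls,
                   covariates = character(0))
  d2 <- compute_dic(fit2, pan)
  expect_equal(d2$dic - d2$dbar - d2$p_d, 0)
  expect_gt(d2$p_d, 0)

  fit2$log_likelihood <- NULL
  expect_error(compute_dic(fit2, pan), "log-likelihood")
})

test_that("compare_models ranks specs and rejects singleton lists", {
  lat <- generate_grid_lattice(6, 6, seed = 3)
  adj <- queen_adjacency(lat)
  cfg <- sim_config(6, 6, beta0 = log(0.05), beta = 0.3, seed = 9)
  pan <- simulate_area_panel(lat, cfg, "d", adjacency = adj)
  mc <- mcmc_config(1500, 500, seed = 2)
  specs <- list(model_spec("d", name = "m1"), model_spec("d", name = "m1b"))
  tab <- compare_models(pan, adj, bym_priors(), mc, specs)
  expect_equal(nrow(tab), 2L)
  expect_true(tab$best[1] && !tab$best[2])
  expect_equal(order(tab$dic), 1:2)
  # duplicate specs agree to Monte-Carlo tolerance
  expect_lt(abs(tab$dic[1] - tab$dic[2]), 15)
  expect_error(compare_models(pan, adj, bym_priors(), mc,
                              specs[1]), "at least two")
})

test_that("exceedance probabilities match a brute-force recount", {
  # two areas with strongly separated rates
  set.seed(4)
  n_draw <- 400
  u <- cbind(rnorm(n_draw, -1, 0.2), rnorm(n_draw, 1, 0.2))
  u <- u - rowMeans(u)  # keep the constraint
  pan <- toy_panel(c(2, 40), c(100, 100))
  fit <- fake_fit(matrix(numeric(0), n_draw, 0), u = u,
                  beta0 = rnorm(n_draw, -2, 0.1), covariates = character(0))
  exc <- exceedance_probabilities(fit, pan, threshold_fraction = 0.5)
  # independent recount straight from the draws
  rates <- exp(fit$beta0 + u)
  ref <- (rates[, 1] * 100 + rates[, 2] * 100) / 200
  manual <- colMeans(rates < 0.5 * ref)
  expect_equal(exc$probability, unname(manual))
  expect_gt(exc$probability[1], 0.9)
  expect_lt(exc$probability[2], 0.1)

  # limits: infinite threshold -> 1, vanishing threshold -> 0
  expect_equal(exceedance_probabilities(fit, pan, 1e9)$probability, c(1, 1))
  expect_equal(exceedance_probabilities(fit, pan, 1e-9)$probability, c(0, 0))
  # fixed reference mode
  excf <- exceedance_probabilities(fit, pan, 1, reference = "fixed_value",
                                   reference_value = median(rates))
  expect_true(all(excf$probability >= 0 & excf$probability <= 1))
  expect_error(exceedance_probabilities(fit, pan, 1, reference = "fixed_value"),
               "reference_value")
})

test_that("exceedance probability is monotone in the threshold fraction", {
  set.seed(12)
  n_draw <- 300
  u <- matrix(rnorm(n_draw * 2, 0, 0.5), n_draw, 2)
  u <- u - rowMeans(u)
  pan <- toy_panel(c(5, 9), c(50, 80))
  fit <- fake_fit(matrix(numeric(0), n_draw, 0), u = u,
                  beta0 = rnorm(n_draw, -2, 0.3), covariates = character(0))
  probs <- sapply(c(0.25, 0.5, 0.75, 1, 1.5), function(f) {
    exceedance_probabilities(fit, pan, f)$probability
  })
  for (i in 1:2) expect_true(all(diff(probs[i, ]) >= 0))
})
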