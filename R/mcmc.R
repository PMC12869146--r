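#' Model specification for the BYM Poisson regression
#'
#' Selects which fixed effects and which random-effect components a fit
#' includes. The study's comparison set is: a crude model (one covariate,
#' unstructured effect only), a crude spatial model (one covariate, both
#' effects), and a fully adjusted spatial model (all covariates, both
#' effects). With both random effects disabled the model reduces to a plain
#' Poisson GLM with offset, which is allowed.
#'
#' @param covariate_names ordered character vector of panel covariate
#'   columns to include (empty for intercept-only).
#' @param include_structured include the ICAR spatial effect u?
#' @param include_unstructured include the iid normal effect v?
#' @param name optional label used in model-comparison tables.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(covariate_names = character(0),
                       include_structured = TRUE,
                       include_unstructured = TRUE,
                       name = NULL) {
  structure(list(covariate_names = as.character(covariate_names),
                 include_structured = isTRUE(include_structured),
                 include_unstructured = isTRUE(include_unstructured),
                 name = name %||% paste0(
                   if (length(covariate_names)) paste(covariate_names,
                                                      collapse = "+")
                   else "intercept",
                   if (include_structured) "+u" else "",
                   if (include_unstructured) "+v" else "")),
            class = "model_spec")
}

#' Priors for the BYM model
#'
#' Independent normal priors with common precision `beta_prec` on the
#' intercept and coefficients (the default 1e-4 is effectively vague on
#' standardized covariates), and Gamma(shape, rate) hyperpriors on the two
#' random-effect precisions (the default Gamma(1, 0.0005) is a common
#' weakly-informative choice for disease-mapping precisions). Either
#' precision can instead be fixed at a known value, which is how the
#' sampler is compared against low-dimensional integration oracles.
#'
#' @param beta_prec normal prior precision for beta0 and beta.
#' @param tau_shape,tau_rate Gamma hyperprior parameters shared by tau_u and
#'   tau_v.
#' @param fixed_tau_u,fixed_tau_v optional positive values; when given, the
#'   corresponding precision is held fixed instead of being sampled.
#' @return list of class `bym_priors`.
#' @export
bym_priors <- function(beta_prec = 1e-4, tau_shape = 1, tau_rate = 5e-4,
                       fixed_tau_u = NULL, fixed_tau_v = NULL) {
  if (!(beta_prec > 0) || !(tau_shape > 0) || !(tau_rate > 0)) {
    abort("prior parameters must be strictly positive")
  }
  for (f in list(fixed_tau_u, fixed_tau_v)) {
    if (!is.null(f) && !(f > 0)) abort("fixed precisions must be > 0")
  }
  structure(list(beta_prec = beta_prec, tau_shape = tau_shape,
                 tau_rate = tau_rate, fixed_tau_u = fixed_tau_u,
                 fixed_tau_v = fixed_tau_v),
            class = "bym_priors")
}

#' MCMC settings
#'
#' @param n_iterations total Metropolis-within-Gibbs sweeps.
#' @param n_burnin sweeps discarded as burn-in (`< n_iterations`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; fixed seeds give bit-identical output.
#' @param proposal_scales named list of initial random-walk SDs for the
#'   `u`, `v` and `beta` blocks.
#' @param adapt_during_burnin adapt proposal scales during burn-in toward
#'   an acceptance rate of ~0.44 for single-site blocks (~0.25 for the
#'   multivariate beta block), frozen afterwards so the chain is a valid
#'   fixed-kernel Markov chain.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 10000L, n_burnin = 2000L, thin = 1L,
                        seed = 1L,
                        proposal_scales = list(u = 0.5, v = 0.5, beta = 0.05),
                        adapt_during_burnin = TRUE) {
  n_iterations <- as.integer(n_iterations)
  n_burnin <- as.integer(n_burnin)
  thin <- as.integer(thin)
  if (!(n_iterations > n_burnin) || n_burnin < 0) {
    abort("need n_iterations > n_burnin >= 0")
  }
  if (thin < 1) abort("`thin` must be >= 1")
  sc <- proposal_scales
  if (any(unlist(sc) <= 0)) abort("proposal scales must be > 0")
  structure(list(n_iterations = n_iterations, n_burnin = n_burnin,
                 thin = thin, seed = as.integer(seed),
                 proposal_scales = sc,
                 adapt_during_burnin = isTRUE(adapt_during_burnin)),
            class = "mcmc_config")
}

#' Fit the BYM Poisson spatial model by Metropolis-within-Gibbs
#'
#' Samples the posterior of the Besag-York-Mollie convolution model
#' \deqn{Y_i \sim Poisson(E_i e^{\eta_i}), \quad
#'       \eta_i = \beta_0 + x_i'\beta + u_i + v_i,}
#' with an intrinsic CAR prior on the structured effect u over the supplied
#' adjacency graph, iid normal unstructured effects v, normal priors on the
#' coefficients and Gamma hyperpriors (or fixed values) for the precisions.
#'
#' The sweep is: (1) normal random-walk Metropolis updates of beta0 and of
#' each coefficient beta_j, each with its own adapted scale (coefficients
#' have very different conditional posterior scales than the intercept, so
#' per-coordinate updates mix far better than a joint block);
#' (2) single-site random-walk updates of every u_i,
#' vectorized over the colour classes of a proper colouring of the graph
#' (sites in one class are conditionally independent, so their accept/reject
#' decisions may be made simultaneously); (3) recentring of u to the
#' per-component sum-to-zero constraint, with beta0 absorbing the global
#' shift; (4) vectorized single-site updates of every v_i; (5) conjugate
#' Gamma Gibbs draws of tau_u (shape + (n - c)/2, rate + pairsum/2) and
#' tau_v (shape + n/2, rate + sum(v^2)/2). Structured effects of isolated
#' areas (degree 0) are held at 0; those areas are carried by v. Proposal
#' scales adapt during burn-in only.
#'
#' @param panel an [area_year_panel] with standardized covariates.
#' @param adjacency an [adjacency_matrix] over exactly the panel's areas,
#'   in panel order.
#' @param spec a [model_spec].
#' @param priors a [bym_priors].
#' @param mcmc an [mcmc_config].
#' @return object of class `bym_fit`: retained draws (`beta0`, `beta`, `u`,
#'   `v`, `tau_u`, `tau_v`, `log_likelihood`), acceptance rates, final
#'   proposal scales, and the spec/dimensions needed by summaries.
#' @export
fit_bym_poisson <- function(panel, adjacency, spec = model_spec(),
                            priors = bym_priors(), mcmc = mcmc_config()) {
  stopifnot(inherits(panel, "area_year_panel"),
            inherits(adjacency, "adjacency_matrix"),
            inherits(spec, "model_spec"), inherits(priors, "bym_priors"),
            inherits(mcmc, "mcmc_config"))
  n <- nrow(panel)
  if (adjacency$n_areas != n) abort("panel and adjacency area counts differ")
  if (!is.null(adjacency$area_ids) &&
      !identical(adjacency$area_ids, panel$area_id)) {
    abort("panel and adjacency must cover identical areas in the same order")
  }
  X <- panel_covariates(panel)[, spec$covariate_names, drop = FALSE]
  p <- ncol(X)
  if (p > 0) {
    mns <- colMeans(X); sds <- apply(X, 2, stats::sd)
    if (any(abs(mns) > 0.05) || any(abs(sds - 1) > 0.1)) {
      warning("covariates do not look standardized; ",
              "coefficients are interpreted per 1 SD", call. = FALSE)
    }
  }
  Y <- panel$count; E <- panel$population
  if (all(Y == 0) && p == 0) {
    warning("no telehealth outcomes observed anywhere; ",
            "the posterior is driven by the priors", call. = FALSE)
  }
  const_ll <- sum(Y * log(E) - lgamma(Y + 1))

  use_u <- spec$include_structured
  use_v <- spec$include_unstructured
  comp <- connected_components(adjacency)
  W <- adjacency_to_sparse(adjacency)
  deg <- adjacency$degrees
  free_u <- which(deg > 0)          # isolated areas keep u = 0
  rank_def <- comp$n_components
  n_free <- n - rank_def            # ICAR rank = n - c (singletons included)
  classes <- colour_classes(adjacency)
  classes <- lapply(classes, function(ix) ix[deg[ix] > 0])
  classes <- classes[vapply(classes, length, 0L) > 0]
  comp_split <- split(seq_len(n), comp$label)
  comp_split <- comp_split[vapply(comp_split, length, 0L) > 1]

  # state
  beta0 <- log((sum(Y) + 0.5) / sum(E))
  beta <- rep(0, p)
  u <- rep(0, n); v <- rep(0, n)
  tau_u <- priors$fixed_tau_u %||% 10
  tau_v <- priors$fixed_tau_v %||% 10
  eta <- rep(beta0, n)

  sc_u <- mcmc$proposal_scales$u %||% 0.5
  sc_v <- mcmc$proposal_scales$v %||% 0.5
  sc_b <- rep(mcmc$proposal_scales$beta %||% 0.05, p + 1)

  n_keep <- (mcmc$n_iterations - mcmc$n_burnin) %/% mcmc$thin
  draws <- list(beta0 = numeric(n_keep),
                beta = matrix(NA_real_, n_keep, p,
                              dimnames = list(NULL, spec$covariate_names)),
                u = matrix(NA_real_, n_keep, n),
                v = matrix(NA_real_, n_keep, n),
                tau_u = numeric(n_keep), tau_v = numeric(n_keep),
                log_likelihood = numeric(n_keep))

  acc <- c(beta = 0, u = 0, v = 0)
  att <- c(beta = 0, u = 0, v = 0)
  acc_b <- numeric(p + 1); att_b <- numeric(p + 1)
  acc_tot <- acc; att_tot <- att
  adapt_every <- 50L
  kept <- 0L

  with_seed(mcmc$seed, {
    for (iter in seq_len(mcmc$n_iterations)) {
      ## beta0 and each beta_j: scalar random walks with individual scales
      for (j in seq_len(p + 1)) {
        db <- stats::rnorm(1, 0, sc_b[j])
        if (j == 1) {
          eta_star <- eta + db
          cur <- beta0
        } else {
          eta_star <- eta + db * X[, j - 1]
          cur <- beta[j - 1]
        }
        dll <- sum(Y * (eta_star - eta) - E * (exp(eta_star) - exp(eta)))
        dpr <- -0.5 * priors$beta_prec * ((cur + db)^2 - cur^2)
        att["beta"] <- att["beta"] + 1
        att_b[j] <- att_b[j] + 1
        if (log(stats::runif(1)) < dll + dpr) {
          if (j == 1) beta0 <- beta0 + db else beta[j - 1] <- beta[j - 1] + db
          eta <- eta_star
          acc["beta"] <- acc["beta"] + 1
          acc_b[j] <- acc_b[j] + 1
        }
      }

      ## structured effects, one colour class at a time
      if (use_u) {
        for (ix in classes) {
          s_nb <- as.numeric(W %*% u)[ix]
          prop <- stats::rnorm(length(ix), u[ix], sc_u)
          eta_i <- eta[ix]
          eta_s <- eta_i + (prop - u[ix])
          dll_i <- Y[ix] * (eta_s - eta_i) - E[ix] * (exp(eta_s) - exp(eta_i))
          dpr_i <- -0.5 * tau_u *
            (deg[ix] * (prop^2 - u[ix]^2) - 2 * s_nb * (prop - u[ix]))
          ok <- log(stats::runif(length(ix))) < dll_i + dpr_i
          u[ix[ok]] <- prop[ok]
          eta[ix[ok]] <- eta_s[ok]
          acc["u"] <- acc["u"] + sum(ok)
          att["u"] <- att["u"] + length(ix)
        }
        # identifiability: recentre u per component, beta0 absorbs the shift
        shift <- numeric(n)
        for (ix in comp_split) shift[ix] <- mean(u[ix])
        gshift <- sum(shift) / n
        u <- u - shift
        beta0 <- beta0 + gshift
        eta <- eta - shift + gshift
      }

      ## unstructured effects, all sites at once (iid prior, local likelihood)
      if (use_v) {
        prop <- stats::rnorm(n, v, sc_v)
        eta_s <- eta + (prop - v)
        dll_i <- Y * (eta_s - eta) - E * (exp(eta_s) - exp(eta))
        dpr_i <- -0.5 * tau_v * (prop^2 - v^2)
        ok <- log(stats::runif(n)) < dll_i + dpr_i
        v[ok] <- prop[ok]
        eta[ok] <- eta_s[ok]
        acc["v"] <- acc["v"] + sum(ok)
        att["v"] <- att["v"] + n
      }

      ## conjugate precision updates
      if (use_u && is.null(priors$fixed_tau_u)) {
        fc <- tau_u_full_conditional(u, adjacency, n_free, priors)
        tau_u <- stats::rgamma(1, fc$shape, rate = fc$rate)
      }
      if (use_v && is.null(priors$fixed_tau_v)) {
        fc <- tau_v_full_conditional(v, priors)
        tau_v <- stats::rgamma(1, fc$shape, rate = fc$rate)
      }

      ## burn-in adaptation (Robbins-Monro style on the log scale)
      if (mcmc$adapt_during_burnin && iter <= mcmc$n_burnin &&
          iter %% adapt_every == 0L) {
        tune <- function(scale, a, m, target) {
          if (any(m == 0)) return(scale)
          pmin(10, pmax(1e-3, scale * exp(a / m - target)))
        }
        sc_b <- tune(sc_b, acc_b, att_b, 0.44)
        sc_u <- tune(sc_u, acc["u"], att["u"], 0.44)
        sc_v <- tune(sc_v, acc["v"], att["v"], 0.44)
        acc_tot <- acc_tot + acc; att_tot <- att_tot + att
        acc[] <- 0; att[] <- 0
        acc_b[] <- 0; att_b[] <- 0
      }

      ## store
      if (iter > mcmc$n_burnin &&
          (iter - mcmc$n_burnin) %% mcmc$thin == 0L) {
        kept <- kept + 1L
        draws$beta0[kept] <- beta0
        if (p > 0) draws$beta[kept, ] <- beta
        draws$u[kept, ] <- u
        draws$v[kept, ] <- v
        draws$tau_u[kept] <- tau_u
        draws$tau_v[kept] <- tau_v
        draws$log_likelihood[kept] <-
          sum(Y * eta - E * exp(eta)) + const_ll
      }
    }
  })
  acc_tot <- acc_tot + acc; att_tot <- att_tot + att

  structure(list(beta0 = draws$beta0, beta = draws$beta,
                 u = draws$u, v = draws$v,
                 tau_u = draws$tau_u, tau_v = draws$tau_v,
                 log_likelihood = draws$log_likelihood,
                 acceptance = ifelse(att_tot > 0, acc_tot / att_tot, NA),
                 proposal_scales = list(u = sc_u, v = sc_v, beta = sc_b),
                 spec = spec, priors = priors, mcmc = mcmc,
                 area_id = panel$area_id, n_areas = n,
                 components = comp),
            class = "bym_fit")
}

# Gamma full conditional of the ICAR precision:
# shape + (n - c)/2, rate + (sum over pairs of squared differences)/2
tau_u_full_conditional <- function(u, adjacency, n_free, priors) {
  list(shape = priors$tau_shape + n_free / 2,
       rate = priors$tau_rate + icar_pair_sum(u, adjacency) / 2)
}

# Gamma full conditional of the iid-effect precision:
# shape + n/2, rate + sum(v^2)/2
tau_v_full_conditional <- function(v, priors) {
  list(shape = priors$tau_shape + length(v) / 2,
       rate = priors$tau_rate + sum(v^2) / 2)
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf("<bym_fit> %d retained draws, %d areas, model %s\n",
              length(x$beta0), x$n_areas, x$spec$name))
  cat(sprintf("  acceptance: beta %.2f, u %.2f, v %.2f\n",
              x$acceptance["beta"], x$acceptance["u"], x$acceptance["v"]))
  invisible(x)
}

#' Linear predictor draws from a fit
#'
#' Reconstructs the draws x retained-iteration matrix of eta_i = beta0 +
#' x_i' beta + u_i + v_i, the quantity exceedance maps and fitted rates are
#' based on.
#'
#' @param fit a `bym_fit`.
#' @param panel the [area_year_panel] the fit used.
#' @return numeric matrix, retained draws in rows, areas in columns.
#' @export
posterior_eta <- function(fit, panel) {
  stopifnot(inherits(fit, "bym_fit"))
  X <- panel_covariates(panel)[, fit$spec$covariate_names, drop = FALSE]
  eta <- matrix(fit$beta0, nrow = length(fit$beta0), ncol = fit$n_areas)
  if (ncol(X) > 0) eta <- eta + fit$beta %*% t(X)
  eta + fit$u + fit$v
}

#' Split-chain convergence diagnostics
#'
#' Potential scale reduction (split-Rhat) and a crude effective sample size
#' for the scalar chains of a fit; values of Rhat close to 1 indicate the
#' two halves of the chain agree. Reported for monitoring; thresholds are a
#' matter for the analyst, not hard failures.
#'
#' @param fit a `bym_fit`.
#' @return data.frame with columns `parameter`, `rhat`, `ess`.
#' @export
convergence_diagnostics <- function(fit) {
  chains <- c(list(beta0 = fit$beta0),
              if (ncol(fit$beta) > 0)
                stats::setNames(asplit(fit$beta, 2), colnames(fit$beta)),
              list(tau_u = fit$tau_u, tau_v = fit$tau_v))
  rows <- lapply(names(chains), function(nm) {
    x <- as.numeric(chains[[nm]])
    m <- length(x) %/% 2
    if (m < 10 || stats::sd(x) == 0) {
      return(data.frame(parameter = nm, rhat = NA_real_, ess = NA_real_))
    }
    halves <- list(x[1:m], x[(m + 1):(2 * m)])
    W <- mean(vapply(halves, stats::var, 0))
    B <- m * stats::var(vapply(halves, mean, 0))
    varp <- (m - 1) / m * W + B / m
    rhat <- sqrt(varp / W)
    rho1 <- stats::cor(x[-1], x[-length(x)])
    ess <- length(x) * max(1e-3, (1 - rho1) / (1 + rho1))
    data.frame(parameter = nm, rhat = rhat, ess = ess)
  })
  do.call(rbind, rows)
}

#' Serialize posterior samples
#'
#' Long-format CSV (iteration, parameter, value) for the scalar parameters
#' and a JSON summary (posterior means and 95% intervals).
#'
#' @param fit a `bym_fit`.
#' @param csv_path,json_path file paths (either may be `NULL` to skip).
#' @export
write_posterior_samples <- function(fit, csv_path = NULL, json_path = NULL) {
  scalars <- c(list(beta0 = fit$beta0),
               if (ncol(fit$beta) > 0)
                 stats::setNames(asplit(fit$beta, 2), colnames(fit$beta)),
               list(tau_u = fit$tau_u, tau_v = fit$tau_v))
  if (!is.null(csv_path)) {
    long <- do.call(rbind, lapply(names(scalars), function(nm) {
      data.frame(iteration = seq_along(scalars[[nm]]), parameter = nm,
                 value = as.numeric(scalars[[nm]]))
    }))
    utils::write.csv(long, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    summ <- lapply(scalars, function(x) {
      x <- as.numeric(x)
      list(mean = mean(x),
           q2.5 = unname(stats::quantile(x, 0.025)),
           q97.5 = unname(stats::quantile(x, 0.975)))
    })
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
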