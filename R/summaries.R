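#' Relative risks with 95% credible intervals
#'
#' The reporting convention of spatial rate regressions: the point estimate
#' is exp(posterior mean of beta_j) and the interval is exp of the 2.5% and
#' 97.5% posterior quantiles of beta_j. Because exp is monotone, quantiles
#' commute with the transform, so these are identically the quantiles of
#' the RR draws; covariates are standardized, so each RR reads as the
#' multiplicative change in the outcome rate per 1 SD of the covariate.
#'
#' @param samples a `bym_fit` with at least 100 retained draws.
#' @return data.frame of class `rr_summary`: `covariate`, `rr`, `lower`,
#'   `upper`.
#' @export
summarize_rr <- function(samples) {
  stopifnot(inherits(samples, "bym_fit"))
  if (length(samples$beta0) < 100) {
    abort("need at least 100 retained draws to summarize RRs")
  }
  nm <- colnames(samples$beta)
  rows <- lapply(nm, function(j) {
    b <- samples$beta[, j]
    q <- stats::quantile(b, c(0.025, 0.975), names = FALSE)
    data.frame(covariate = j, rr = exp(mean(b)),
               lower = exp(q[1]), upper = exp(q[2]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(covariate = character(0), rr = numeric(0),
               lower = numeric(0), upper = numeric(0))
  class(out) <- c("rr_summary", "data.frame")
  out
}

#' Deviance information criterion
#'
#' DIC = Dbar + pD with Dbar the posterior mean of the deviance
#' D = -2 log-likelihood, pD = Dbar - Dhat, and Dhat the deviance at the
#' posterior means of all parameters. The deviance is conditional on the
#' random effects (the "focus" is the area-level rates), the usual choice
#' for convolution models. Lower DIC indicates better fit; a negative pD
#' (possible when the posterior mean is a poor summary) triggers a warning,
#' not a failure.
#'
#' @param samples a `bym_fit` with stored per-draw log-likelihoods.
#' @param panel the [area_year_panel] the fit used.
#' @return list of class `dic_result`: `dbar`, `d_hat`, `p_d`, `dic`.
#' @export
compute_dic <- function(samples, panel) {
  stopifnot(inherits(samples, "bym_fit"))
  if (is.null(samples$log_likelihood) || !length(samples$log_likelihood)) {
    abort("fit carries no log-likelihood trace")
  }
  dbar <- mean(-2 * samples$log_likelihood)
  beta_bar <- if (ncol(samples$beta) > 0) colMeans(samples$beta) else numeric(0)
  # evaluate at the posterior means, against the covariates the fit used
  sub <- panel
  attr(sub, "covariate_names") <- samples$spec$covariate_names
  ll_hat <- bym_log_likelihood(
    sub, beta0 = mean(samples$beta0), beta = beta_bar,
    u = colMeans(samples$u), v = colMeans(samples$v))
  d_hat <- -2 * ll_hat
  p_d <- dbar - d_hat
  if (p_d < 0) {
    warning("negative effective number of parameters (pD < 0)", call. = FALSE)
  }
  structure(list(dbar = dbar, d_hat = d_hat, p_d = p_d, dic = dbar + p_d),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.2f (Dbar = %.2f, pD = %.2f)\n", x$dic, x$dbar, x$p_d))
  invisible(x)
}

#' Compare model specifications by DIC
#'
#' Fits each specification on the same panel (with a spec-indexed seed so
#' fits are independent but reproducible) and returns the DIC table sorted
#' ascending, flagging the winner.
#'
#' @param panel an [area_year_panel].
#' @param adjacency matching [adjacency_matrix].
#' @param priors a [bym_priors].
#' @param mcmc an [mcmc_config]; spec k runs with seed `mcmc$seed + k - 1`.
#' @param specs list of at least two [model_spec] objects.
#' @return data.frame with columns `model`, `dbar`, `d_hat`, `p_d`, `dic`,
#'   `best`, sorted by DIC; attribute `fits` holds the `bym_fit` objects.
#' @export
compare_models <- function(panel, adjacency, priors, mcmc, specs) {
  if (!is.list(specs) || length(specs) < 2) {
    abort("`specs` must list at least two model specifications")
  }
  fits <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    mk <- mcmc; mk$seed <- mcmc$seed + k - 1L
    fit <- tryCatch(fit_bym_poisson(panel, adjacency, spec, priors, mk),
                    error = function(e) {
                      abort("model '%s' failed to fit: %s", spec$name,
                            conditionMessage(e))
                    })
    dic <- compute_dic(fit, panel)
    fits[[k]] <- fit
    rows[[k]] <- data.frame(model = spec$name, dbar = dic$dbar,
                            d_hat = dic$d_hat, p_d = dic$p_d, dic = dic$dic,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$dic)
  tab <- tab[ord, ]
  tab$best <- seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Exceedance probabilities for low telehealth use
#'
#' For each area, the posterior probability that its fitted per-person rate
#' exp(eta_i) falls below `threshold_fraction` times a reference rate —
#' e.g. `threshold_fraction = 0.5` flags areas whose use is at least 50%
#' below the state average. With `reference = "state_mean"` the reference is
#' the population-weighted mean fitted rate computed within each draw (so
#' rates and reference stay coherent draw by draw); with `"fixed_value"` it
#' is the supplied `reference_value` (rate per person).
#'
#' @param samples a `bym_fit`.
#' @param panel the [area_year_panel] the fit used.
#' @param threshold_fraction positive multiplier of the reference rate.
#' @param reference `"state_mean"` or `"fixed_value"`.
#' @param reference_value rate per person when `reference = "fixed_value"`.
#' @return data.frame of class `exceedance_map`: `area_id`, `probability`;
#'   attributes `threshold_fraction` and `reference`.
#' @export
exceedance_probabilities <- function(samples, panel, threshold_fraction,
                                     reference = c("state_mean", "fixed_value"),
                                     reference_value = NULL) {
  stopifnot(inherits(samples, "bym_fit"))
  reference <- match.arg(reference)
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0) {
    abort("`threshold_fraction` must be > 0")
  }
  rates <- exp(posterior_eta(samples, panel))
  ref <- if (reference == "state_mean") {
    as.numeric(rates %*% panel$population) / sum(panel$population)
  } else {
    if (is.null(reference_value) || !(reference_value > 0)) {
      abort("supply a positive `reference_value` for reference = 'fixed_value'")
    }
    rep(reference_value, nrow(rates))
  }
  prob <- colMeans(rates < threshold_fraction * ref)
  out <- data.frame(area_id = panel$area_id, probability = prob,
                    stringsAsFactors = FALSE)
  attr(out, "threshold_fraction") <- threshold_fraction
  attr(out, "reference") <- reference
  class(out) <- c("exceedance_map", "data.frame")
  out
}

#' Join an exceedance map onto the lattice GeoJSON
#'
#' Writes the lattice as a GeoJSON FeatureCollection with the exceedance
#' probability added to each feature's properties, ready for choropleth
#' rendering by any GIS tool.
#'
#' @param map an `exceedance_map`.
#' @param lattice the [area_lattice].
#' @param path output file.
#' @export
write_exceedance_geojson <- function(map, lattice, path) {
  stopifnot(inherits(map, "exceedance_map"))
  prob <- map$probability[match(lattice$areas$area_id, map$area_id)]
  feats <- lapply(seq_len(n_areas(lattice)), function(i) {
    id <- lattice$areas$area_id[i]
    ring <- lattice$polygons[[id]]
    list(type = "Feature",
         properties = list(area_id = id,
                           population = lattice$areas$population[i],
                           rurality = lattice$areas$rurality[i],
                           exceedance_probability = prob[i],
                           threshold_fraction = attr(map, "threshold_fraction")),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(ring, 1, c,
                                                         simplify = FALSE)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
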