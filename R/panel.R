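#' Simulation configuration
#'
#' Bundles the ground-truth parameters of a synthetic study: grid size, the
#' log-linear model coefficients, random-effect precisions, area population
#' range, the expected telehealth fraction of visits, and the seed. These are
#' the "truth" that parameter-recovery tests try to get back.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param beta0 intercept on the log-rate scale (log expected outcomes per
#'   person); e.g. `log(0.05)` means 5 outcomes per 100 residents.
#' @param beta numeric vector of covariate coefficients, log relative risk
#'   per 1 SD of each (standardized) covariate. May be empty.
#' @param tau_u,tau_v positive precisions of the spatially structured (ICAR)
#'   and unstructured (iid normal) random effects; `Inf` disables an effect.
#' @param population_range c(min, max) area population.
#' @param telehealth_share expected fraction of all visits that are
#'   telehealth, between 0 and 1; drives the volume of in-person records
#'   emitted alongside the telehealth outcomes.
#' @param outcome whether the panel count is unique telehealth `"patients"`
#'   (the study's rate numerator) or telehealth `"visits"`.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_rows, n_cols, beta0, beta = numeric(0),
                       tau_u = 4, tau_v = 4,
                       population_range = c(500L, 5000L),
                       telehealth_share = 0.3,
                       outcome = c("patients", "visits"),
                       seed = 1L) {
  outcome <- match.arg(outcome)
  if (n_rows < 1 || n_cols < 1) abort("grid dimensions must be >= 1")
  if (!(tau_u > 0) || !(tau_v > 0)) abort("precisions must be > 0")
  if (telehealth_share < 0 || telehealth_share > 1) {
    abort("`telehealth_share` must lie in [0, 1]")
  }
  assert_scalar_number(beta0, "beta0")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 beta0 = beta0, beta = as.numeric(beta),
                 tau_u = tau_u, tau_v = tau_v,
                 population_range = population_range,
                 telehealth_share = telehealth_share,
                 outcome = outcome, seed = as.integer(seed)),
            class = "sim_config")
}

#' Area-year panels
#'
#' The model's data: one row per area with the outcome count `count`
#' (nonnegative integer), the exposure offset `population` (persons), a year
#' label and the covariate columns named in `covariate_names`. Covariates
#' are expected to be standardized (mean 0, SD 1) before fitting.
#'
#' @param df data.frame with columns `area_id`, `year`, `count`,
#'   `population` plus the covariates.
#' @param covariate_names character vector (may be empty) naming covariate
#'   columns of `df`.
#' @return `df` with class `area_year_panel` and a `covariate_names`
#'   attribute.
#' @export
area_year_panel <- function(df, covariate_names = character(0)) {
  need <- c("area_id", "year", "count", "population")
  if (!all(need %in% names(df))) {
    abort("panel requires columns %s", paste(need, collapse = ", "))
  }
  if (!all(covariate_names %in% names(df))) abort("missing covariate columns")
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    abort("counts must be nonnegative integers")
  }
  if (any(df$population < 1)) abort("populations must be >= 1")
  structure(df, class = c("area_year_panel", "data.frame"),
            covariate_names = covariate_names)
}

panel_covariates <- function(panel) {
  nm <- attr(panel, "covariate_names")
  as.matrix(as.data.frame(panel)[, nm, drop = FALSE])
}

#' Simulate an area-year outcome panel
#'
#' Draws the full generative model on a lattice for one study year:
#' covariates are drawn (optionally with pairwise correlation `rho`) and
#' standardized; structured effects u come from the ICAR prior over the
#' queen-contiguity graph, unstructured effects v are iid normal; the linear
#' predictor is eta_i = beta0 + x_i' beta + u_i + v_i and counts are
#' Y_i ~ Poisson(pop_i * exp(eta_i)), i.e. a Poisson log-linear model with
#' log-population offset. The simulation truth (beta0, beta, u, v,
#' precisions) is attached as attribute `truth` for recovery tests.
#' Multi-year studies are produced by repeated calls with year-indexed
#' seeds; each panel carries a single year.
#'
#' @param lattice an [area_lattice].
#' @param config a [sim_config]; `length(config$beta)` must equal
#'   `length(covariate_names)`.
#' @param covariate_names names for the simulated covariate columns.
#' @param year calendar year label.
#' @param rho pairwise correlation between covariates (equicorrelation),
#'   in [0, 1).
#' @param adjacency optional precomputed [adjacency_matrix] (otherwise queen
#'   contiguity is derived from the lattice).
#' @return an [area_year_panel] with attributes `truth` and `outcome_type`.
#' @export
simulate_area_panel <- function(lattice, config, covariate_names,
                                year = 2020L, rho = 0, adjacency = NULL) {
  stopifnot(inherits(lattice, "area_lattice"), inherits(config, "sim_config"))
  p <- length(covariate_names)
  if (p != length(config$beta)) {
    abort("`beta` has length %d but %d covariate name(s) given",
          length(config$beta), p)
  }
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1)")
  n <- n_areas(lattice)
  if (is.null(adjacency)) adjacency <- queen_adjacency(lattice)
  seed <- stage_seed(config$seed, as.integer(year))

  u <- if (is.finite(config$tau_u)) {
    simulate_icar_effects(adjacency, config$tau_u, seed = seed + 1L)$values
  } else rep(0, n)

  sims <- with_seed(seed, {
    X <- if (p > 0) {
      z0 <- stats::rnorm(n)
      Z <- matrix(stats::rnorm(n * p), n, p)
      raw <- sqrt(rho) * z0 + sqrt(1 - rho) * Z
      scale(raw)  # standardize: mean 0, sample SD 1
    } else matrix(numeric(0), n, 0)
    v <- if (is.finite(config$tau_v)) {
      stats::rnorm(n, 0, 1 / sqrt(config$tau_v))
    } else rep(0, n)
    eta <- config$beta0 + as.numeric(X %*% config$beta) + u + v
    y <- stats::rpois(n, lattice$areas$population * exp(eta))
    list(X = X, v = v, eta = eta, y = y)
  })

  df <- data.frame(area_id = lattice$areas$area_id,
                   year = as.integer(year),
                   count = sims$y,
                   population = lattice$areas$population,
                   stringsAsFactors = FALSE)
  if (p > 0) {
    Xdf <- as.data.frame(sims$X)
    names(Xdf) <- covariate_names
    df <- cbind(df, Xdf)
  }
  panel <- area_year_panel(df, covariate_names)
  attr(panel, "truth") <- list(beta0 = config$beta0, beta = config$beta,
                               u = u, v = sims$v, eta = sims$eta,
                               tau_u = config$tau_u, tau_v = config$tau_v)
  attr(panel, "outcome_type") <- config$outcome
  panel
}

#' Simulate claims-style visit records from a panel
#'
#' Expands the panel's telehealth outcomes into visit-level records (patient
#' id, area id, year, modality, diagnosis code) the way a claims extract
#' would carry them, plus the surrounding in-person visit volume implied by
#' `config$telehealth_share`. With `outcome = "patients"` each panel count
#' Y_i becomes Y_i distinct telehealth patients (each with >= 1 telehealth
#' visit); with `"visits"` it becomes Y_i telehealth visits spread over
#' fewer patients. Diagnosis codes are drawn from a year-dependent weight
#' table over `icd_catalog`. A fraction `invalid_fraction` of the records is
#' then corrupted with a missing or out-of-frame area id to exercise
#' downstream cohort filters; with `invalid_fraction = 0` the unique
#' telehealth patient counts per area-year reproduce the panel exactly.
#'
#' Patient ids are deterministic functions of (area, year, index), so
#' deduplication behaviour is reproducible.
#'
#' @param panel an [area_year_panel] (normally from [simulate_area_panel]).
#' @param config the [sim_config] used for the panel.
#' @param icd_catalog non-empty character vector of diagnosis codes.
#' @param invalid_fraction fraction (between 0 and 1) of records to corrupt.
#' @param seed integer seed; defaults to one derived from `config$seed` and
#'   the panel year.
#' @return data.frame of class `visit_record_set` with columns `patient_id`,
#'   `area_id`, `year`, `modality`, `diagnosis_code`.
#' @export
simulate_visit_records <- function(panel, config, icd_catalog,
                                   invalid_fraction = 0, seed = NULL) {
  stopifnot(inherits(panel, "area_year_panel"), inherits(config, "sim_config"))
  if (length(icd_catalog) == 0) abort("`icd_catalog` must be non-empty")
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    abort("`invalid_fraction` must lie in [0, 1]")
  }
  year <- panel$year[1]
  if (is.null(seed)) seed <- stage_seed(config$seed, 7919L + as.integer(year))
  outcome <- attr(panel, "outcome_type") %||% "patients"
  s <- config$telehealth_share
  m <- length(icd_catalog)
  # year-dependent diagnosis mix: rotate a 1/rank weight profile by year
  w <- 1 / (((seq_len(m) + as.integer(year)) %% m) + 1)

  with_seed(seed, {
    pieces <- vector("list", nrow(panel))
    for (i in seq_len(nrow(panel))) {
      y_i <- panel$count[i]
      if (y_i == 0) next
      aid <- panel$area_id[i]
      if (outcome == "patients") {
        n_pat <- y_i
        extra <- stats::rpois(n_pat, 0.5)
        tele_per_pat <- 1L + extra
      } else {
        n_pat <- max(1L, round(y_i / 1.5))
        tele_per_pat <- drop(stats::rmultinom(1, y_i - n_pat, rep(1, n_pat))) + 1L
      }
      pat_ids <- sprintf("P_%s_%d_%05d", aid, year, seq_len(n_pat))
      n_tele <- sum(tele_per_pat)
      n_inp <- stats::rpois(1, n_tele * (1 - s) / max(s, 0.02))
      inp_pat <- if (n_inp > 0) {
        # in-person visits split between telehealth patients and new patients
        from_tele <- stats::runif(n_inp) < 0.5
        ifelse(from_tele,
               pat_ids[sample.int(n_pat, n_inp, replace = TRUE)],
               sprintf("Q_%s_%d_%05d", aid, year,
                       sample.int(max(n_pat, n_inp), n_inp, replace = TRUE)))
      } else character(0)
      pieces[[i]] <- data.frame(
        patient_id = c(rep(pat_ids, times = tele_per_pat), inp_pat),
        area_id = aid,
        year = as.integer(year),
        modality = c(rep("telehealth", n_tele), rep("in_person", n_inp)),
        stringsAsFactors = FALSE
      )
    }
    rec <- do.call(rbind, pieces)
    if (is.null(rec)) {
      rec <- data.frame(patient_id = character(0), area_id = character(0),
                        year = integer(0), modality = character(0),
                        stringsAsFactors = FALSE)
    }
    nrec <- nrow(rec)
    rec$diagnosis_code <- if (nrec > 0) {
      icd_catalog[sample.int(m, nrec, replace = TRUE, prob = w)]
    } else character(0)
    if (invalid_fraction > 0 && nrec > 0) {
      bad <- which(stats::runif(nrec) < invalid_fraction)
      if (length(bad)) {
        half <- seq_along(bad) %% 2L == 0L
        rec$area_id[bad[half]] <- NA_character_
        rec$area_id[bad[!half]] <- "X_OUT_OF_FRAME"
      }
    }
    rownames(rec) <- NULL
    visit_record_set(rec)
  })
}

#' Visit record sets
#'
#' Visit-level records as a claims extract would carry them. Modality must
#' be `telehealth` or `in_person`; `NA` area ids are tolerated (they are what
#' the cohort filters remove).
#'
#' @param df data.frame with columns `patient_id`, `area_id`, `year`,
#'   `modality`, `diagnosis_code`.
#' @return `df` with class `visit_record_set`.
#' @export
visit_record_set <- function(df) {
  need <- c("patient_id", "area_id", "year", "modality", "diagnosis_code")
  if (!all(need %in% names(df))) {
    abort("records require columns %s", paste(need, collapse = ", "))
  }
  ok <- df$modality %in% c("telehealth", "in_person") | is.na(df$modality)
  if (!all(ok)) abort("modality must be 'telehealth' or 'in_person'")
  structure(as.data.frame(df)[, need],
            class = c("visit_record_set", "data.frame"))
}

#' Visit-record and area-table CSV input/output
#'
#' Plain CSV (UTF-8, comma separator, header row) with the documented
#' columns: records as `patient_id, area_id, year, modality, diagnosis_code`;
#' the area table as `area_id, population, rurality`.
#'
#' @param records a [visit_record_set].
#' @param lattice an [area_lattice].
#' @param path file path.
#' @return the path invisibly (writers) or the parsed object (readers).
#' @export
write_visit_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_visit_records
#' @export
read_visit_records <- function(path) {
  df <- utils::read.csv(path, colClasses = c(patient_id = "character",
                                             area_id = "character",
                                             diagnosis_code = "character"),
                        na.strings = "")
  visit_record_set(df)
}

#' @rdname write_visit_records
#' @export
write_area_table <- function(lattice, path) {
  utils::write.csv(lattice$areas, path, row.names = FALSE)
  invisible(path)
}

#' Write simulation truth to JSON
#'
#' Persists a panel's generative parameters (beta0, beta, random effects,
#' precisions) so a downstream recovery analysis can be audited.
#'
#' @param panel an [area_year_panel] carrying a `truth` attribute.
#' @param path file path.
#' @export
write_truth_json <- function(panel, path) {
  truth <- attr(panel, "truth")
  if (is.null(truth)) abort("panel carries no simulation truth")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
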