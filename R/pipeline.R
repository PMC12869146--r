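#' Pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end run:
#' either a `simulation` block (grid size, truth parameters, claims
#' emulation settings) or an `inputs` block (paths to a lattice GeoJSON and
#' a visit-record CSV), the study years, the model/prior/MCMC settings, the
#' exceedance thresholds, an output directory, and one global seed from
#' which every stage seed is derived.
#'
#' @param config a named list, or a path to a YAML or JSON file holding one.
#' @return the validated config (class `pipeline_config`) with defaults
#'   filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML/JSON path")
  has_sim <- !is.null(config$simulation)
  has_inp <- !is.null(config$inputs)
  if (!has_sim && !has_inp) {
    abort("config must contain a `simulation` or an `inputs` block")
  }
  if (is.null(config$years) || !length(config$years)) {
    abort("config must name at least one study year")
  }
  config$years <- sort(as.integer(config$years))
  config$fit_years <- as.integer(config$fit_years %||% max(config$years))
  if (!all(config$fit_years %in% config$years)) {
    abort("`fit_years` must be a subset of `years`")
  }
  if (is.null(config$output_dir)) abort("config must set `output_dir`")
  config$seed <- as.integer(config$seed %||% 1L)
  if (has_sim) {
    s <- config$simulation
    for (f in c("n_rows", "n_cols", "beta0")) {
      if (is.null(s[[f]])) abort("simulation block missing `%s`", f)
    }
    s$covariates <- s[["covariates"]] %||%
      c("population_density", "pct_broadband", "deprivation_index")
    # exact indexing: `$` would partial-match `beta` to `beta0`
    s$beta <- s[["beta"]] %||% rep(0, length(s$covariates))
    if (length(s$beta) != length(s$covariates)) {
      abort("simulation beta/covariates length mismatch")
    }
    s$tau_u <- s$tau_u %||% 4; s$tau_v <- s$tau_v %||% 4
    s$population_range <- s$population_range %||% c(500L, 5000L)
    s$telehealth_share <- s$telehealth_share %||% 0.3
    s$invalid_fraction <- s$invalid_fraction %||% 0.02
    s$icd_catalog <- s$icd_catalog %||%
      c("I10", "E78.5", "E11.9", "F41.9", "J06.9", "M54.5", "K21.9",
        "F32.9", "U07.1", "Z20.828")
    config$simulation <- s
  }
  mc <- config$mcmc %||% list()
  config$mcmc <- list(n_iterations = as.integer(mc$n_iterations %||% 5000L),
                      n_burnin = as.integer(mc$n_burnin %||% 1000L),
                      thin = as.integer(mc$thin %||% 2L))
  pr <- config$priors %||% list()
  config$priors <- bym_priors(beta_prec = pr$beta_prec %||% 1e-4,
                              tau_shape = pr$tau_shape %||% 1,
                              tau_rate = pr$tau_rate %||% 5e-4)
  ex <- config$exceedance %||% list()
  config$exceedance <- list(threshold_fraction = ex$threshold_fraction %||% 0.5,
                            reference = ex$reference %||% "state_mean")
  structure(config, class = c("pipeline_config", "list"))
}

#' Demonstration pipeline configuration
#'
#' A small synthetic study: a 10 x 10 lattice, three standardized
#' covariates with nonzero effects, three study years with the final year
#' fitted, and 5000 MCMC sweeps — sized to run end to end in well under a
#' minute while exercising every stage.
#'
#' @param output_dir directory for artifacts.
#' @param seed global seed.
#' @return a [pipeline_config].
#' @export
demo_pipeline_config <- function(output_dir, seed = 1L) {
  pipeline_config(list(
    simulation = list(n_rows = 10, n_cols = 10, beta0 = log(0.05),
                      covariates = c("population_density", "pct_broadband",
                                     "deprivation_index"),
                      beta = c(0.3, 0.15, -0.2)),
    years = 2019:2021, fit_years = 2021L,
    mcmc = list(n_iterations = 5000L, n_burnin = 1000L, thin = 2L),
    output_dir = output_dir, seed = seed))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> cohort filter -> use rates / shares /
#' trend -> VIF screen -> BYM model comparison -> RR summaries ->
#' exceedance maps, writing every intermediate artifact plus a run manifest
#' (stage seeds, package version, file MD5 hashes). Identical configs and
#' seeds produce identical manifests. Any stage failure aborts with the
#' stage name after writing a partial manifest.
#'
#' @param config a [pipeline_config] (or anything `pipeline_config()`
#'   accepts).
#' @return the manifest, invisibly. Artifacts written per run: the filter
#'   ledger (JSON), use-rate table (CSV), rurality shares (CSV), trend test
#'   (JSON), and per fitted year a VIF report (JSON), RR summary (CSV), DIC
#'   table (JSON) and exceedance GeoJSON.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  seeds <- list()
  stage <- "setup"
  fail <- function(e) {
    manifest <- build_manifest(config, seeds, files, partial = TRUE)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    abort("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  out <- function(name) file.path(config$output_dir, name)
  emit <- function(path) files <<- c(files, path)

  tryCatch({
    ## lattice
    stage <- "lattice"
    if (!is.null(config$simulation)) {
      s <- config$simulation
      seeds$lattice <- stage_seed(config$seed, 1L)
      lattice <- generate_grid_lattice(s$n_rows, s$n_cols,
                                       seed = seeds$lattice,
                                       population_range = s$population_range)
      emit(write_lattice_geojson(lattice, out("lattice.geojson")))
    } else {
      lattice <- read_lattice_geojson(config$inputs$lattice_geojson)
    }
    adjacency <- queen_adjacency(lattice)

    ## records (and, in simulation mode, per-year panels carrying truth)
    stage <- "records"
    panels <- list()
    if (!is.null(config$simulation)) {
      s <- config$simulation
      rec_list <- list()
      for (yr in config$years) {
        seeds[[paste0("panel_", yr)]] <- stage_seed(config$seed, 10L + yr)
        cfg <- sim_config(s$n_rows, s$n_cols, beta0 = s$beta0, beta = s$beta,
                          tau_u = s$tau_u, tau_v = s$tau_v,
                          population_range = s$population_range,
                          telehealth_share = s$telehealth_share,
                          seed = seeds[[paste0("panel_", yr)]])
        panel <- simulate_area_panel(lattice, cfg, s$covariates, year = yr,
                                     adjacency = adjacency)
        panels[[as.character(yr)]] <- panel
        rec_list[[as.character(yr)]] <-
          simulate_visit_records(panel, cfg, s$icd_catalog,
                                 invalid_fraction = s$invalid_fraction)
      }
      records <- visit_record_set(do.call(rbind, rec_list))
      emit(write_visit_records(records, out("visit_records.csv")))
      emit(write_area_table(lattice, out("area_table.csv")))
    } else {
      records <- read_visit_records(config$inputs$records_csv)
    }

    ## cohort filters
    stage <- "cohort_filters"
    filt <- apply_cohort_filters(records, lattice$areas$area_id, config$years)
    emit(write_ledger_json(filt$ledger, out("filter_ledger.json")))

    ## descriptive layer
    stage <- "use_rates"
    rates <- compute_use_rates(filt$records, lattice)
    utils::write.csv(rates, out("use_rates.csv"), row.names = FALSE)
    emit(out("use_rates.csv"))

    stage <- "rurality_shares"
    shares <- rurality_shares(filt$records, lattice)
    utils::write.csv(shares, out("rurality_shares.csv"), row.names = FALSE)
    emit(out("rurality_shares.csv"))

    stage <- "trend_test"
    df <- as.data.frame(filt$records)
    tele_by_year <- vapply(config$years, function(yr) {
      sum(df$year == yr & df$modality == "telehealth")
    }, numeric(1))
    tot_by_year <- vapply(config$years, function(yr) sum(df$year == yr),
                          numeric(1))
    if (length(config$years) >= 3 && all(tot_by_year > 0)) {
      tr <- trend_test(tele_by_year, tot_by_year)
      jsonlite::write_json(list(statistic = tr$statistic,
                                p_value = tr$p_value,
                                direction = tr$direction),
                           out("trend_test.json"), auto_unbox = TRUE,
                           digits = NA)
      emit(out("trend_test.json"))
    }

    ## per-year inference
    for (yr in config$fit_years) {
      ystr <- as.character(yr)
      stage <- paste0("panel_", yr)
      panel <- if (!is.null(config$simulation)) {
        rebuild_panel_from_records(panels[[ystr]], rates, yr)
      } else {
        panel_from_inputs(config, lattice, rates, yr)
      }

      stage <- paste0("vif_screen_", yr)
      covs <- attr(panel, "covariate_names")
      vrep <- if (length(covs) >= 2) {
        vif_screen(panel_covariates(panel), threshold = 5.0)
      } else NULL
      retained <- if (is.null(vrep)) covs else attr(vrep, "retained")
      if (!is.null(vrep)) {
        emit(write_vif_json(vrep, out(sprintf("vif_report_%d.json", yr))))
      }

      stage <- paste0("fit_", yr)
      seeds[[paste0("fit_", yr)]] <- stage_seed(config$seed, 100L + yr)
      mcmc <- mcmc_config(n_iterations = config$mcmc$n_iterations,
                          n_burnin = config$mcmc$n_burnin,
                          thin = config$mcmc$thin,
                          seed = seeds[[paste0("fit_", yr)]])
      primary <- retained[1]
      specs <- list(
        model_spec(primary, include_structured = FALSE, name = "crude"),
        model_spec(primary, name = "crude_spatial"),
        model_spec(retained, name = "fully_adjusted"))
      dic_tab <- compare_models(panel, adjacency, config$priors, mcmc, specs)
      jsonlite::write_json(as.data.frame(dic_tab),
                           out(sprintf("dic_table_%d.json", yr)),
                           auto_unbox = TRUE, digits = NA)
      emit(out(sprintf("dic_table_%d.json", yr)))

      fit <- attr(dic_tab, "fits")[[match("fully_adjusted", dic_tab$model)]]
      stage <- paste0("rr_summary_", yr)
      rr <- summarize_rr(fit)
      utils::write.csv(rr, out(sprintf("rr_summary_%d.csv", yr)),
                       row.names = FALSE)
      emit(out(sprintf("rr_summary_%d.csv", yr)))

      stage <- paste0("exceedance_", yr)
      thr <- config$exceedance$threshold_fraction
      if (is.list(thr) || length(thr) > 1) thr <- thr[[ystr]] %||% 0.5
      exc <- exceedance_probabilities(fit, panel, threshold_fraction = thr,
                                      reference = config$exceedance$reference)
      emit(write_exceedance_geojson(exc, lattice,
                                    out(sprintf("exceedance_%d.geojson", yr))))
    }

    stage <- "manifest"
    manifest <- build_manifest(config, seeds, files, partial = FALSE)
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
  }, error = fail)
}

# counts from the filtered records replace the simulated counts, so the
# fitted panel reflects what survived the cohort filters
rebuild_panel_from_records <- function(sim_panel, rates, yr) {
  r <- rates[rates$year == yr, ]
  cnt <- r$unique_telehealth_patients[match(sim_panel$area_id, r$area_id)]
  cnt[is.na(cnt)] <- 0L
  out <- sim_panel
  out$count <- cnt
  out
}

panel_from_inputs <- function(config, lattice, rates, yr) {
  tab <- utils::read.csv(config$inputs$area_table_csv,
                         colClasses = c(area_id = "character"))
  covs <- setdiff(names(tab), c("area_id", "population", "rurality"))
  r <- rates[rates$year == yr, ]
  cnt <- r$unique_telehealth_patients[match(lattice$areas$area_id, r$area_id)]
  cnt[is.na(cnt)] <- 0L
  df <- data.frame(area_id = lattice$areas$area_id, year = yr, count = cnt,
                   population = lattice$areas$population,
                   stringsAsFactors = FALSE)
  Z <- standardize_covariates(tab[match(df$area_id, tab$area_id), covs,
                                  drop = FALSE])
  area_year_panel(cbind(df, as.data.frame(Z)), covs)
}

build_manifest <- function(config, seeds, files, partial) {
  files <- unique(files)
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
  names(hashes) <- basename(files)
  list(package = "telespat",
       version = as.character(utils::packageVersion("telespat")),
       global_seed = config$seed,
       stage_seeds = seeds,
       partial = partial,
       artifacts = hashes)
}
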