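#' Apply cohort filters to visit records
#'
#' Reproduces the claims-cohort cleaning sequence: records with missing
#' fields are dropped first, then records outside the study years, then
#' records whose area id is not in the valid set (non-resident or invalid
#' areas). Every stage is logged in a filter ledger so the attrition can be
#' reported as a selection flow diagram.
#'
#' @param records a [visit_record_set].
#' @param valid_area_ids non-empty character vector of admissible area ids.
#' @param study_years integer vector of admissible years.
#' @return list with `records` (the surviving [visit_record_set]) and
#'   `ledger` (data.frame of class `filter_ledger` with columns `stage`,
#'   `records_in`, `records_dropped`, `records_out`; stages compose, so
#'   `records_in - records_dropped == records_out` at every row).
#' @export
apply_cohort_filters <- function(records, valid_area_ids, study_years) {
  stopifnot(inherits(records, "visit_record_set"))
  if (length(valid_area_ids) == 0) abort("`valid_area_ids` must be non-empty")
  if (length(study_years) == 0) abort("`study_years` must be non-empty")
  df <- as.data.frame(records)

  stages <- list(
    missing_fields = function(d) {
      stats::complete.cases(d[, c("patient_id", "area_id", "year", "modality",
                                  "diagnosis_code")]) &
        d$patient_id != "" & d$area_id != ""
    },
    year_range = function(d) d$year %in% study_years,
    area_validity = function(d) d$area_id %in% valid_area_ids
  )

  rows <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    n_in <- nrow(df)
    keep <- stages[[k]](df)
    df <- df[keep, , drop = FALSE]
    rows[[k]] <- data.frame(stage = names(stages)[k],
                            records_in = n_in,
                            records_dropped = n_in - nrow(df),
                            records_out = nrow(df),
                            stringsAsFactors = FALSE)
  }
  ledger <- do.call(rbind, rows)
  class(ledger) <- c("filter_ledger", "data.frame")
  rownames(df) <- NULL
  list(records = visit_record_set(df), ledger = ledger)
}

#' Write a filter ledger as JSON
#' @param ledger a `filter_ledger`.
#' @param path file path.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(as.data.frame(ledger), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Telehealth use rates per area-year
#'
#' The study's outcome: the proportion of unique patients per area who used
#' telehealth in a given year. The numerator counts each patient at most
#' once per area-year (however many telehealth visits they made); the
#' denominator is the area's resident population. A patient appearing in two
#' areas in one year counts in each area's numerator — the estimand is the
#' area-level rate, and the records are the evidence each area has.
#'
#' @param records a [visit_record_set]; all area ids must exist in the
#'   lattice (run [apply_cohort_filters] first).
#' @param lattice an [area_lattice] supplying populations.
#' @return data.frame of class `use_rate_table` with one row per area-year
#'   present in the records (plus zero rows for area-years with only
#'   in-person records): `area_id`, `year`, `unique_telehealth_patients`,
#'   `population`, `rate`.
#' @export
compute_use_rates <- function(records, lattice) {
  stopifnot(inherits(records, "visit_record_set"),
            inherits(lattice, "area_lattice"))
  df <- as.data.frame(records)
  unknown <- setdiff(unique(df$area_id), lattice$areas$area_id)
  unknown <- unknown[!is.na(unknown)]
  if (length(unknown)) {
    abort("area id(s) not in lattice: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (anyNA(df$area_id)) abort("records contain missing area ids; filter first")
  tele <- df[df$modality == "telehealth", , drop = FALSE]
  counts <- if (nrow(tele)) {
    tt <- unique(tele[, c("patient_id", "area_id", "year")])
    stats::aggregate(cbind(unique_telehealth_patients = rep(1L, nrow(tt))),
                     by = list(area_id = tt$area_id, year = tt$year), FUN = sum)
  } else {
    data.frame(area_id = character(0), year = integer(0),
               unique_telehealth_patients = integer(0))
  }
  frame <- unique(df[, c("area_id", "year")])
  out <- merge(frame, counts, by = c("area_id", "year"), all.x = TRUE)
  out$unique_telehealth_patients[is.na(out$unique_telehealth_patients)] <- 0L
  pop <- lattice$areas$population[match(out$area_id, lattice$areas$area_id)]
  if (any(pop < 1)) abort("zero population area in lattice")
  out$population <- pop
  out$rate <- out$unique_telehealth_patients / out$population
  out <- out[order(out$year, out$area_id), ]
  rownames(out) <- NULL
  class(out) <- c("use_rate_table", "data.frame")
  out
}

#' Annual telehealth-visit shares by rurality class
#'
#' For each year, the percentage of that year's telehealth visits falling in
#' each rurality class: share(class, year) = 100 * telehealth visits in
#' class / total telehealth visits that year. The denominator is all
#' telehealth visits of the year, including visits in areas with an unknown
#' rurality class (such visits appear in no class's numerator, so printed
#' shares can sum to slightly under 100). Shares are rounded half-up to one
#' decimal. Years with zero telehealth visits are flagged in the
#' `empty_years` attribute rather than emitted as zeros.
#'
#' @param records a [visit_record_set].
#' @param lattice an [area_lattice] supplying rurality classes.
#' @return data.frame with columns `year`, `rurality`, `visits`, `share`;
#'   attribute `empty_years` lists years with no telehealth visits.
#' @export
rurality_shares <- function(records, lattice) {
  stopifnot(inherits(records, "visit_record_set"),
            inherits(lattice, "area_lattice"))
  df <- as.data.frame(records)
  tele <- df[df$modality == "telehealth" & !is.na(df$area_id), , drop = FALSE]
  years <- sort(unique(df$year))
  empty <- setdiff(years, unique(tele$year))
  if (nrow(tele) == 0) {
    out <- data.frame(year = integer(0), rurality = character(0),
                      visits = integer(0), share = numeric(0))
    attr(out, "empty_years") <- empty
    return(out)
  }
  rur <- lattice$areas$rurality[match(tele$area_id, lattice$areas$area_id)]
  totals <- table(tele$year)
  keep <- !is.na(rur)
  cls <- stats::aggregate(cbind(visits = rep(1L, sum(keep))),
                          by = list(year = tele$year[keep],
                                    rurality = rur[keep]),
                          FUN = sum)
  out <- rurality_shares_from_counts(
    cls, year_totals = stats::setNames(as.numeric(totals), names(totals)))
  attr(out, "empty_years") <- empty
  out
}

#' Shares from pre-aggregated visit counts
#'
#' The arithmetic core of [rurality_shares], exposed for working directly
#' with aggregated tables (e.g. counts as printed in a report):
#' share = 100 * visits / year total, rounded half-up to one decimal. By
#' default the denominator is the sum of the supplied counts within each
#' year; `year_totals` overrides it, which matters when the published total
#' includes visits outside the tabulated classes.
#'
#' @param counts data.frame with columns `year`, `rurality`, `visits`.
#' @param year_totals optional named numeric vector (names = years) of
#'   denominator totals.
#' @return data.frame with columns `year`, `rurality`, `visits`, `share`.
#' @export
#' @examples
#' rurality_shares_from_counts(
#'   data.frame(year = 2016, rurality = c("suburban_town", "city", "rural"),
#'              visits = c(2318, 558, 478)),
#'   year_totals = c("2016" = 3359))
rurality_shares_from_counts <- function(counts, year_totals = NULL) {
  need <- c("year", "rurality", "visits")
  if (!all(need %in% names(counts))) {
    abort("`counts` requires columns %s", paste(need, collapse = ", "))
  }
  cls <- as.data.frame(counts)[, need]
  tot_in_year <- tapply(cls$visits, cls$year, sum)
  denom <- if (is.null(year_totals)) {
    as.numeric(tot_in_year[as.character(cls$year)])
  } else {
    as.numeric(year_totals[as.character(cls$year)])
  }
  if (anyNA(denom) || any(denom <= 0)) abort("invalid year totals")
  cls$share <- round_half_up(100 * cls$visits / denom, 1)
  cls <- cls[order(cls$year, match(cls$rurality, rurality_classes())), ]
  rownames(cls) <- NULL
  cls
}

#' Cochran-Armitage trend test on annual proportions
#'
#' Tests for a monotone trend in a proportion across ordered years using the
#' Cochran-Armitage score test (via [stats::prop.trend.test]) with equally
#' spaced year scores; the p-value is the usual two-sided chi-squared
#' p-value, and the reported statistic is the signed square root (positive
#' for an increasing trend). For tiny counts, where the chi-squared
#' approximation is doubtful, `method = "permutation"` computes the p-value
#' by permuting individual outcomes across years.
#'
#' @param successes_by_year,totals_by_year equal-length integer vectors
#'   (length >= 3) of successes and totals per year, in year order;
#'   `successes <= totals`, all totals positive.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_permutations number of permutations when
#'   `method = "permutation"`.
#' @return list of class `trend_test_result`: `statistic` (signed z),
#'   `p_value`, `direction` (`increasing`, `decreasing`, or `flat`).
#' @export
trend_test <- function(successes_by_year, totals_by_year,
                       method = c("asymptotic", "permutation"),
                       n_permutations = 10000L) {
  method <- match.arg(method)
  s <- as.numeric(successes_by_year); t <- as.numeric(totals_by_year)
  if (length(s) != length(t) || length(s) < 3) {
    abort("need equal-length vectors of at least 3 years")
  }
  if (any(t <= 0)) abort("all totals must be positive")
  if (any(s < 0) || any(s > t)) abort("successes must lie in [0, total]")
  scores <- seq_along(s)
  # signed trend: weighted covariance between year score and proportion
  sbar <- sum(t * scores) / sum(t)
  slope_num <- sum(s * (scores - sbar))
  direction <- if (slope_num > 0) "increasing"
               else if (slope_num < 0) "decreasing" else "flat"
  ca_stat <- function(s) sum(s * (scores - sbar))  # permutation-invariant core
  if (method == "asymptotic") {
    pt <- suppressWarnings(stats::prop.trend.test(s, t, score = scores))
    z <- sign(slope_num) * sqrt(unname(pt$statistic))
    p <- unname(pt$p.value)
  } else {
    # permute individual 0/1 outcomes across year slots
    outcomes <- rep(rep(c(1L, 0L), length(s)), times = rbind(s, t - s))
    obs <- abs(ca_stat(s))
    yrs <- rep(scores, times = t)
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- outcomes[sample.int(length(outcomes))]
      sp <- vapply(scores, function(k) sum(perm[yrs == k]), numeric(1))
      if (abs(ca_stat(sp)) >= obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_permutations)
    z <- sign(slope_num) * sqrt(max(0, suppressWarnings(
      unname(stats::prop.trend.test(s, t, score = scores)$statistic))))
  }
  structure(list(statistic = z, p_value = p, direction = direction),
            class = "trend_test_result")
}

#' @export
print.trend_test_result <- function(x, ...) {
  cat(sprintf("Trend test: z = %.3f, p = %.3g (%s)\n",
              x$statistic, x$p_value, x$direction))
  invisible(x)
}

#' Rank the most frequent telehealth diagnoses per year
#'
#' Counts telehealth visits by diagnosis code within each year and returns
#' the top `k` codes per year (fewer if fewer codes occur), ranked by
#' descending count with lexicographic tie-break on the code. This is the
#' long-format table behind a diagnoses-by-year heat map.
#'
#' @param records a [visit_record_set].
#' @param k positive integer, codes to keep per year.
#' @return data.frame with columns `year`, `diagnosis_code`, `count`,
#'   `rank`.
#' @export
rank_top_diagnoses <- function(records, k) {
  stopifnot(inherits(records, "visit_record_set"))
  if (!is.numeric(k) || k < 1) abort("`k` must be a positive integer")
  df <- as.data.frame(records)
  tele <- df[df$modality == "telehealth" & !is.na(df$diagnosis_code), ,
             drop = FALSE]
  if (nrow(tele) == 0) {
    return(data.frame(year = integer(0), diagnosis_code = character(0),
                      count = integer(0), rank = integer(0)))
  }
  agg <- stats::aggregate(cbind(count = rep(1L, nrow(tele))),
                          by = list(year = tele$year,
                                    diagnosis_code = tele$diagnosis_code),
                          FUN = sum)
  out <- do.call(rbind, lapply(split(agg, agg$year), function(d) {
    d <- d[order(-d$count, d$diagnosis_code), , drop = FALSE]
    d <- utils::head(d, k)
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  out[, c("year", "diagnosis_code", "count", "rank")]
}
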