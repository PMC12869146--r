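test_that("cohort filters drop the right records and attribute them to stages", {
  rec <- make_records(
    patient = sprintf("P%02d", 1:10),
    area = c(rep("A1", 5), rep("A2", 2), "BAD", "BAD2", NA),
    year = c(rep(2020L, 8), 2010L, 2020L),
    modality = rep(c("telehealth", "in_person"), 5))
  res <- apply_cohort_filters(rec, valid_area_ids = c("A1", "A2"),
                              study_years = 2016:2021)
  led <- res$ledger
  expect_equal(led$stage, c("missing_fields", "year_range", "area_validity"))
  expect_equal(led$records_dropped, c(1L, 1L, 1L))   # NA, 2010, BAD* in order
  expect_equal(nrow(res$records), 7L)
  # the out-of-range year on a BAD area is charged to the year stage first
  expect_true(all(res$records$area_id %in% c("A1", "A2")))

  all_ok <- apply_cohort_filters(
    make_records(sprintf("P%d", 1:10), "A1", 2020L, "telehealth"),
    valid_area_ids = "A1", study_years = 2020)
  expect_equal(all_ok$ledger$records_dropped, c(0L, 0L, 0L))

  expect_error(apply_cohort_filters(rec, character(0), 2020), "non-empty")
})

test_that("ledger conservation holds on random record sets", {
  lat <- generate_grid_lattice(3, 3, seed = 4)
  for (k in 1:10) {
    cfg <- sim_config(3, 3, beta0 = log(0.05), seed = 60 + k)
    panel <- simulate_area_panel(lat, cfg, character(0))
    rec <- simulate_visit_records(panel, cfg, c("I10", "E78.5"),
                                  invalid_fraction = stats::runif(1, 0, 0.4))
    res <- apply_cohort_filters(rec, lat$areas$area_id, 2016:2021)
    led <- res$ledger
    expect_equal(led$records_in - led$records_dropped, led$records_out)
    expect_equal(led$records_out[-nrow(led)], led$records_in[-1])
    expect_equal(led$records_out[nrow(led)], nrow(res$records))
  }
})

test_that("filter drop rate tracks the injected corruption rate", {
  lat <- grid_lattice_with(3, 3, population = rep(3000, 9))
  cfg <- sim_config(3, 3, beta0 = log(0.1), seed = 77)
  panel <- simulate_area_panel(lat, cfg, character(0))
  rec <- simulate_visit_records(panel, cfg, "I10", invalid_fraction = 0.2)
  n <- nrow(rec)
  expect_gt(n, 5000)
  res <- apply_cohort_filters(rec, lat$areas$area_id, 2016:2021)
  dropped <- sum(res$ledger$records_dropped)
  expect_lt(abs(dropped - 0.2 * n), 4 * sqrt(n * 0.2 * 0.8))
})

test_that("use rates deduplicate patients and zero out telehealth-free areas", {
  lat <- grid_lattice_with(1, 2, population = c(100, 100))
  ids <- lat$areas$area_id
  rec <- make_records(
    patient = c(rep("P1", 5), sprintf("P%d", 2:11), "P99"),
    area = c(rep(ids[1], 5), rep(ids[1], 10), ids[2]),
    year = 2020L,
    modality = c(rep("telehealth", 15), "in_person"))
  rates <- compute_use_rates(rec, lat)
  r1 <- rates[rates$area_id == ids[1], ]
  expect_equal(r1$unique_telehealth_patients, 11L)  # P1 counted once
  expect_equal(r1$rate, 0.11)
  r2 <- rates[rates$area_id == ids[2], ]
  expect_equal(r2$rate, 0)

  # duplicating any telehealth record leaves the numerator unchanged
  dup <- visit_record_set(rbind(as.data.frame(rec), as.data.frame(rec)[1, ]))
  expect_equal(compute_use_rates(dup, lat)$rate, rates$rate)

  bad <- make_records("P1", "NOWHERE", 2020L, "telehealth")
  expect_error(compute_use_rates(bad, lat), "NOWHERE")
})

test_that("rurality shares reproduce printed-table arithmetic", {
  # three classified areas plus one unclassified area whose visits only
  # enter the denominator (totals in published tables can exceed the sum
  # over classified areas)
  lat <- grid_lattice_with(2, 2, population = rep(10000, 4),
                           rurality = c("suburban_town", "city", "rural", NA))
  ids <- lat$areas$area_id
  mk_year <- function(counts, year) {
    n <- sum(counts)
    make_records(patient = sprintf("P_%d_%d", year, seq_len(n)),
                 area = rep(ids, counts), year = year,
                 modality = "telehealth")
  }
  rec <- mk_year(c(2318L, 558L, 478L, 5L), 2016L)
  sh <- rurality_shares(rec, lat)
  get <- function(year, cls) sh$share[sh$year == year & sh$rurality == cls]
  expect_equal(get(2016, "suburban_town"), 69.0)
  expect_equal(get(2016, "city"), 16.6)
  expect_equal(get(2016, "rural"), 14.2)

  # the counts-level path handles pandemic-scale totals directly
  big <- rurality_shares_from_counts(
    data.frame(year = c(2020, 2021, 2021, 2021),
               rurality = c("rural", "suburban_town", "rural", "city"),
               visits = c(644404, 421564, 368343, 180754)),
    year_totals = c("2020" = 1564817, "2021" = 978207))
  getb <- function(year, cls) big$share[big$year == year & big$rurality == cls]
  expect_equal(getb(2020, "rural"), 41.2)
  expect_equal(getb(2021, "suburban_town"), 43.1)
  expect_equal(getb(2021, "rural"), 37.7)
  expect_equal(getb(2021, "city"), 18.5)

  # shares sum to ~100 when the denominator is the within-class sum
  all_cls <- rurality_shares_from_counts(
    data.frame(year = 2020, rurality = rurality_classes(),
               visits = c(533124, 387289, 644404)))
  expect_equal(sum(all_cls$share), 100, tolerance = 0.1)
})

test_that("degenerate share layouts behave as documented", {
  lat <- grid_lattice_with(1, 2, rurality = c("city", "rural"))
  ids <- lat$areas$area_id
  one_class <- make_records(sprintf("P%d", 1:10), ids[1], 2020L, "telehealth")
  sh <- rurality_shares(one_class, lat)
  expect_equal(sh$share[sh$rurality == "city"], 100.0)
  expect_false("rural" %in% sh$rurality)
  # a year with no telehealth visits is flagged, not reported as zero
  none <- make_records("P1", ids[1], 2019L, "in_person")
  both <- visit_record_set(rbind(as.data.frame(one_class),
                                 as.data.frame(none)))
  sh2 <- rurality_shares(both, lat)
  expect_equal(attr(sh2, "empty_years"), 2019L)
  expect_false(2019L %in% sh2$year)
})

test_that("trend test flags monotone trends and respects symmetry", {
  flat <- trend_test(rep(50, 5), rep(100, 5))
  expect_equal(flat$statistic, 0, tolerance = 1e-10)
  expect_equal(flat$p_value, 1, tolerance = 1e-10)
  expect_equal(flat$direction, "flat")

  up <- trend_test(c(1000, 1750, 2500, 3250, 4000), rep(10000, 5))
  expect_lt(up$p_value, 0.001)
  expect_equal(up$direction, "increasing")

  down <- trend_test(rev(c(1000, 1750, 2500, 3250, 4000)), rep(10000, 5))
  expect_equal(down$direction, "decreasing")
  expect_equal(down$p_value, up$p_value)
  expect_equal(down$statistic, -up$statistic)

  expect_error(trend_test(c(1, 2), c(10, 10)), "3 years")
  expect_error(trend_test(c(1, 2, 3), c(10, 0, 10)), "positive")
  expect_error(trend_test(c(11, 2, 3), c(10, 10, 10)), "successes")
})

test_that("asymptotic trend p-value matches a permutation oracle", {
  # counts large enough for the chi-squared approximation to be accurate,
  # small enough for the permutation null to be cheap
  s <- c(30, 40, 52); t <- c(200, 200, 200)
  asym <- trend_test(s, t)
  set.seed(402)
  perm <- trend_test(s, t, method = "permutation", n_permutations = 20000)
  expect_lt(abs(asym$p_value - perm$p_value), 0.01)
  expect_equal(perm$direction, "increasing")
})

test_that("diagnosis ranking orders by count with lexicographic ties", {
  rec <- make_records(
    patient = sprintf("P%d", 1:13),
    area = "A1", year = 2020L,
    modality = c(rep("telehealth", 12), "in_person"),
    code = c(rep("I10", 5), rep("E78.5", 3), "Z99", rep("A01", 2),
             rep("B01", 1), "ZZZ"))
  top <- rank_top_diagnoses(rec, k = 3)
  expect_equal(top$diagnosis_code, c("I10", "E78.5", "A01"))
  expect_equal(top$rank, 1:3)
  expect_equal(top$count, c(5L, 3L, 2L))

  tie <- make_records(sprintf("P%d", 1:8), "A1", 2020L, "telehealth",
                      code = c(rep("B99", 4), rep("A10", 4)))
  expect_equal(rank_top_diagnoses(tie, 2)$diagnosis_code, c("A10", "B99"))

  # k beyond the catalogue returns everything without padding
  expect_equal(nrow(rank_top_diagnoses(tie, 10)), 2L)
})
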