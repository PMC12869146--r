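test_that("panel counts have the closed-form Poisson mean when effects vanish", {
  # beta = 0, u = v = 0, rate 0.1, population 1000 -> E[Y] = 100
  lat <- grid_lattice_with(2, 2, population = rep(1000, 4))
  adj <- queen_adjacency(lat)
  draws <- unlist(lapply(1:1250, function(k) {
    cfg <- sim_config(2, 2, beta0 = log(0.1), tau_u = Inf, tau_v = Inf,
                      seed = k)
    simulate_area_panel(lat, cfg, character(0), adjacency = adj)$count
  }))
  expect_equal(length(draws), 5000L)
  expect_equal(mean(draws), 100, tolerance = 0.01)
  expect_true(all(draws >= 0 & draws == round(draws)))
})

test_that("counts are equidispersed in the no-random-effect limit", {
  lat <- grid_lattice_with(2, 2, population = rep(2000, 4))
  adj <- queen_adjacency(lat)
  draws <- unlist(lapply(1:500, function(k) {
    cfg <- sim_config(2, 2, beta0 = log(0.05), tau_u = Inf, tau_v = Inf,
                      seed = 5000 + k)
    simulate_area_panel(lat, cfg, character(0), adjacency = adj)$count
  }))
  expect_equal(stats::var(draws) / mean(draws), 1, tolerance = 0.15)
})

test_that("panel simulation is an exact round trip under the same seed", {
  lat <- generate_grid_lattice(4, 4, seed = 3)
  adj <- queen_adjacency(lat)
  cfg <- sim_config(4, 4, beta0 = log(0.05), beta = c(0.3, -0.2), seed = 17)
  a <- simulate_area_panel(lat, cfg, c("d", "p"), adjacency = adj)
  b <- simulate_area_panel(lat, cfg, c("d", "p"), adjacency = adj)
  expect_identical(a$count, b$count)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
})

test_that("panel rejects mismatched coefficient/covariate dimensions", {
  lat <- generate_grid_lattice(2, 2, seed = 1)
  cfg <- sim_config(2, 2, beta0 = 0, beta = c(0.1, 0.2), seed = 1)
  expect_error(simulate_area_panel(lat, cfg, "only_one"), "covariate")
})

test_that("visit records aggregate back to the panel when nothing is corrupted", {
  lat <- generate_grid_lattice(3, 3, seed = 9)
  adj <- queen_adjacency(lat)
  cfg <- sim_config(3, 3, beta0 = log(0.03), seed = 23)
  panel <- simulate_area_panel(lat, cfg, character(0), adjacency = adj)
  rec <- simulate_visit_records(panel, cfg, c("I10", "E11.9", "F41.9"),
                                invalid_fraction = 0)
  tele <- as.data.frame(rec)
  tele <- tele[tele$modality == "telehealth", ]
  got <- tapply(tele$patient_id, tele$area_id, function(p) length(unique(p)))
  for (i in seq_len(nrow(panel))) {
    cnt <- got[panel$area_id[i]]
    cnt <- if (is.na(cnt)) 0L else as.integer(cnt)
    expect_equal(cnt, panel$count[i], info = panel$area_id[i])
  }
})

test_that("corruption injects close to the requested fraction of bad ids", {
  lat <- grid_lattice_with(3, 3, population = rep(4000, 9))
  adj <- queen_adjacency(lat)
  cfg <- sim_config(3, 3, beta0 = log(0.08), seed = 31)
  panel <- simulate_area_panel(lat, cfg, character(0), adjacency = adj)
  rec <- simulate_visit_records(panel, cfg, "I10", invalid_fraction = 0.1)
  n <- nrow(rec)
  bad <- sum(is.na(rec$area_id) | !(rec$area_id %in% lat$areas$area_id))
  expect_gt(n, 5000)
  # binomial MC band: ~4 SDs around 0.1 n
  expect_lt(abs(bad - 0.1 * n), 4 * sqrt(n * 0.1 * 0.9))
})

test_that("a multi-visit patient still counts once in the unique numerator", {
  rec <- make_records(patient = rep("P1", 5), area = "A1", year = 2020,
                      modality = "telehealth")
  lat <- grid_lattice_with(1, 1, population = 100)
  lat$areas$area_id <- "A1"; names(lat$polygons) <- "A1"
  rates <- compute_use_rates(rec, lat)
  expect_equal(rates$unique_telehealth_patients, 1L)
  expect_equal(rates$rate, 0.01)
})

test_that("record CSV round trip preserves content and NA area ids", {
  lat <- generate_grid_lattice(2, 2, seed = 2)
  cfg <- sim_config(2, 2, beta0 = log(0.05), seed = 4)
  panel <- simulate_area_panel(lat, cfg, character(0))
  rec <- simulate_visit_records(panel, cfg, c("I10", "E78.5"),
                                invalid_fraction = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_visit_records(rec, path)
  back <- read_visit_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})
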