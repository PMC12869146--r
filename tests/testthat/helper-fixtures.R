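# Shared builders for small fixtures, generated in code at test time.

# a tiny panel with explicit counts/populations and no covariates
toy_panel <- function(counts, populations, year = 2020L) {
  area_year_panel(data.frame(
    area_id = sprintf("T%02d", seq_along(counts)),
    year = year, count = counts, population = populations,
    stringsAsFactors = FALSE))
}

path_adjacency <- function(n) {
  pairs <- if (n >= 2) cbind(seq_len(n - 1), 2:n) else NULL
  adjacency_matrix(n, pairs, area_ids = sprintf("T%02d", seq_len(n)))
}

# hand-built records: one row per visit
make_records <- function(patient, area, year, modality, code = "I10") {
  visit_record_set(data.frame(patient_id = patient, area_id = area,
                              year = year, modality = modality,
                              diagnosis_code = code,
                              stringsAsFactors = FALSE))
}

# a lattice with explicitly chosen populations / rurality over a grid
grid_lattice_with <- function(n_rows, n_cols, population = NULL,
                              rurality = NULL, seed = 1) {
  lat <- generate_grid_lattice(n_rows, n_cols, seed = seed)
  if (!is.null(population)) lat$areas$population <- population
  if (!is.null(rurality)) lat$areas$rurality <- rurality
  lat
}
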