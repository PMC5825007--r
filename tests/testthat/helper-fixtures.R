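# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# small world: 24x24 cells, 12 species, fitted model + ranges + planning grid
tiny_study <- function() {
  if (is.null(.fixtures$tiny)) {
    env <- make_landscape(24, 24, seed = 101)
    species_set <- simulate_species(env, n_species = 12, seed = 102)
    pa_mask <- make_existing_pas(env, target_fraction = 0.057, seed = 103)
    occ <- suppressWarnings(sample_occurrences(species_set, env, seed = 104))
    ssm <- build_site_species_matrix(occ, env)
    fit <- fit_mars_multiresponse(ssm)
    rmaps <- build_range_maps(fit, ssm, env)
    agg <- aggregate_to_planning_units(rmaps$ranges, env, pu_side_cells = 4)
    .fixtures$tiny <- list(env = env, species_set = species_set,
                           pa_mask = pa_mask, occ = occ, ssm = ssm,
                           fit = fit, ranges = rmaps$ranges,
                           range_summary = rmaps$summary,
                           planning_grid = agg$planning_grid,
                           amounts = agg$amounts)
  }
  .fixtures$tiny
}

# bare planning grid without going through a landscape
make_test_grid <- function(n_pu_rows, n_pu_cols, side_km = 2, status = 0L) {
  grid <- tidyr::expand_grid(pu_row = seq_len(n_pu_rows),
                             pu_col = seq_len(n_pu_cols))
  grid <- dplyr::mutate(grid,
                        pu_id = (.data$pu_row - 1L) * n_pu_cols + .data$pu_col,
                        area_km2 = side_km^2, cost = side_km^2,
                        status = as.integer(status))
  grid <- grid[, c("pu_id", "pu_row", "pu_col", "area_km2", "cost", "status")]
  attr(grid, "n_pu_rows") <- n_pu_rows
  attr(grid, "n_pu_cols") <- n_pu_cols
  attr(grid, "pu_side_cells") <- 1L
  attr(grid, "side_km") <- side_km
  attr(grid, "cell_area") <- side_km^2
  class(grid) <- c("planning_grid", class(grid))
  grid
}

# random small reserve-selection instance for oracle comparisons
random_problem <- function(seed, n_pu_rows = 3, n_pu_cols = 4, n_species = 4,
                           blm = 0, spf_range = c(5, 30), lock_in = 0L,
                           lock_out = 0L) {
  set.seed(seed)
  grid <- make_test_grid(n_pu_rows, n_pu_cols)
  n_pu <- nrow(grid)
  if (lock_in > 0) grid$status[sample.int(n_pu, lock_in)] <- 2L
  if (lock_out > 0) grid$status[sample(which(grid$status == 0L), lock_out)] <- 3L
  ids <- sprintf("sp%02d", seq_len(n_species))
  amounts <- purrr::map_dfr(ids, function(sp) {
    pus <- sort(sample(grid$pu_id, sample(2:max(3, n_pu %/% 2), 1)))
    tibble::tibble(species_id = sp, pu = pus,
                   amount = round(runif(length(pus), 0.5, 4), 3))
  })
  targets <- tibble::tibble(species_id = ids,
                            prop = runif(n_species, 0.2, 0.7),
                            spf = runif(n_species, spf_range[1], spf_range[2]))
  conservation_problem(grid, amounts, targets, blm = blm)
}

# brute-force AUC by explicit pair counting
auc_pairs <- function(pres, abs) {
  conc <- 0
  for (p in pres) for (a in abs) {
    conc <- conc + (p > a) + 0.5 * (p == a)
  }
  conc / (length(pres) * length(abs))
}
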