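#' Published study geometry for the South Korean assessment
#'
#' The printed inputs of the national plant-biodiversity assessment this
#' package generalises: mainland extent, existing protected-area (PA)
#' extent, survey size, and scenario extents. `korea_study_arithmetic()`
#' recomputes the derived quantities (percentages, extent targets, modelling
#' group sizes) from these inputs at run time.
#'
#' @return `korea_study_constants()`: a named list of printed inputs.
#'   `korea_study_arithmetic()`: a tibble `(quantity, value)` of derived
#'   values.
#' @export
korea_study_constants <- function() {
  list(
    mainland_km2 = 95219,
    existing_pa_km2 = 5463.20,
    double_pa_km2 = 10926.08,
    common_plus_existing_km2 = 6192.47,
    n_records = 150959,
    n_species_modelled = 2297,
    n_species_absent = 1833,
    aichi_fraction = 0.17,
    n_model_groups = 15
  )
}

#' @rdname korea_study_constants
#' @export
korea_study_arithmetic <- function() {
  k <- korea_study_constants()
  sizes <- vapply(
    partition_species_groups(sprintf("s%04d", seq_len(k$n_species_modelled)),
                             n_groups = k$n_model_groups, seed = 1),
    length, 0L)
  tibble::tibble(
    quantity = c("existing_pa_pct", "double_pa_extent_km2", "double_pa_pct",
                 "aichi_extent_km2", "common_selection_pct",
                 "mean_records_per_species", "survey_coverage_pct",
                 "model_group_size_min", "model_group_size_max"),
    value = c(
      100 * k$existing_pa_km2 / k$mainland_km2,
      2 * k$existing_pa_km2,
      100 * k$double_pa_km2 / k$mainland_km2,
      k$aichi_fraction * k$mainland_km2,
      100 * k$common_plus_existing_km2 / k$mainland_km2,
      k$n_records / k$n_species_modelled,
      100 * k$n_species_modelled / (k$n_species_modelled + k$n_species_absent),
      min(sizes), max(sizes)
    )
  )
}

#' Species whose true range the PA mask misses entirely
#'
#' The lowland-gap check: with an elevation-biased existing-PA mask, a
#' realistic world must contain at least one species with 0% of its true
#' range protected.
#'
#' @param species_set a `virtual_species_set`.
#' @param pa_mask logical fine-grid matrix.
#' @return Character vector of species ids with zero protected range.
#' @export
lowland_gap_species <- function(species_set, pa_mask) {
  ids <- species_set$species$species_id
  ids[vapply(ids, function(sp) {
    !any(species_set$range[[sp]] & pa_mask)
  }, TRUE)]
}

#' Run the full synthetic conservation assessment
#'
#' Generates a world (landscape, virtual species, elevation-biased existing
#' PAs, transect survey), fits the multi-response MARS models in random
#' species groups, binarizes ranges with the SD threshold, aggregates to
#' planning units, and runs the lock-in and free additional-PA scenarios.
#' Returns everything needed for gap reporting.
#'
#' @param seed master seed for every stage.
#' @param n_rows,n_cols fine-grid dimensions (default 120 x 120 cells of
#'   0.1 km^2).
#' @param n_species number of virtual species (default 60).
#' @param pu_side_cells planning-unit block side in cells (default 6).
#' @param pa_fraction existing-PA fraction of the landscape (default 0.057).
#' @param prop uniform representation target for the scenarios
#'   (default 0.15).
#' @param blm boundary length modifier (default 0.0007).
#' @param config an [anneal_config()]; its seed is overridden by `seed`.
#' @param survey_spec,niche_spec overrides forwarded to the generators.
#' @return A list: `env`, `species_set`, `pa_mask`, `occurrences`, `matrix`,
#'   `model`s (per group), `eval` (AUC table), `ranges`, `range_summary`,
#'   `planning_grid`, `amounts`, `scenarios` (lock-in and free runs),
#'   `representation` (per scenario + existing PAs), `lowland_gap`.
#' @export
run_synthetic_study <- function(seed = 1, n_rows = 120, n_cols = 120,
                                n_species = 60, pu_side_cells = 6,
                                pa_fraction = 0.057, prop = 0.15,
                                blm = 0.0007, config = anneal_config(),
                                survey_spec = list(), niche_spec = list()) {
  env <- make_landscape(n_rows, n_cols, seed = seed)
  species_set <- simulate_species(env, n_species = n_species, seed = seed + 1,
                                  niche_spec = niche_spec)
  pa_mask <- make_existing_pas(env, target_fraction = pa_fraction,
                               seed = seed + 2)
  occurrences <- sample_occurrences(species_set, env, seed = seed + 3,
                                    survey_spec = survey_spec)

  ssm <- build_site_species_matrix(occurrences, env)
  groups <- partition_species_groups(colnames(ssm$responses), seed = seed + 4)

  ranges <- list()
  evals <- list()
  models <- list()
  summaries <- list()
  for (g in seq_along(groups)) {
    sub <- ssm
    sub$responses <- ssm$responses[, groups[[g]], drop = FALSE]
    model <- fit_mars_multiresponse(sub)
    rm_g <- build_range_maps(model, sub, env)
    models[[g]] <- model
    evals[[g]] <- evaluate_sdm(model, sub)
    ranges <- c(ranges, rm_g$ranges)
    summaries[[g]] <- rm_g$summary
  }
  eval_tab <- dplyr::bind_rows(evals)
  range_summary <- dplyr::bind_rows(summaries)

  nonempty <- names(ranges)[vapply(ranges, function(r) r$range_area_km2 > 0, TRUE)]
  ranges <- ranges[nonempty]
  agg <- aggregate_to_planning_units(ranges, env, pu_side_cells = pu_side_cells)

  species_tbl <- species_set$species[
    species_set$species$species_id %in% nonempty,
    c("species_id", "endangered", "endemic", "bio_resource")]
  inputs <- list(planning_grid = agg$planning_grid, amounts = agg$amounts,
                 species = species_tbl, pa_mask = pa_mask, env = env)

  config$seed <- as.integer(seed)
  lockin <- run_scenario(inputs, scenario_additional(
    prop = prop, lock_in = TRUE, blm = blm, extent_target = "fraction_0.17"),
    config)
  free <- run_scenario(inputs, scenario_additional(
    prop = prop, lock_in = FALSE, blm = blm, extent_target = "fraction_0.17"),
    config)

  pa_grid <- mark_status(agg$planning_grid, pa_mask, mode = "lock_in")
  existing_ids <- pa_grid$pu_id[pa_grid$status == 2L]
  rep_tables <- list(
    existing = representation(agg$amounts, existing_ids, species_tbl),
    lockin = representation(agg$amounts, lockin$network, species_tbl),
    free = representation(agg$amounts, free$network, species_tbl)
  )

  list(env = env, species_set = species_set, pa_mask = pa_mask,
       occurrences = occurrences, matrix = ssm, groups = groups,
       models = models, eval = eval_tab, ranges = ranges,
       range_summary = range_summary,
       planning_grid = agg$planning_grid, amounts = agg$amounts,
       species = species_tbl, existing_pu = existing_ids,
       scenarios = list(lockin = lockin, free = free),
       representation = rep_tables,
       lowland_gap = lowland_gap_species(species_set, pa_mask),
       seed = seed)
}
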