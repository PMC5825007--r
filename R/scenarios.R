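#' Area-capped network from a ranked summed solution
#'
#' Reserve selectors do not target a total extent directly, so the final
#' network takes planning units in descending summed-solution score
#' (locked-in PUs rank first; ties broken by ascending PU id) and stops at
#' the prefix whose cumulative area is nearest the extent target. When two
#' prefixes are equidistant from the target the smaller one wins (the
#' don't-exceed rule), so the achieved area never overshoots more than it
#' must.
#'
#' @param summed_solution tibble `(pu_id, count)` from [run_repeats()].
#' @param planning_grid a `planning_grid` (areas and statuses).
#' @param extent_target total area to select, km^2; must be at least the
#'   locked-in area.
#' @return A `capped_network`: list with `selected` (PU ids), `achieved_km2`,
#'   `achieved_fraction` (of total PU area), `rank_cutoff` (number of PUs
#'   taken) and `extent_target`.
#' @export
area_cap_selection <- function(summed_solution, planning_grid, extent_target) {
  df <- dplyr::left_join(summed_solution,
                         planning_grid[, c("pu_id", "area_km2", "status")],
                         by = "pu_id")
  locked_area <- sum(df$area_km2[df$status == 2L])
  if (extent_target < locked_area) {
    stop("extent_target (", extent_target,
         " km^2) is below the locked-in area (", locked_area, " km^2)",
         call. = FALSE)
  }
  df <- df[df$status != 3L, ]
  df <- df[order(-(df$status == 2L), -df$count, df$pu_id), ]
  cum_area <- cumsum(df$area_km2)
  cut <- which.min(abs(cum_area - extent_target)) # first minimum: don't exceed
  # a zero-PU prefix can be nearest when the target is below half the first PU
  if (extent_target < cum_area[1] / 2 && locked_area == 0) cut <- 0L
  selected <- if (cut > 0) df$pu_id[seq_len(cut)] else integer(0)
  achieved <- if (cut > 0) cum_area[cut] else 0
  structure(
    list(selected = sort(selected), achieved_km2 = achieved,
         achieved_fraction = achieved / sum(planning_grid$area_km2),
         rank_cutoff = cut, extent_target = extent_target),
    class = "capped_network"
  )
}

#' @export
print.capped_network <- function(x, ...) {
  cat("<capped_network> ", length(x$selected), " PUs, ",
      round(x$achieved_km2, 2), " km^2 (",
      round(100 * x$achieved_fraction, 2), "% of the landscape; target ",
      round(x$extent_target, 2), " km^2)\n", sep = "")
  invisible(x)
}

#' Scenario specifications
#'
#' Presets for the three study designs: `scenario_equal_area()` re-selects
#' the existing protected extent from scratch (nothing locked in);
#' `scenario_additional()` grows the network to a larger extent target with
#' the existing PAs locked in (`lock_in = TRUE`, the default) or ignored
#' (`lock_in = FALSE`), e.g. double the existing extent or 17% of the
#' landscape.
#'
#' @param name scenario label.
#' @param lock_in lock existing PAs in (status 2) or leave all PUs free?
#' @param targets a target tibble (see [targets_uniform()]) or a function of
#'   the species table returning one.
#' @param blm boundary length modifier.
#' @param extent_target extent in km^2, or one of `"equal_area"`,
#'   `"double_existing"`, `"fraction_0.17"`.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name, lock_in, targets, blm = 0.0007,
                          extent_target = "equal_area") {
  structure(list(name = name, lock_in = lock_in, targets = targets,
                 blm = blm, extent_target = extent_target),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @param prop uniform representation target used by the presets.
#' @export
scenario_equal_area <- function(prop = 0.1, blm = 0, ...) {
  scenario_spec("equal_area", lock_in = FALSE,
                targets = function(sp) targets_uniform(sp$species_id, prop),
                blm = blm, extent_target = "equal_area")
}

#' @rdname scenario_spec
#' @param ... passed through to [scenario_spec()].
#' @export
scenario_additional <- function(prop = 0.15, lock_in = TRUE, blm = 0.0007,
                                extent_target = "fraction_0.17", ...) {
  scenario_spec(if (lock_in) "additional_lockin" else "additional_free",
                lock_in = lock_in,
                targets = function(sp) targets_uniform(sp$species_id, prop),
                blm = blm, extent_target = extent_target)
}

resolve_extent <- function(extent_target, planning_grid, pa_mask_area) {
  total <- sum(planning_grid$area_km2)
  if (is.numeric(extent_target)) {
    if (extent_target > total) stop("extent_target exceeds the landscape",
                                    call. = FALSE)
    return(extent_target)
  }
  switch(extent_target,
         equal_area = pa_mask_area,
         double_existing = 2 * pa_mask_area,
         fraction_0.17 = 0.17 * total,
         stop("unknown extent_target '", extent_target, "'", call. = FALSE))
}

#' Run a full conservation scenario
#'
#' Sets statuses per the scenario (lock-in or free), assembles the
#' conservation problem, runs the repeat annealer, and caps the ranked
#' summed solution at the scenario's extent target.
#'
#' @param inputs list with `planning_grid`, `amounts`, `species`
#'   (tibble with species_id + group flags), `pa_mask` (fine logical matrix)
#'   and `env` (the fine [env_stack]).
#' @param spec a [scenario_spec()].
#' @param config an [anneal_config()].
#' @return List with `network` (a `capped_network`), `result` (the
#'   `selection_result`), `problem`, and `spec`.
#' @export
run_scenario <- function(inputs, spec, config = anneal_config()) {
  stopifnot(inherits(spec, "scenario_spec"))
  grid <- mark_status(inputs$planning_grid, inputs$pa_mask,
                      mode = if (spec$lock_in) "lock_in" else "free")
  targets <- if (is.function(spec$targets)) spec$targets(inputs$species)
  else spec$targets
  problem <- conservation_problem(grid, inputs$amounts, targets,
                                  blm = spec$blm)
  result <- run_repeats(problem, config)
  pa_area <- sum(inputs$pa_mask) * inputs$env$cell_area
  extent <- resolve_extent(spec$extent_target, grid, pa_area)
  network <- area_cap_selection(result$summed_solution, grid, extent)
  list(network = network, result = result, problem = problem, spec = spec)
}

#' Planning units commonly selected across scenario networks
#'
#' @param networks list (length >= 2) of `capped_network` objects, or of PU
#'   id vectors, from the same planning grid.
#' @param planning_grid the shared `planning_grid` (for area bookkeeping).
#' @return List with `selected` (PU ids in every network) and `area_km2`.
#' @export
common_selection <- function(networks, planning_grid) {
  if (length(networks) < 2) stop("need at least 2 networks", call. = FALSE)
  sets <- lapply(networks, function(n)
    if (inherits(n, "capped_network")) n$selected else n)
  all_ids <- planning_grid$pu_id
  for (s in sets) {
    if (length(setdiff(s, all_ids)) > 0) {
      stop("network references PUs outside the planning grid", call. = FALSE)
    }
  }
  common <- Reduce(intersect, sets)
  area <- sum(planning_grid$area_km2[planning_grid$pu_id %in% common])
  list(selected = sort(common), area_km2 = area)
}

#' Expand a planning-unit selection to the fine grid
#'
#' @param selected PU ids.
#' @param planning_grid a `planning_grid` carrying block geometry.
#' @return Logical fine-grid matrix.
#' @export
pu_selection_to_mask <- function(selected, planning_grid) {
  k <- attr(planning_grid, "pu_side_cells")
  nr <- attr(planning_grid, "n_pu_rows")
  nc <- attr(planning_grid, "n_pu_cols")
  if (is.null(k)) stop("planning grid lacks block geometry", call. = FALSE)
  mask <- matrix(FALSE, nr * k, nc * k)
  rows <- planning_grid$pu_row[planning_grid$pu_id %in% selected]
  cols <- planning_grid$pu_col[planning_grid$pu_id %in% selected]
  for (i in seq_along(rows)) {
    mask[(rows[i] - 1) * k + seq_len(k), (cols[i] - 1) * k + seq_len(k)] <- TRUE
  }
  mask
}
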