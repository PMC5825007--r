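#' Data-driven thresholds for binarizing occurrence probabilities
#'
#' `sd_threshold()` implements the standard-deviation rule for presence-only
#' data: the cut is the mean of the modelled probabilities at the species'
#' own occurrence points minus one sample standard deviation, floored at
#' `floor` so clamped-zero probabilities cannot produce a degenerate
#' full-landscape range. `max_sss_threshold()` is the usual alternative: the
#' candidate cut maximizing sensitivity + specificity (ties broken by the
#' lowest such cut).
#'
#' @param prob_at_occurrences modelled probabilities at a species' occurrence
#'   points (at least 2, since the SD is sample-based).
#' @param floor minimum allowed threshold, in `[0, 1)` (default 0.001).
#' @param centre_offset multiplier `c` in `mean - c * sd`; default 1. Set
#'   `centre_offset = NULL` to use the SD itself as the cut (the other
#'   reading of the rule).
#' @return A single threshold value.
#' @examples
#' sd_threshold(c(0.2, 0.4, 0.6, 0.8)) # 0.5 - 0.2582 = 0.2418
#' @export
sd_threshold <- function(prob_at_occurrences, floor = 0.001, centre_offset = 1) {
  if (length(prob_at_occurrences) < 2) {
    stop("at least 2 occurrence probabilities are needed (sample SD)",
         call. = FALSE)
  }
  stopifnot(floor >= 0, floor < 1)
  s <- sd(prob_at_occurrences)
  raw <- if (is.null(centre_offset)) s else
    mean(prob_at_occurrences) - centre_offset * s
  max(floor, raw)
}

#' @rdname sd_threshold
#' @param presence_scores,absence_scores model scores at presence and
#'   (pseudo-)absence sites for `max_sss_threshold()`.
#' @export
max_sss_threshold <- function(presence_scores, absence_scores) {
  if (length(presence_scores) == 0 || length(absence_scores) == 0) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  cuts <- sort(unique(c(presence_scores, absence_scores)))
  sss <- vapply(cuts, function(k) {
    mean(presence_scores >= k) + mean(absence_scores < k)
  }, 0)
  cuts[which.max(sss)] # which.max returns the first (lowest) maximizer
}

#' Binarize a probability raster into a species range
#'
#' Presence is `p >= threshold` (so occurrence points at exactly the
#' threshold stay inside the range). Range area is cell count times cell
#' area; mean range elevation averages over range cells only and is `NA` for
#' an empty range.
#'
#' @param prob_raster numeric matrix of occurrence probabilities.
#' @param threshold cut in `[0, 1]`.
#' @param env optional [env_stack] for area and elevation bookkeeping.
#' @param species_id optional label.
#' @return A `binary_range`: list with `species_id`, `mask` (logical matrix),
#'   `threshold`, `range_area_km2`, `mean_range_elevation_m`.
#' @export
binarize <- function(prob_raster, threshold, env = NULL, species_id = NA_character_) {
  stopifnot(is.matrix(prob_raster), threshold >= 0, threshold <= 1)
  mask <- prob_raster >= threshold
  cell_area <- if (!is.null(env)) env$cell_area else 1
  elev <- if (!is.null(env)) env$layers$elevation else NULL
  structure(
    list(
      species_id = species_id,
      mask = mask,
      threshold = threshold,
      range_area_km2 = sum(mask) * cell_area,
      mean_range_elevation_m =
        if (!is.null(elev) && any(mask)) mean(elev[mask]) else NA_real_
    ),
    class = "binary_range"
  )
}

#' @export
print.binary_range <- function(x, ...) {
  cat("<binary_range> ", x$species_id, ": ", x$range_area_km2,
      " km^2 at threshold ", signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Species richness map for a group of binary ranges
#'
#' @param ranges list of `binary_range` objects (or logical matrices) on a
#'   shared grid.
#' @param group_filter optional character vector of species ids to stack.
#' @return Integer matrix; each cell counts the group members present there.
#' @export
richness_map <- function(ranges, group_filter = NULL) {
  masks <- lapply(ranges, function(r) if (inherits(r, "binary_range")) r$mask else r)
  ids <- vapply(seq_along(ranges), function(i) {
    r <- ranges[[i]]
    if (inherits(r, "binary_range") && !is.na(r$species_id)) r$species_id
    else names(ranges)[i] %||% as.character(i)
  }, "")
  if (!is.null(group_filter)) masks <- masks[ids %in% group_filter]
  if (length(masks) == 0) {
    warning("empty species group: returning a zero richness map", call. = FALSE)
    proto <- if (inherits(ranges[[1]], "binary_range")) ranges[[1]]$mask else ranges[[1]]
    return(matrix(0L, nrow(proto), ncol(proto)))
  }
  dims <- dim(masks[[1]])
  out <- matrix(0L, dims[1], dims[2])
  for (m in masks) {
    stopifnot(identical(dim(m), dims))
    out <- out + m
  }
  out
}

#' Threshold and binarize every species of a fitted model
#'
#' Applies [sd_threshold()] (or [max_sss_threshold()]) per species to the
#' model's probabilities and returns all binary ranges plus a summary table.
#'
#' @param model a `mars_model`.
#' @param matrix the fitted `site_species_matrix` (supplies per-species
#'   occurrence probabilities).
#' @param env the [env_stack] to predict over.
#' @param rule `"sd_below_mean"` (default) or `"max_sss"`.
#' @param floor threshold floor passed to [sd_threshold()].
#' @return List with `ranges` (named list of `binary_range`) and `summary`
#'   (tibble: species_id, threshold, range_area_km2,
#'   mean_range_elevation_m).
#' @export
build_range_maps <- function(model, matrix, env,
                             rule = c("sd_below_mean", "max_sss"),
                             floor = 0.001) {
  rule <- match.arg(rule)
  prob_fit <- mars_basis(model, matrix$predictors) %*% model$coefficients
  prob_fit <- pmin(pmax(prob_fit, 0), 1)
  prob_rasters <- predict_probabilities(model, env)

  ranges <- vector("list", length(model$species))
  names(ranges) <- model$species
  for (j in seq_along(model$species)) {
    sp <- model$species[j]
    pres <- matrix$responses[, sp] == 1
    theta <- if (rule == "sd_below_mean") {
      sd_threshold(prob_fit[pres, j], floor = floor)
    } else {
      max_sss_threshold(prob_fit[pres, j], prob_fit[!pres, j])
    }
    ranges[[sp]] <- binarize(prob_rasters[[sp]], theta, env, species_id = sp)
  }
  summary <- purrr::map_dfr(ranges, function(r) tibble::tibble(
    species_id = r$species_id, threshold = r$threshold,
    range_area_km2 = r$range_area_km2,
    mean_range_elevation_m = r$mean_range_elevation_m
  ))
  list(ranges = ranges, summary = summary)
}
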