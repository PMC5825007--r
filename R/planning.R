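#' Aggregate fine-grid species ranges onto coarse planning units
#'
#' Planning units (PUs) are square blocks of `pu_side_cells` x
#' `pu_side_cells` fine cells. The amount of a species in a PU is the area of
#' its binary range inside that PU (fine cells times cell area), so per
#' species the amounts sum exactly to its range area. The fine grid must tile
#' evenly into PUs.
#'
#' @param ranges named list of `binary_range` objects (or logical matrices).
#' @param env the fine-grid [env_stack].
#' @param pu_side_cells PU block side, in fine cells (default 6; with 0.1 km^2
#'   cells this gives 3.6 km^2 units, the desk-scale analogue of a 4 km^2
#'   planning grid).
#' @return List with `planning_grid` (tibble: pu_id, pu_row, pu_col,
#'   area_km2, cost, status; PU geometry in attributes) and `amounts`
#'   (tibble: species_id, pu, amount).
#' @export
aggregate_to_planning_units <- function(ranges, env, pu_side_cells = 6) {
  stopifnot(inherits(env, "env_stack"))
  k <- as.integer(pu_side_cells)
  if (k < 1 || env$n_rows %% k != 0 || env$n_cols %% k != 0) {
    stop("pu_side_cells must evenly divide both grid dimensions",
         call. = FALSE)
  }
  n_pu_rows <- env$n_rows %/% k
  n_pu_cols <- env$n_cols %/% k
  pu_area <- k^2 * env$cell_area
  side_km <- k * sqrt(env$cell_area)

  grid <- tidyr::expand_grid(pu_row = seq_len(n_pu_rows),
                             pu_col = seq_len(n_pu_cols))
  grid <- dplyr::mutate(grid,
                        pu_id = (.data$pu_row - 1L) * n_pu_cols + .data$pu_col,
                        area_km2 = pu_area, cost = pu_area, status = 0L)
  grid <- grid[, c("pu_id", "pu_row", "pu_col", "area_km2", "cost", "status")]

  Gr <- block_indicator(env$n_rows, k)
  Gc <- block_indicator(env$n_cols, k)
  amounts <- purrr::map_dfr(names(ranges), function(sp) {
    m <- ranges[[sp]]
    if (inherits(m, "binary_range")) m <- m$mask
    counts <- t(Gr) %*% (m * 1) %*% Gc # n_pu_rows x n_pu_cols cell counts
    idx <- which(counts > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    tibble::tibble(
      species_id = sp,
      pu = as.integer((idx[, 1] - 1L) * n_pu_cols + idx[, 2]),
      amount = as.numeric(counts[idx] * env$cell_area)
    )
  })
  if (nrow(amounts) == 0) {
    amounts <- tibble::tibble(species_id = character(0), pu = integer(0),
                              amount = numeric(0))
  }
  amounts <- dplyr::arrange(amounts, .data$species_id, .data$pu)

  attr(grid, "n_pu_rows") <- n_pu_rows
  attr(grid, "n_pu_cols") <- n_pu_cols
  attr(grid, "pu_side_cells") <- k
  attr(grid, "side_km") <- side_km
  attr(grid, "cell_area") <- env$cell_area
  class(grid) <- c("planning_grid", class(grid))
  list(planning_grid = grid, amounts = amounts)
}

block_indicator <- function(n, k) {
  g <- matrix(0, n, n %/% k)
  g[cbind(seq_len(n), rep(seq_len(n %/% k), each = k))] <- 1
  g
}

#' Boundary list of a rectangular planning-unit lattice
#'
#' One row per rook-adjacent PU pair with shared edge length equal to the PU
#' side (canonical ordering `id1 < id2`, each pair once). Landscape-edge
#' exposure is emitted as self-pairs (`id1 == id2`) whose length totals the
#' PU's exposed outer edges; set `include_exposure = FALSE` to omit them.
#'
#' @param planning_grid a `planning_grid`.
#' @param include_exposure emit outer-edge self-pairs? Default `TRUE`.
#' @return Tibble `(id1, id2, boundary)` with lengths in km.
#' @export
build_boundary_list <- function(planning_grid, include_exposure = TRUE) {
  nr <- attr(planning_grid, "n_pu_rows")
  nc <- attr(planning_grid, "n_pu_cols")
  side <- attr(planning_grid, "side_km")
  id <- function(r, c) (r - 1L) * nc + c

  horiz <- if (nc > 1) tidyr::expand_grid(r = seq_len(nr), c = seq_len(nc - 1)) else NULL
  vert <- if (nr > 1) tidyr::expand_grid(r = seq_len(nr - 1), c = seq_len(nc)) else NULL
  pairs <- dplyr::bind_rows(
    if (!is.null(horiz)) tibble::tibble(id1 = id(horiz$r, horiz$c),
                                        id2 = id(horiz$r, horiz$c + 1)),
    if (!is.null(vert)) tibble::tibble(id1 = id(vert$r, vert$c),
                                       id2 = id(vert$r + 1, vert$c))
  )
  out <- if (!is.null(pairs) && nrow(pairs) > 0) {
    tibble::tibble(id1 = pmin(pairs$id1, pairs$id2),
                   id2 = pmax(pairs$id1, pairs$id2),
                   boundary = side)
  } else {
    tibble::tibble(id1 = integer(0), id2 = integer(0), boundary = numeric(0))
  }

  if (include_exposure) {
    grid <- tidyr::expand_grid(r = seq_len(nr), c = seq_len(nc))
    exposed <- (grid$r == 1) + (grid$r == nr) + (grid$c == 1) + (grid$c == nc)
    sel <- exposed > 0
    out <- dplyr::bind_rows(out, tibble::tibble(
      id1 = id(grid$r[sel], grid$c[sel]),
      id2 = id(grid$r[sel], grid$c[sel]),
      boundary = exposed[sel] * side
    ))
  }
  dplyr::arrange(out, .data$id1, .data$id2)
}

#' Mark planning-unit statuses from a protected-area mask
#'
#' Under `mode = "lock_in"` a PU is locked in (status 2) when the fraction of
#' its fine cells covered by the PA mask is at least `coverage_cutoff`
#' (default 0.5, i.e. majority coverage; the boundary case of exactly 50%
#' locks in). Under `mode = "free"` every status is 0 regardless of the mask.
#'
#' @param planning_grid a `planning_grid`.
#' @param pa_mask logical fine-grid matrix.
#' @param mode `"lock_in"` or `"free"`.
#' @param coverage_cutoff lock-in coverage fraction (default 0.5).
#' @return The planning grid with updated `status`.
#' @export
mark_status <- function(planning_grid, pa_mask, mode = c("lock_in", "free"),
                        coverage_cutoff = 0.5) {
  mode <- match.arg(mode)
  planning_grid$status <- 0L
  if (mode == "free") return(planning_grid)
  k <- attr(planning_grid, "pu_side_cells")
  nc <- attr(planning_grid, "n_pu_cols")
  Gr <- block_indicator(nrow(pa_mask), k)
  Gc <- block_indicator(ncol(pa_mask), k)
  cover <- (t(Gr) %*% (pa_mask * 1) %*% Gc) / k^2
  idx <- which(cover >= coverage_cutoff, arr.ind = TRUE)
  locked <- (idx[, 1] - 1L) * nc + idx[, 2]
  planning_grid$status[match(locked, planning_grid$pu_id)] <- 2L
  planning_grid
}

#' Assemble a conservation problem
#'
#' Bundles planning units, boundary list, per-species amounts,
#' representation targets and the boundary length modifier (BLM) into the
#' object consumed by [objective_value()], [anneal()] and [run_repeats()].
#'
#' @param planning_grid a `planning_grid` (costs and statuses set).
#' @param amounts tibble `(species_id, pu, amount)`.
#' @param targets tibble `(species_id, prop, spf)`; see [targets_uniform()].
#' @param boundary boundary list from [build_boundary_list()]; built
#'   automatically when omitted.
#' @param blm boundary length modifier, `>= 0`.
#' @return A `conservation_problem`.
#' @export
conservation_problem <- function(planning_grid, amounts, targets,
                                 boundary = NULL, blm = 0) {
  stopifnot(is.finite(blm), blm >= 0)
  if (is.null(boundary)) boundary <- build_boundary_list(planning_grid)
  missing_amt <- setdiff(targets$species_id, unique(amounts$species_id))
  if (length(missing_amt) > 0) {
    stop("targets name species without amounts: ",
         paste(head(missing_amt, 5), collapse = ", "), call. = FALSE)
  }
  totals <- dplyr::summarise(dplyr::group_by(amounts, .data$species_id),
                             range_area = sum(.data$amount), .groups = "drop")
  targets <- dplyr::left_join(targets, totals, by = "species_id")
  structure(
    list(pu = planning_grid, amounts = amounts, targets = targets,
         boundary = boundary, blm = blm),
    class = "conservation_problem"
  )
}

#' @export
print.conservation_problem <- function(x, ...) {
  cat("<conservation_problem> ", nrow(x$pu), " planning units, ",
      nrow(x$targets), " species, BLM = ", x$blm, "\n", sep = "")
  cat("locked in:", sum(x$pu$status == 2L),
      " locked out:", sum(x$pu$status == 3L), "\n")
  invisible(x)
}

#' Representation target presets
#'
#' `targets_uniform()` gives every species the same proportion-of-range
#' target. `targets_tiered()` assigns targets by conservation group: a high
#' tier for endangered species, a middle tier for endemics and designated
#' biological resources, and a base tier for the rest (the classic 50/30/10
#' scheme by default).
#'
#' @param species_ids character vector (uniform preset).
#' @param prop proportion of each species' range to represent, in `[0,1]`.
#' @param spf species penalty factor (> 0) applied to unmet targets.
#' @return Tibble `(species_id, prop, spf)`.
#' @export
targets_uniform <- function(species_ids, prop, spf = 10) {
  stopifnot(prop >= 0, prop <= 1, spf > 0)
  tibble::tibble(species_id = species_ids, prop = prop, spf = spf)
}

#' @rdname targets_uniform
#' @param species_table tibble with `species_id` and logical `endangered`,
#'   `endemic`, `bio_resource` columns (tiered preset).
#' @param endangered,endemic_bio,other tier proportions (defaults 0.5, 0.3,
#'   0.1).
#' @export
targets_tiered <- function(species_table, endangered = 0.5, endemic_bio = 0.3,
                           other = 0.1, spf = 10) {
  prop <- ifelse(species_table$endangered, endangered,
                 ifelse(species_table$endemic | species_table$bio_resource,
                        endemic_bio, other))
  tibble::tibble(species_id = species_table$species_id, prop = prop, spf = spf)
}
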