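#' Sample survey-style occurrence records along mountain transects
#'
#' Emulates a national inventory in which a walking transect is surveyed in
#' each sampled block, with routes biased toward mountains. Transect start
#' cells are drawn with probability proportional to `rank(elevation)^bias`
#' (bias 0 = unbiased), a random orientation is chosen, and the straight-line
#' path (clipped at the landscape edge) gives the survey sites. At every site
#' each species is recorded with probability `detection_prob *
#' suitability(site)`. Species ending with fewer than two records are dropped
#' with a warning (two records is the minimum a species needs downstream).
#'
#' @param species_set a `virtual_species_set` from [simulate_species()].
#' @param env the generating [env_stack].
#' @param seed integer seed.
#' @param survey_spec list overriding defaults: `n_transects` (default 15),
#'   `transect_length` in cells (default 40), `detection_prob` in (0,1]
#'   (default 0.6), `elevation_bias` (exponent on the elevation rank,
#'   default 1).
#' @return A tibble `(species_id, row, col)`, one row per record, with
#'   attributes `sites` (tibble of distinct surveyed cells) and
#'   `dropped_species` (character).
#' @export
sample_occurrences <- function(species_set, env, seed = 1, survey_spec = list()) {
  stopifnot(inherits(species_set, "virtual_species_set"), inherits(env, "env_stack"))
  spec <- utils::modifyList(
    list(n_transects = 15, transect_length = 40, detection_prob = 0.6,
         elevation_bias = 1),
    survey_spec
  )
  if (!is.numeric(spec$n_transects) || spec$n_transects < 1) {
    stop("survey_spec$n_transects must be >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))

  elev <- env$layers$elevation
  n_cells <- length(elev)
  w <- if (spec$elevation_bias == 0) rep(1, n_cells) else
    rank(as.vector(elev), ties.method = "average")^spec$elevation_bias

  sites <- matrix(integer(0), ncol = 2)
  starts <- matrix(integer(0), ncol = 2)
  for (k in seq_len(spec$n_transects)) {
    start <- sample.int(n_cells, 1, prob = w)
    r0 <- (start - 1) %% env$n_rows + 1
    c0 <- (start - 1) %/% env$n_rows + 1
    starts <- rbind(starts, c(r0, c0))
    # path centred on the start cell with a uniform orientation, clipped at
    # the landscape edge, so bias enters only through start-cell selection
    theta <- runif(1, 0, 2 * pi)
    steps <- seq(0, spec$transect_length - 1) - (spec$transect_length - 1) / 2
    rr <- round(r0 + steps * sin(theta))
    cc <- round(c0 + steps * cos(theta))
    keep <- rr >= 1 & rr <= env$n_rows & cc >= 1 & cc <= env$n_cols
    sites <- rbind(sites, cbind(rr[keep], cc[keep]))
  }
  sites <- unique(sites)

  ids <- species_set$species$species_id
  recs <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    p <- spec$detection_prob *
      species_set$suitability[[ids[j]]][cbind(sites[, 1], sites[, 2])]
    hit <- runif(nrow(sites)) < p
    if (any(hit)) {
      recs[[j]] <- tibble::tibble(species_id = ids[j],
                                  row = sites[hit, 1], col = sites[hit, 2])
    }
  }
  occ <- dplyr::bind_rows(recs)

  counts <- table(occ$species_id)
  dropped <- union(setdiff(ids, names(counts)), names(counts)[counts < 2])
  if (length(dropped) > 0) {
    warning(length(dropped), " species with < 2 records dropped: ",
            paste(head(sort(dropped), 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
    occ <- occ[!occ$species_id %in% dropped, , drop = FALSE]
  }
  occ <- dplyr::arrange(occ, .data$species_id, .data$row, .data$col)
  attr(occ, "sites") <- tibble::tibble(row = sites[, 1], col = sites[, 2])
  attr(occ, "transect_starts") <- tibble::tibble(row = starts[, 1],
                                                 col = starts[, 2])
  attr(occ, "dropped_species") <- sort(dropped)
  occ
}

#' Build an elevation-biased existing protected-area mask
#'
#' Grows contiguous patches (rook adjacency) until the mask covers
#' `target_fraction` of all cells. Patch seeds and frontier cells are chosen
#' with probability proportional to `rank(elevation)^elevation_bias`; with
#' `elevation_bias = 0` growth is elevation-blind and the mask's mean
#' elevation is unbiased, while positive bias concentrates the mask on
#' mountains, as real protected-area systems often are.
#'
#' @param env an [env_stack].
#' @param target_fraction fraction of cells to protect, in (0, 1);
#'   default 0.057, a typical existing national PA share.
#' @param elevation_bias non-negative exponent (default 8).
#' @param seed integer seed.
#' @param n_patches number of patches to seed (default 5).
#' @return Logical matrix (`TRUE` = protected) with exactly
#'   `round(target_fraction * n_cells)` cells set.
#' @export
make_existing_pas <- function(env, target_fraction = 0.057, elevation_bias = 8,
                              seed = 1, n_patches = 5) {
  stopifnot(inherits(env, "env_stack"))
  n_cells <- env$n_rows * env$n_cols
  n_target <- round(target_fraction * n_cells)
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction >= 1 || n_target < 1 || n_target >= n_cells) {
    stop("target_fraction infeasible for this grid", call. = FALSE)
  }
  set.seed(as.integer(seed))

  elev <- env$layers$elevation
  w <- if (elevation_bias == 0) rep(1, n_cells) else
    rank(as.vector(elev), ties.method = "average")^elevation_bias

  mask <- matrix(FALSE, env$n_rows, env$n_cols)
  n_seed <- min(n_patches, n_target)
  seeds <- sample.int(n_cells, n_seed, prob = w)
  mask[seeds] <- TRUE

  frontier <- logical(n_cells)
  add_neighbours <- function(idx) {
    r <- (idx - 1) %% env$n_rows + 1
    c <- (idx - 1) %/% env$n_rows + 1
    nb <- rbind(cbind(r - 1, c), cbind(r + 1, c), cbind(r, c - 1), cbind(r, c + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= env$n_rows &
               nb[, 2] >= 1 & nb[, 2] <= env$n_cols, , drop = FALSE]
    nb[, 1] + (nb[, 2] - 1) * env$n_rows
  }
  frontier[add_neighbours(seeds)] <- TRUE
  frontier[mask] <- FALSE

  n_sel <- sum(mask)
  while (n_sel < n_target) {
    cand <- which(frontier)
    if (length(cand) == 0) { # all patches boxed in; reseed
      cand <- which(!mask)
    }
    pick <- if (length(cand) == 1) cand else
      sample(cand, 1, prob = w[cand])
    mask[pick] <- TRUE
    n_sel <- n_sel + 1
    frontier[pick] <- FALSE
    nb <- add_neighbours(pick)
    frontier[nb[!mask[nb]]] <- TRUE
  }
  mask
}
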