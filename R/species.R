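#' Simulate virtual species with Gaussian environmental niches
#'
#' Each virtual species gets a niche centre and width on a small set of
#' predictor layers. Suitability at a cell is the product of Gaussian
#' kernels, `exp(-0.5 * sum(((x - centre)/width)^2))`, rescaled so the best
#' cell on the landscape scores 1; the species' true range is the set of
#' cells with rescaled suitability >= 0.5. Niche widths are drawn
#' log-uniformly with stratification across species, so a single world spans
#' several orders of magnitude in true range area and contains both lowland
#' and montane specialists. A configurable fraction of species is flagged as
#' endangered, endemic or a designated biological resource.
#'
#' @param env an [env_stack].
#' @param n_species number of species to simulate (>= 1).
#' @param seed integer seed.
#' @param niche_spec list overriding the default niche model:
#'   `predictors` (character, default annual mean temperature and annual
#'   precipitation), `width_range` (named list of `c(lo, hi)` width bounds per
#'   predictor, on the predictor's scale), `centre_quantiles` (range of
#'   landscape quantiles from which niche centres are drawn), and flag
#'   fractions `p_endangered`, `p_endemic`, `p_bio_resource`.
#' @return A `virtual_species_set`: list with `species` (a tibble: species_id,
#'   the three group flags, niche centres/widths, prevalence, range_area_km2,
#'   mean_range_elevation_m), `suitability` and `range` (named lists of
#'   matrices), and the generating `cell_area`.
#' @examples
#' env <- make_landscape(24, 24, seed = 1)
#' sp <- simulate_species(env, n_species = 8, seed = 2)
#' sp$species
#' @export
simulate_species <- function(env, n_species = 60, seed = 1, niche_spec = list()) {
  stopifnot(inherits(env, "env_stack"))
  if (!is.numeric(n_species) || n_species < 1) {
    stop("n_species must be >= 1", call. = FALSE)
  }
  spec <- utils::modifyList(default_niche_spec(), niche_spec)
  for (nm in spec$predictors) {
    if (is.null(env$layers[[nm]])) stop("env lacks predictor layer '", nm, "'", call. = FALSE)
    wr <- spec$width_range[[nm]]
    if (is.null(wr) || any(wr <= 0)) {
      stop("niche widths must be strictly positive for '", nm, "'", call. = FALSE)
    }
  }
  n_species <- as.integer(n_species)
  set.seed(as.integer(seed))

  elev <- env$layers$elevation
  pred_vals <- lapply(spec$predictors, function(nm) as.vector(env$layers[[nm]]))
  names(pred_vals) <- spec$predictors

  # stratified log-uniform widths: one stratum per species, shuffled, so the
  # realised range-size spectrum always spans narrow to near-ubiquitous
  strata <- sample((seq_len(n_species) - runif(n_species)) / n_species)

  rows <- vector("list", n_species)
  suit_list <- vector("list", n_species)
  range_list <- vector("list", n_species)
  ids <- sprintf("sp%03d", seq_len(n_species))

  for (i in seq_len(n_species)) {
    centres <- widths <- numeric(length(spec$predictors))
    names(centres) <- names(widths) <- spec$predictors
    log_sq <- 0
    for (nm in spec$predictors) {
      q <- runif(1, spec$centre_quantiles[1], spec$centre_quantiles[2])
      centres[nm] <- quantile(pred_vals[[nm]], q, names = FALSE)
      wr <- spec$width_range[[nm]]
      widths[nm] <- exp(log(wr[1]) + strata[i] * (log(wr[2]) - log(wr[1])) +
                          rnorm(1, 0, spec$width_jitter))
      widths[nm] <- min(max(widths[nm], wr[1]), wr[2])
      log_sq <- log_sq + ((pred_vals[[nm]] - centres[nm]) / widths[nm])^2
    }
    suit <- exp(-0.5 * log_sq)
    mx <- max(suit)
    suit <- if (mx > 0) suit / mx else suit
    sm <- matrix(suit, env$n_rows, env$n_cols)
    rng <- sm >= 0.5
    n_in <- sum(rng)
    rows[[i]] <- tibble::tibble(
      species_id = ids[i],
      endangered = FALSE, endemic = FALSE, bio_resource = FALSE,
      niche_centre = list(centres), niche_width = list(widths),
      prevalence = n_in / (env$n_rows * env$n_cols),
      range_area_km2 = n_in * env$cell_area,
      mean_range_elevation_m = if (n_in > 0) mean(elev[rng]) else NA_real_
    )
    suit_list[[i]] <- sm
    range_list[[i]] <- rng
  }

  species <- dplyr::bind_rows(rows)
  species$endangered <- runif(n_species) < spec$p_endangered
  species$endemic <- !species$endangered & runif(n_species) < spec$p_endemic
  species$bio_resource <- !species$endangered & !species$endemic &
    runif(n_species) < spec$p_bio_resource
  names(suit_list) <- names(range_list) <- ids

  structure(
    list(species = species, suitability = suit_list, range = range_list,
         cell_area = env$cell_area, seed = as.integer(seed)),
    class = "virtual_species_set"
  )
}

default_niche_spec <- function() {
  list(
    predictors = c("annual_mean_temp", "annual_precip"),
    width_range = list(annual_mean_temp = c(0.25, 12), annual_precip = c(40, 2500)),
    width_jitter = 0.25,
    centre_quantiles = c(0.02, 0.98),
    p_endangered = 0.10, p_endemic = 0.15, p_bio_resource = 0.25
  )
}

#' @export
print.virtual_species_set <- function(x, ...) {
  cat("<virtual_species_set> ", nrow(x$species), " species; range areas ",
      round(min(x$species$range_area_km2), 2), "-",
      round(max(x$species$range_area_km2), 2), " km^2\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.virtual_species_set <- function(x, ...) x$species
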