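#' Environmental raster stacks
#'
#' An `env_stack` bundles co-registered environmental layers on a fine
#' analysis grid: elevation (m), slope (degrees), aspect (degrees clockwise
#' from north), northness (sine of aspect, dimensionless), four temperature
#' summaries (deg C) and three precipitation summaries (mm). Layers are plain
#' numeric matrices sharing dimensions; `cell_area` is the area of one fine
#' cell in km^2.
#'
#' @param layers named list of numeric matrices with identical dimensions.
#' @param cell_area area of one grid cell in km^2 (default 0.1).
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, cell_area = 0.1) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- dim(layers[[1]])
  for (nm in names(layers)) {
    if (!is.matrix(layers[[nm]]) || !identical(dim(layers[[nm]]), dims)) {
      stop("layer '", nm, "' does not share the stack dimensions", call. = FALSE)
    }
  }
  if (!is.numeric(cell_area) || length(cell_area) != 1 || cell_area <= 0) {
    stop("cell_area must be a single positive number", call. = FALSE)
  }
  structure(
    list(n_rows = dims[1], n_cols = dims[2], cell_area = cell_area,
         layers = layers),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat("<env_stack> ", x$n_rows, " x ", x$n_cols, " cells of ",
      x$cell_area, " km^2 (", round(landscape_area(x), 1), " km^2 total)\n",
      sep = "")
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Total landscape area in km^2
#' @param env an `env_stack`.
#' @return A single number, cells x cell_area.
#' @export
landscape_area <- function(env) {
  env$n_rows * env$n_cols * env$cell_area
}

#' @export
as_tibble.env_stack <- function(x, ...) {
  grid <- tidyr::expand_grid(row = seq_len(x$n_rows), col = seq_len(x$n_cols))
  vals <- purrr::map(x$layers, ~ as.vector(t(.x)))
  dplyr::bind_cols(grid, tibble::as_tibble(vals))
}

default_relief <- function() {
  list(
    base_elev = 60,
    # ridge segments in unit (u = north->south, v = west->east) coordinates:
    # a main eastern spine and two secondary ranges, loosely the shape of a
    # mountainous peninsula whose main range hugs one coast
    ridges = list(
      list(u0 = 0.05, v0 = 0.78, u1 = 0.95, v1 = 0.86, height = 1250, width = 0.16),
      list(u0 = 0.30, v0 = 0.25, u1 = 0.65, v1 = 0.55, height = 750, width = 0.11),
      list(u0 = 0.80, v0 = 0.12, u1 = 0.96, v1 = 0.45, height = 550, width = 0.09)
    ),
    noise_sd = 55, noise_smooth = 5,
    sea_level_temp = 14, lapse_rate = 6.5, lat_gradient = 4,
    seasonal_amp_north = 11, seasonal_amp_south = 8,
    precip_base = 1100, precip_orographic = 550, precip_south = 350,
    wettest_frac = 0.55, driest_frac = 0.08
  )
}

smooth_noise <- function(n_rows, n_cols, sd, window) {
  raw <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  k <- 2L * as.integer(window) + 1L
  kern <- stats::dnorm(seq(-window, window), sd = window / 2)
  kern <- kern / sum(kern)
  pad_filter <- function(m) {
    # reflect-pad then separable convolution along rows
    idx <- c(rev(seq_len(window)), seq_len(nrow(m)), nrow(m) - seq_len(window) + 1L)
    mp <- m[idx, , drop = FALSE]
    out <- apply(mp, 2, function(col) stats::filter(col, kern, sides = 2))
    out[window + seq_len(nrow(m)), , drop = FALSE]
  }
  sm <- t(pad_filter(t(pad_filter(raw))))
  sm * (sd / stats::sd(as.vector(sm)))
}

dist_to_segment <- function(u, v, s) {
  du <- s$u1 - s$u0; dv <- s$v1 - s$v0
  len2 <- du^2 + dv^2
  t <- ((u - s$u0) * du + (v - s$v0) * dv) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((u - (s$u0 + t * du))^2 + (v - (s$v0 + t * dv))^2)
}

#' Generate a synthetic mountainous landscape
#'
#' Builds an [env_stack] whose elevation comes from deterministic ridge
#' functions plus seeded, spatially smoothed Gaussian noise. Temperature
#' layers follow a lapse-rate model, `T = T_sea - lapse_rate * elev/1000 +
#' lat_gradient * (u - 1/2)` with `u` the north-to-south position in `[0,1]`,
#' so climate is collinear with elevation by construction, as in mountainous
#' study regions. Precipitation is a smooth function of elevation and
#' position. Slope and aspect are derived from elevation by central finite
#' differences; flat cells take aspect 0 (hence northness 0).
#'
#' @param n_rows,n_cols grid dimensions (each at least 8).
#' @param seed integer seed; the same seed reproduces the layers exactly.
#' @param relief_params list overriding entries of the default relief model
#'   (ridge geometry, `lapse_rate`, `sea_level_temp`, `lat_gradient`,
#'   noise and precipitation parameters).
#' @param cell_area km^2 per fine cell (default 0.1).
#' @return An [env_stack] with the eleven standard layers.
#' @examples
#' env <- make_landscape(24, 24, seed = 1)
#' landscape_area(env)
#' @export
make_landscape <- function(n_rows = 120, n_cols = 120, seed = 1,
                           relief_params = list(), cell_area = 0.1) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 8 || n_cols < 8) {
    stop("grid dimensions must be at least 8 x 8", call. = FALSE)
  }
  rp <- default_relief()
  rp[names(relief_params)] <- relief_params # plain override, no recursion
  if (!is.finite(rp$lapse_rate) || !is.finite(rp$lat_gradient)) {
    stop("lapse_rate and gradient parameters must be finite", call. = FALSE)
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)

  u <- matrix((seq_len(n_rows) - 0.5) / n_rows, n_rows, n_cols)
  v <- matrix((seq_len(n_cols) - 0.5) / n_cols, n_rows, n_cols, byrow = TRUE)

  elev <- matrix(rp$base_elev, n_rows, n_cols)
  for (s in rp$ridges) {
    elev <- elev + s$height * exp(-0.5 * (dist_to_segment(u, v, s) / s$width)^2)
  }
  if (rp$noise_sd > 0) {
    set.seed(as.integer(seed))
    elev <- elev + smooth_noise(n_rows, n_cols, rp$noise_sd, rp$noise_smooth)
  }
  elev <- pmax(elev, 0)

  amt <- rp$sea_level_temp - rp$lapse_rate * elev / 1000 +
    rp$lat_gradient * (u - 0.5)
  amp <- rp$seasonal_amp_north + (rp$seasonal_amp_south - rp$seasonal_amp_north) * u
  precip <- rp$precip_base + rp$precip_orographic * elev / 1000 +
    rp$precip_south * sin(pi * u / 2)

  topo <- terrain_layers(elev, cell_area)

  env_stack(
    layers = list(
      elevation = elev,
      slope = topo$slope,
      aspect = topo$aspect,
      northness = topo$northness,
      annual_mean_temp = amt,
      temp_seasonality = amp,
      temp_warmest_q = amt + amp,
      temp_coldest_q = amt - amp,
      annual_precip = precip,
      precip_wettest_q = rp$wettest_frac * precip,
      precip_driest_q = rp$driest_frac * precip
    ),
    cell_area = cell_area
  )
}

# slope (deg), aspect (deg clockwise from north, 0 on flat cells) and
# northness = sin(aspect) from central finite differences on the elevation
# grid; edges use one-sided differences via replication.
terrain_layers <- function(elev, cell_area) {
  n_rows <- nrow(elev); n_cols <- ncol(elev)
  side_m <- sqrt(cell_area) * 1000
  pad_r <- elev[c(1, seq_len(n_rows), n_rows), , drop = FALSE]
  pad_c <- elev[, c(1, seq_len(n_cols), n_cols), drop = FALSE]
  # gy: gradient toward south (increasing row); gx: toward east (increasing col)
  gy <- (pad_r[seq_len(n_rows) + 2L, ] - pad_r[seq_len(n_rows), ]) / (2 * side_m)
  gx <- (pad_c[, seq_len(n_cols) + 2L] - pad_c[, seq_len(n_cols)]) / (2 * side_m)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  # downslope azimuth: north = 0, east = 90. The downslope vector is
  # (-gx, -gy) in (east, south) components; azimuth from north uses
  # north-component = +gy (south component negated).
  flat <- gx == 0 & gy == 0
  az <- atan2(-gx, gy) * 180 / pi
  az <- (az + 360) %% 360
  az[flat] <- 0
  list(slope = slope, aspect = az, northness = sin(az * pi / 180))
}

#' @export
autoplot.env_stack <- function(object, layer = "elevation", ...) {
  df <- as_tibble.env_stack(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data[[layer]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = layer, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
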