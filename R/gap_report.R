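#' Per-species representation inside a reserve network
#'
#' For each species, the percent of its modelled range area captured by the
#' network: `100 * sum(amounts over selected PUs) / range_area`. Group means
#' are arithmetic means over the species carrying each flag (the `all` group
#' covers every species).
#'
#' @param amounts tibble `(species_id, pu, amount)`.
#' @param network PU ids, or a `capped_network`.
#' @param species species table with `species_id` and logical `endangered`,
#'   `endemic`, `bio_resource` columns (flags optional).
#' @return A `representation_table`: list with `species` (tibble:
#'   species_id, range_area_km2, amount_inside_km2, percent_inside) and
#'   `group_means` (tibble: group, n_species, mean_percent).
#' @export
representation <- function(amounts, network, species) {
  if (inherits(network, "capped_network")) network <- network$selected
  totals <- dplyr::summarise(dplyr::group_by(amounts, .data$species_id),
                             range_area_km2 = sum(.data$amount),
                             .groups = "drop")
  zero <- totals$species_id[totals$range_area_km2 <= 0]
  if (length(zero) > 0) {
    warning(length(zero), " species with zero range excluded", call. = FALSE)
    totals <- totals[!totals$species_id %in% zero, ]
  }
  inside <- dplyr::summarise(
    dplyr::group_by(amounts[amounts$pu %in% network, ], .data$species_id),
    amount_inside_km2 = sum(.data$amount), .groups = "drop")
  tab <- dplyr::left_join(totals, inside, by = "species_id")
  tab$amount_inside_km2[is.na(tab$amount_inside_km2)] <- 0
  tab$percent_inside <- 100 * tab$amount_inside_km2 / tab$range_area_km2

  tab <- dplyr::left_join(tab, species, by = "species_id")
  groups <- list(all = rep(TRUE, nrow(tab)))
  for (g in c("endangered", "endemic", "bio_resource")) {
    if (g %in% names(tab)) groups[[g]] <- tab[[g]] %in% TRUE
  }
  group_means <- purrr::map_dfr(names(groups), function(g) tibble::tibble(
    group = g, n_species = sum(groups[[g]]),
    mean_percent = if (any(groups[[g]]))
      mean(tab$percent_inside[groups[[g]]]) else NA_real_
  ))
  structure(list(species = tab, group_means = group_means),
            class = "representation_table")
}

#' @export
print.representation_table <- function(x, ...) {
  cat("<representation_table> ", nrow(x$species), " species\n", sep = "")
  print(x$group_means)
  invisible(x)
}

#' @export
tidy.representation_table <- function(x, ...) x$species

#' @export
glance.representation_table <- function(x, ...) {
  tidyr::pivot_wider(x$group_means[, c("group", "mean_percent")],
                     names_from = "group", values_from = "mean_percent",
                     names_prefix = "mean_pct_")
}

#' Equal-width stratification of species
#'
#' Splits species into `n_classes` equal-width classes over the observed
#' range of a classing variable (range size or mean range elevation).
#' Boundary values fall in the lower class except the global maximum, which
#' stays in the top class. Degenerate spread (all values equal) yields a
#' single class with a warning.
#'
#' @param values numeric classing values (finite).
#' @param n_classes number of classes (default 10).
#' @return Integer class assignments in `1..n_classes`, with a `breaks`
#'   attribute.
#' @export
stratify <- function(values, n_classes = 10) {
  if (!all(is.finite(values))) stop("classing values must be finite", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    warning("degenerate spread: a single stratification class", call. = FALSE)
    out <- rep(1L, length(values))
    attr(out, "breaks") <- c(lo, hi)
    return(out)
  }
  breaks <- seq(lo, hi, length.out = n_classes + 1)
  cls <- findInterval(values, breaks, left.open = TRUE) # boundaries drop down
  cls[values == lo] <- 1L
  cls[cls > n_classes] <- n_classes
  out <- as.integer(cls)
  attr(out, "breaks") <- breaks
  out
}

#' Wilcoxon rank-sum test with an exact small-sample path
#'
#' Compares per-species representation between two networks within a
#' stratification class. The statistic `W` counts pairs (with half-weight for
#' ties), as in `stats::wilcox.test`. For `n_a + n_b <= 12` the two-sided
#' p-value is computed by full enumeration of all group relabellings
#' (exact even under ties); otherwise it comes from the normal approximation
#' with midranks, tie-corrected variance and continuity correction.
#'
#' @param sample_a,sample_b numeric samples (non-empty).
#' @param exact_max largest `n_a + n_b` for the exact path (default 12).
#' @return List with `statistic` (W), `p_value`, and `method`.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b, exact_max = 12) {
  n_a <- length(sample_a); n_b <- length(sample_b)
  if (n_a == 0 || n_b == 0) stop("both samples must be non-empty", call. = FALSE)
  w_stat <- function(idx_a, pooled_ranks) {
    sum(pooled_ranks[idx_a]) - length(idx_a) * (length(idx_a) + 1) / 2
  }
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled, ties.method = "average")
  W <- w_stat(seq_len(n_a), r)

  if (n_a + n_b <= exact_max) {
    combos <- utils::combn(n_a + n_b, n_a)
    mu <- n_a * n_b / 2
    ws <- apply(combos, 2, function(ix) w_stat(ix, r))
    p <- mean(abs(ws - mu) >= abs(W - mu) - 1e-12)
    return(list(statistic = W, p_value = p, method = "exact permutation"))
  }
  ht <- suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = FALSE, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "normal approximation")
}

#' Stratified comparison of representation between two networks
#'
#' Classes species by range size or mean range elevation
#' ([stratify()]), then per class reports each network's mean percent
#' representation and a Wilcoxon rank-sum test of the paired species values.
#'
#' @param rep_a,rep_b `representation_table`s for the two networks over the
#'   same species set.
#' @param class_values named numeric vector of the classing variable
#'   (names = species ids), e.g. range areas or mean range elevations.
#' @param n_classes number of equal-width classes (default 10).
#' @param class_var label for the classing variable.
#' @return A `stratified_comparison` tibble: class, class_lo, class_hi,
#'   n_species, mean_percent_a, mean_percent_b, statistic, p_value, method.
#' @export
stratified_comparison <- function(rep_a, rep_b, class_values, n_classes = 10,
                                  class_var = "value") {
  a <- rep_a$species; b <- rep_b$species
  ids <- intersect(a$species_id, b$species_id)
  ids <- ids[ids %in% names(class_values)]
  vals <- class_values[ids]
  cls <- stratify(unname(vals), n_classes)
  breaks <- attr(cls, "breaks")
  pa <- setNames(a$percent_inside, a$species_id)[ids]
  pb <- setNames(b$percent_inside, b$species_id)[ids]

  out <- purrr::map_dfr(sort(unique(cls)), function(k) {
    in_k <- cls == k
    ht <- wilcoxon_rank_sum(pa[in_k], pb[in_k])
    tibble::tibble(
      class = k,
      class_lo = breaks[min(k, length(breaks) - 1)],
      class_hi = breaks[min(k + 1, length(breaks))],
      n_species = sum(in_k),
      mean_percent_a = mean(pa[in_k]),
      mean_percent_b = mean(pb[in_k]),
      statistic = ht$statistic,
      p_value = ht$p_value,
      method = ht$method
    )
  })
  attr(out, "class_var") <- class_var
  class(out) <- c("stratified_comparison", class(out))
  out
}

#' @export
autoplot.stratified_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("class", "mean_percent_a", "mean_percent_b")],
    cols = c("mean_percent_a", "mean_percent_b"),
    names_to = "network", values_to = "mean_percent")
  df$network <- ifelse(df$network == "mean_percent_a", "a", "b")
  stars <- ifelse(object$p_value <= 0.01, "**",
                  ifelse(object$p_value <= 0.05, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$class),
                                   y = .data$mean_percent,
                                   fill = .data$network)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::annotate("text", x = seq_along(stars),
                      y = max(df$mean_percent) * 1.05, label = stars) +
    ggplot2::labs(x = paste0(attr(object, "class_var") %||% "class",
                             " (equal-width classes)"),
                  y = "mean % of range inside network", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Perimeter-to-area ratio of a reserve network
#'
#' Exterior boundary length of the selected PU set (edges shared by two
#' selected PUs are interior and excluded; outer-landscape exposure counts)
#' divided by its total area.
#'
#' @param network PU ids or a `capped_network`.
#' @param planning_grid a `planning_grid`.
#' @param boundary optional boundary list (built if omitted).
#' @return Ratio in 1/km.
#' @export
perimeter_area_ratio <- function(network, planning_grid, boundary = NULL) {
  if (inherits(network, "capped_network")) network <- network$selected
  if (length(network) == 0) stop("empty network", call. = FALSE)
  if (is.null(boundary)) boundary <- build_boundary_list(planning_grid)
  sel <- planning_grid$pu_id %in% network
  names(sel) <- planning_grid$pu_id
  internal <- boundary$id1 != boundary$id2
  s1 <- sel[as.character(boundary$id1)]
  s2 <- sel[as.character(boundary$id2)]
  perim <- sum(boundary$boundary[internal & (s1 != s2)]) +
    sum(boundary$boundary[!internal & s1])
  area <- sum(planning_grid$area_km2[sel])
  perim / area
}

#' Percent of one network's area inside another
#'
#' @param network_a,network_b PU ids or `capped_network`s on the same grid.
#' @param planning_grid the shared `planning_grid`.
#' @return `100 * area(a intersect b) / area(a)`.
#' @export
network_overlap <- function(network_a, network_b, planning_grid) {
  if (inherits(network_a, "capped_network")) network_a <- network_a$selected
  if (inherits(network_b, "capped_network")) network_b <- network_b$selected
  if (length(network_a) == 0) stop("network_a is empty", call. = FALSE)
  area_of <- function(ids) sum(planning_grid$area_km2[planning_grid$pu_id %in% ids])
  100 * area_of(intersect(network_a, network_b)) / area_of(network_a)
}

#' Elevation summary of a reserve network
#'
#' Pools the fine cells inside the selected PUs and returns the mean and
#' sample SD of their elevation.
#'
#' @param network PU ids or a `capped_network`.
#' @param planning_grid a `planning_grid` with block geometry.
#' @param env the fine [env_stack].
#' @return Tibble `(mean_elevation_m, sd_elevation_m, n_cells)`.
#' @export
elevation_summary <- function(network, planning_grid, env) {
  if (inherits(network, "capped_network")) network <- network$selected
  if (length(network) == 0) stop("empty network", call. = FALSE)
  mask <- pu_selection_to_mask(network, planning_grid)
  vals <- env$layers$elevation[mask]
  tibble::tibble(mean_elevation_m = mean(vals),
                 sd_elevation_m = sd(vals),
                 n_cells = length(vals))
}
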