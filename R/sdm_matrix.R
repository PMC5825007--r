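#' Build the site-by-species matrix with inventory pseudo-absences
#'
#' Multi-response distribution modelling fits all species jointly on a matrix
#' with one row per distinct surveyed site. A cell of the response matrix is
#' 1 where the species was recorded; everywhere else the *other* species'
#' survey locations act as inventory pseudo-absences (0). Predictor values
#' are extracted from the environmental stack at each site.
#'
#' @param occurrences tibble `(species_id, row, col)` as returned by
#'   [sample_occurrences()].
#' @param env an [env_stack].
#' @param predictors character vector of layer names to extract
#'   (default: all layers).
#' @param species_ids optional full species list; listed species with zero
#'   records are excluded with a warning.
#' @return A `site_species_matrix`: list with `sites` (tibble row, col),
#'   `predictors` (sites x p numeric matrix) and `responses`
#'   (sites x S 0/1 matrix, column names = species ids).
#' @export
build_site_species_matrix <- function(occurrences, env, predictors = NULL,
                                      species_ids = NULL) {
  stopifnot(inherits(env, "env_stack"),
            all(c("species_id", "row", "col") %in% names(occurrences)))
  if (any(occurrences$row < 1 | occurrences$row > env$n_rows |
            occurrences$col < 1 | occurrences$col > env$n_cols)) {
    stop("occurrence records fall off the grid", call. = FALSE)
  }
  if (is.null(predictors)) predictors <- names(env$layers)
  missing_layers <- setdiff(predictors, names(env$layers))
  if (length(missing_layers) > 0) {
    stop("env lacks layer(s): ", paste(missing_layers, collapse = ", "),
         call. = FALSE)
  }

  present <- unique(occurrences$species_id)
  if (!is.null(species_ids)) {
    absent <- setdiff(species_ids, present)
    if (length(absent) > 0) {
      warning(length(absent), " species with zero records excluded",
              call. = FALSE)
    }
    present <- intersect(species_ids, present)
  }
  present <- sort(present)

  sites <- dplyr::distinct(occurrences[, c("row", "col")])
  sites <- dplyr::arrange(sites, .data$row, .data$col)
  site_key <- paste(sites$row, sites$col)

  X <- sapply(predictors, function(nm) env$layers[[nm]][cbind(sites$row, sites$col)])
  X <- matrix(X, nrow = nrow(sites), dimnames = list(NULL, predictors))

  Y <- matrix(0L, nrow(sites), length(present),
              dimnames = list(NULL, present))
  occ <- occurrences[occurrences$species_id %in% present, ]
  ri <- match(paste(occ$row, occ$col), site_key)
  Y[cbind(ri, match(occ$species_id, present))] <- 1L

  structure(list(sites = sites, predictors = X, responses = Y),
            class = "site_species_matrix")
}

#' @export
print.site_species_matrix <- function(x, ...) {
  cat("<site_species_matrix> ", nrow(x$sites), " sites x ",
      ncol(x$responses), " species (", ncol(x$predictors), " predictors)\n",
      sep = "")
  invisible(x)
}

#' Randomly partition species into modelling groups
#'
#' Joint models over too many species become ill-conditioned, so species are
#' split into random batches fitted separately. Each group gets
#' `floor(S / n_groups)` species and the remainder is assigned to the final
#' group, so e.g. 2,297 species in 15 groups gives fourteen groups of 153 and
#' one of 155.
#'
#' @param species_ids character vector of species ids.
#' @param n_groups number of groups; if `NULL`, the smallest number keeping
#'   every group at or below `max_batch`.
#' @param seed integer seed for the random assignment.
#' @param max_batch largest tolerable joint model (default 300).
#' @return A list of character vectors partitioning `species_ids`.
#' @export
partition_species_groups <- function(species_ids, n_groups = NULL, seed = 1,
                                     max_batch = 300) {
  s <- length(species_ids)
  if (is.null(n_groups)) n_groups <- max(1L, ceiling(s / max_batch))
  if (n_groups > s) stop("n_groups exceeds the number of species", call. = FALSE)
  set.seed(as.integer(seed))
  shuffled <- sample(species_ids)
  base <- s %/% n_groups
  sizes <- rep(base, n_groups)
  sizes[n_groups] <- sizes[n_groups] + (s - base * n_groups)
  split(shuffled, rep(seq_len(n_groups), times = sizes))
}
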