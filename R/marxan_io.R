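#' Write and read Marxan-format planning files
#'
#' Emits the four standard Marxan 2.43 input files, tab-delimited with
#' headers: `pu.dat` (id, cost, status), `spec.dat` (id, name, prop, spf),
#' `puvspr.dat` (species, pu, amount; always written sorted by pu then
#' species) and `bound.dat` (id1, id2, boundary). Species get stable integer
#' ids in the order of the problem's target table; names carry the species
#' id strings. `read_marxan_files()` inverts the writer (it accepts
#' `puvspr.dat` rows in any order) and restores a [conservation_problem].
#'
#' @param problem a `conservation_problem`.
#' @param directory output directory (created if missing).
#' @param blm boundary length modifier recorded in `input.dat`-style
#'   metadata (`meta.json`), defaulting to the problem's own.
#' @return `write_marxan_files()` returns `directory` invisibly;
#'   `read_marxan_files()` returns a `conservation_problem`.
#' @export
write_marxan_files <- function(problem, directory, blm = problem$blm) {
  stopifnot(inherits(problem, "conservation_problem"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  tsv <- function(df, file) {
    write.table(df, file.path(directory, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  tsv(data.frame(id = problem$pu$pu_id, cost = problem$pu$cost,
                 status = problem$pu$status), "pu.dat")

  spec <- data.frame(id = seq_len(nrow(problem$targets)),
                     name = problem$targets$species_id,
                     prop = problem$targets$prop,
                     spf = problem$targets$spf)
  tsv(spec, "spec.dat")

  sp_id <- setNames(spec$id, spec$name)
  pv <- data.frame(species = sp_id[problem$amounts$species_id],
                   pu = problem$amounts$pu,
                   amount = problem$amounts$amount)
  pv <- pv[order(pv$pu, pv$species), ]
  tsv(pv, "puvspr.dat")

  tsv(data.frame(id1 = problem$boundary$id1, id2 = problem$boundary$id2,
                 boundary = problem$boundary$boundary), "bound.dat")

  jsonlite::write_json(
    list(blm = blm,
         pu_attrs = attributes(problem$pu)[c("n_pu_rows", "n_pu_cols",
                                             "pu_side_cells", "side_km",
                                             "cell_area")]),
    file.path(directory, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' @rdname write_marxan_files
#' @export
read_marxan_files <- function(directory) {
  read_dat <- function(file, cols) {
    path <- file.path(directory, file)
    if (!file.exists(path)) stop("missing Marxan file: ", file, call. = FALSE)
    df <- tryCatch(read.delim(path, check.names = FALSE),
                   error = function(e) stop("malformed ", file, ": ",
                                            conditionMessage(e), call. = FALSE))
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(file, " lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    bad <- which(!stats::complete.cases(df[cols]))
    if (length(bad) > 0) {
      stop("malformed row ", bad[1] + 1L, " in ", file, call. = FALSE)
    }
    df
  }

  pu <- read_dat("pu.dat", c("id", "cost", "status"))
  spec <- read_dat("spec.dat", c("id", "name", "prop", "spf"))
  pv <- read_dat("puvspr.dat", c("species", "pu", "amount"))
  bound <- read_dat("bound.dat", c("id1", "id2", "boundary"))

  bad_sp <- setdiff(pv$species, spec$id)
  if (length(bad_sp) > 0) {
    stop("puvspr.dat references unknown species id ", bad_sp[1],
         " (first bad row ",
         which(pv$species == bad_sp[1])[1] + 1L, ")", call. = FALSE)
  }
  bad_pu <- setdiff(c(pv$pu, bound$id1, bound$id2), pu$id)
  if (length(bad_pu) > 0) {
    stop("unknown planning unit id ", bad_pu[1], call. = FALSE)
  }

  meta_path <- file.path(directory, "meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(blm = 0, pu_attrs = NULL)

  grid <- tibble::tibble(pu_id = as.integer(pu$id),
                         pu_row = NA_integer_, pu_col = NA_integer_,
                         area_km2 = pu$cost, cost = pu$cost,
                         status = as.integer(pu$status))
  if (!is.null(meta$pu_attrs$n_pu_cols)) {
    nc <- meta$pu_attrs$n_pu_cols
    grid$pu_row <- (grid$pu_id - 1L) %/% nc + 1L
    grid$pu_col <- (grid$pu_id - 1L) %% nc + 1L
    grid$area_km2 <- meta$pu_attrs$pu_side_cells^2 * meta$pu_attrs$cell_area
    for (a in names(meta$pu_attrs)) attr(grid, a) <- meta$pu_attrs[[a]]
  }
  class(grid) <- c("planning_grid", class(grid))

  name_of <- setNames(spec$name, spec$id)
  amounts <- tibble::tibble(species_id = unname(name_of[as.character(pv$species)]),
                            pu = as.integer(pv$pu), amount = pv$amount)
  amounts <- dplyr::arrange(amounts, .data$species_id, .data$pu)
  targets <- tibble::tibble(species_id = spec$name, prop = spec$prop,
                            spf = spec$spf)
  boundary <- tibble::tibble(id1 = as.integer(bound$id1),
                             id2 = as.integer(bound$id2),
                             boundary = bound$boundary)
  conservation_problem(grid, amounts, targets, boundary = boundary,
                       blm = meta$blm %||% 0)
}

#' Plain-text raster I/O (ESRI ASCII grid)
#'
#' Writes a numeric matrix as a headered ASCII grid (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` then the rows
#' north-to-south), the text interchange format for single-band rasters.
#'
#' @param m numeric matrix (row 1 = northernmost row).
#' @param path file path.
#' @param cellsize cell side length (km).
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   the matrix (with `cellsize` attribute).
#' @export
write_ascii_grid <- function(m, path, cellsize = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", 0), paste("yllcorner", 0),
    paste("cellsize", format(cellsize, digits = 15)),
    paste("NODATA_value", -9999)
  ), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  vals <- setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                   tolower(vapply(kv, `[[`, "", 1)))
  m <- as.matrix(read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == vals["nrows"], ncol(m) == vals["ncols"])
  m[m == vals["nodata_value"]] <- NA
  attr(m, "cellsize") <- unname(vals["cellsize"])
  m
}

#' Write a generated world to disk
#'
#' Persists occurrences (CSV), every environmental layer and the PA mask
#' (ASCII grids) and a JSON manifest of generation parameters, so a run can
#' be archived or consumed by external tools.
#'
#' @param env an [env_stack]; `occurrences` a record tibble; `pa_mask` a
#'   logical matrix; `out_dir` output directory; `manifest` named list of
#'   generation parameters (seeds etc.) stored as JSON.
#' @param occurrences,pa_mask,out_dir,manifest see above.
#' @return `out_dir`, invisibly.
#' @export
write_world <- function(env, occurrences, pa_mask, out_dir, manifest = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(occurrences[, c("species_id", "row", "col")],
                   file.path(out_dir, "occurrences.csv"), row.names = FALSE)
  side <- sqrt(env$cell_area)
  for (nm in names(env$layers)) {
    write_ascii_grid(env$layers[[nm]], file.path(out_dir, paste0(nm, ".asc")),
                     cellsize = side)
  }
  write_ascii_grid(pa_mask * 1, file.path(out_dir, "pa_mask.asc"),
                   cellsize = side)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
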