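#' Annealing configuration
#'
#' Controls the simulated-annealing schedule. The default iteration count is
#' `10^4 * n_PU` capped at `10^6` (the classic Marxan default); the initial
#' temperature adapts to the problem by probing random flips when
#' `t_init = NULL`; cooling is geometric, multiplying the temperature by
#' `cooling` every `cool_every` iterations (default: once per `n_PU`
#' iterations). Every run finishes with greedy single-flip improvement
#' sweeps.
#'
#' @param n_runs number of repeat runs for [run_repeats()] (default 100).
#' @param n_iter iterations per run; `NULL` = `min(1e4 * n_PU, 1e6)`.
#' @param t_init initial temperature; `NULL` = adaptive (from the spread of
#'   score changes over 100 random probe flips).
#' @param cooling geometric cooling factor in (0, 1) (default 0.95).
#' @param cool_every iterations between coolings; `NULL` = `n_PU`.
#' @param init_prob probability an available PU starts selected (default 0.2).
#' @param seed master seed; per-run seeds are derived from it.
#' @return An `anneal_config` list.
#' @export
anneal_config <- function(n_runs = 100, n_iter = NULL, t_init = NULL,
                          cooling = 0.95, cool_every = NULL, init_prob = 0.2,
                          seed = 1) {
  stopifnot(n_runs >= 1, cooling > 0, cooling < 1,
            init_prob >= 0, init_prob <= 1)
  if (!is.null(t_init)) stopifnot(t_init > 0)
  structure(list(n_runs = as.integer(n_runs), n_iter = n_iter,
                 t_init = t_init, cooling = cooling, cool_every = cool_every,
                 init_prob = init_prob, seed = as.integer(seed)),
            class = "anneal_config")
}

resolve_config <- function(config, n_pu) {
  if (is.null(config$n_iter)) config$n_iter <- min(1e4 * n_pu, 1e6)
  if (is.null(config$cool_every)) config$cool_every <- n_pu
  if (is.null(config$t_init)) config$t_init <- -1 # adaptive, resolved in C++
  config
}

#' Single simulated-annealing run
#'
#' Starts from the locked-in PUs plus a random subset of available PUs, flips
#' one random available PU per iteration (Metropolis acceptance:
#' `delta <= 0` always, otherwise probability `exp(-delta/T)`), cools
#' geometrically, and ends with greedy improvement sweeps until no single
#' flip lowers the score. Locked-out PUs (status 3) are never touched;
#' locked-in PUs (status 2) are in every solution. The score is maintained
#' incrementally; `audit = TRUE` recomputes it from scratch after every
#' accepted flip and reports the worst relative discrepancy.
#'
#' @param problem a `conservation_problem`.
#' @param config an [anneal_config()].
#' @param run_seed seed for this run (defaults to `config$seed`).
#' @param audit cross-check incremental bookkeeping (slower)?
#' @return List with `selected` (PU ids), `objective`, `n_accepted`, and
#'   (when auditing) `max_rel_err`.
#' @export
anneal <- function(problem, config = anneal_config(), run_seed = config$seed,
                   audit = FALSE) {
  stopifnot(inherits(problem, "conservation_problem"))
  enc <- encode_problem(problem)
  anneal_encoded(enc, config, run_seed, audit)
}

anneal_encoded <- function(enc, config, run_seed, audit = FALSE) {
  cfg <- resolve_config(config, enc$n_pu)
  res <- .anneal_core(
    enc$n_pu, enc$cost, enc$status, enc$blm,
    enc$edge_a, enc$edge_b, enc$edge_len, enc$exposure,
    enc$amt_ptr, enc$amt_sp, enc$amt_val, enc$target, enc$spf,
    as.integer(cfg$n_iter), as.double(cfg$t_init), cfg$cooling,
    as.integer(cfg$cool_every), cfg$init_prob, as.double(run_seed), audit
  )
  list(selected = enc$pu_ids[res$selected], objective = res$objective,
       n_accepted = res$n_accepted,
       max_rel_err = if (audit) res$max_rel_err else NA_real_)
}

#' Repeat annealing runs and summed-solution irreplaceability
#'
#' Runs `config$n_runs` independent annealing runs (per-run seeds derived
#' from the master seed), keeps the best (lowest-objective) solution, and
#' counts per-PU selection frequency: the summed solution, an
#' irreplaceability score in `0..n_runs`. Locked-in PUs score exactly
#' `n_runs`; locked-out PUs score 0.
#'
#' @param problem a `conservation_problem`.
#' @param config an [anneal_config()].
#' @return A `selection_result`: list with `runs` (list of PU-id vectors),
#'   `objectives`, `best_run`, `best_solution` (PU ids), and
#'   `summed_solution` (tibble: pu_id, count).
#' @export
run_repeats <- function(problem, config = anneal_config()) {
  stopifnot(inherits(problem, "conservation_problem"))
  enc <- encode_problem(problem)
  seeds <- derive_seeds(config$seed, config$n_runs)

  runs <- vector("list", config$n_runs)
  objectives <- numeric(config$n_runs)
  counts <- setNames(integer(enc$n_pu), enc$pu_ids)
  for (i in seq_len(config$n_runs)) {
    r <- anneal_encoded(enc, config, seeds[i])
    runs[[i]] <- r$selected
    objectives[i] <- r$objective
    counts[as.character(r$selected)] <- counts[as.character(r$selected)] + 1L
  }
  best <- which.min(objectives)
  structure(
    list(runs = runs, objectives = objectives, best_run = best,
         best_solution = runs[[best]],
         summed_solution = tibble::tibble(pu_id = enc$pu_ids,
                                          count = unname(counts)),
         n_runs = config$n_runs),
    class = "selection_result"
  )
}

# deterministic per-run seeds: splitmix-style integer hash of
# (master_seed, run_index), kept in the positive 32-bit range
derive_seeds <- function(master_seed, n_runs) {
  h <- function(i) {
    x <- (as.double(master_seed) * 2654435761 + i * 40503) %% 2^31
    floor(x) + 1
  }
  vapply(seq_len(n_runs), h, 0)
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$n_runs, " runs; best objective ",
      signif(min(x$objectives), 6), " (run ", x$best_run, "); ",
      length(x$best_solution), " PUs in best solution\n", sep = "")
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) x$summed_solution

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(n_runs = x$n_runs,
                 best_objective = min(x$objectives),
                 mean_objective = mean(x$objectives),
                 best_n_pu = length(x$best_solution))
}

#' Exhaustive optimum for small reserve-selection instances
#'
#' Enumerates every status-respecting subset of planning units and returns
#' the minimum of [objective_value()]. Test-only oracle; refuses more than
#' 20 free PUs.
#'
#' @param problem a `conservation_problem` with few PUs.
#' @return List with `selected` (PU ids), `objective`, and `boundary_length`
#'   of the optimum (ties broken toward the first subset in enumeration
#'   order).
#' @export
exhaustive_optimum <- function(problem) {
  pu <- problem$pu
  free <- pu$pu_id[pu$status == 0L]
  locked <- pu$pu_id[pu$status == 2L]
  nf <- length(free)
  if (nf > 20) stop("exhaustive search limited to 20 free PUs", call. = FALSE)

  best_obj <- Inf; best_sel <- locked
  for (code in 0:(2^nf - 1)) {
    sel <- c(locked, free[bitwAnd(bitwShiftR(code, seq_len(nf) - 1L), 1L) == 1L])
    obj <- objective_value(problem, sel)
    if (obj < best_obj) {
      best_obj <- obj
      best_sel <- sel
    }
  }
  list(selected = sort(best_sel), objective = best_obj,
       boundary_length = boundary_length_of(problem, best_sel))
}

# total boundary length (selected/unselected edges + outer exposure) of a
# PU set under the problem's boundary list
boundary_length_of <- function(problem, selected) {
  sel <- problem$pu$pu_id %in% selected
  names(sel) <- problem$pu$pu_id
  b <- problem$boundary
  internal <- b$id1 != b$id2
  s1 <- sel[as.character(b$id1)]
  s2 <- sel[as.character(b$id2)]
  sum(b$boundary[internal & (s1 != s2)]) + sum(b$boundary[!internal & s1])
}
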