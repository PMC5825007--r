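#' Marxan-form objective value of a candidate reserve network
#'
#' `score = sum(cost of selected PUs) + BLM * boundary(R) +
#' sum_s SPF_s * max(0, (target_s - held_s) / target_s)` where `boundary(R)`
#' is the total edge length between selected and unselected PUs plus the
#' selected PUs' outer-landscape exposure (self-pairs in the boundary list),
#' `held_s` is the amount of species `s` inside the network and
#' `target_s = prop_s * range_area_s`. The shortfall is proportional
#' (shortfall/target), which makes the species penalty factor unit-free.
#'
#' This is a deliberately plain, from-scratch implementation: the annealer
#' maintains the same score incrementally in compiled code, and tests hold
#' the two routes to each other.
#'
#' @param problem a `conservation_problem`.
#' @param selected integer vector of selected PU ids.
#' @return A single number (lower is better).
#' @export
objective_value <- function(problem, selected) {
  sel <- problem$pu$pu_id %in% selected
  names(sel) <- problem$pu$pu_id
  cost <- sum(problem$pu$cost[sel])

  b <- problem$boundary
  internal <- b$id1 != b$id2
  s1 <- sel[as.character(b$id1)]
  s2 <- sel[as.character(b$id2)]
  boundary <- sum(b$boundary[internal & (s1 != s2)]) +
    sum(b$boundary[!internal & s1])

  amt_in <- problem$amounts[problem$amounts$pu %in% problem$pu$pu_id[sel], ]
  held <- tapply(amt_in$amount, amt_in$species_id, sum)
  target <- problem$targets$prop * problem$targets$range_area
  held_s <- held[problem$targets$species_id]
  held_s[is.na(held_s)] <- 0
  shortfall <- ifelse(target > 0, pmax(0, (target - held_s) / target), 0)

  cost + problem$blm * boundary + sum(problem$targets$spf * shortfall)
}

# integer-indexed encoding of a conservation_problem for the compiled core
encode_problem <- function(problem) {
  pu_ids <- problem$pu$pu_id
  n <- length(pu_ids)
  idx <- match(problem$amounts$pu, pu_ids)
  sp <- match(problem$amounts$species_id, problem$targets$species_id)
  keep <- !is.na(sp)
  ord <- order(idx[keep], sp[keep])
  a_pu <- idx[keep][ord]; a_sp <- sp[keep][ord]
  a_val <- problem$amounts$amount[keep][ord]
  amt_ptr <- c(0L, cumsum(tabulate(a_pu, nbins = n)))

  b <- problem$boundary
  internal <- b$id1 != b$id2
  e1 <- match(b$id1[internal], pu_ids) - 1L
  e2 <- match(b$id2[internal], pu_ids) - 1L
  elen <- b$boundary[internal]
  exposure <- numeric(n)
  selfp <- !internal
  if (any(selfp)) {
    si <- match(b$id1[selfp], pu_ids)
    exposure[si] <- exposure[si] + b$boundary[selfp]
  }

  list(
    n_pu = n, pu_ids = pu_ids,
    cost = problem$pu$cost, status = as.integer(problem$pu$status),
    blm = problem$blm,
    edge_a = e1, edge_b = e2, edge_len = elen, exposure = exposure,
    amt_ptr = as.integer(amt_ptr), amt_sp = as.integer(a_sp - 1L),
    amt_val = a_val,
    target = problem$targets$prop * problem$targets$range_area,
    spf = problem$targets$spf
  )
}
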