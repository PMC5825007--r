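test_that("the objective reproduces hand-computed examples", {
  # empty selection with all SPF effectively 0 scores 0
  grid <- make_test_grid(1, 4, side_km = 2)
  amounts <- tibble::tibble(species_id = "s1", pu = 1:4, amount = 1)
  tg0 <- tibble::tibble(species_id = "s1", prop = 0, spf = 1e-300)
  prob0 <- conservation_problem(grid, amounts, tg0, blm = 0)
  expect_equal(objective_value(prob0, integer(0)), 0)

  # 4-PU chain, 1 km^2 per PU, prop 0.5 (target 2), SPF 10, BLM 0, cost 4
  tg <- tibble::tibble(species_id = "s1", prop = 0.5, spf = 10)
  prob <- conservation_problem(grid, amounts, tg, blm = 0)
  expect_equal(objective_value(prob, c(1L, 3L)), 8) # target met
  expect_equal(objective_value(prob, 2L), 4 + 10 * 0.5) # half short
  # BLM = 0: score depends only on count + held, not arrangement
  expect_equal(objective_value(prob, c(1L, 2L)),
               objective_value(prob, c(2L, 4L)))

  # with BLM > 0 the same selections differ by boundary length
  probb <- conservation_problem(grid, amounts, tg, blm = 1)
  # adjacent pair: perimeter 2*(2+4)=12; separated pair: two 2x2 squares = 16
  expect_equal(objective_value(probb, c(1L, 2L)) + 4 * 1,
               objective_value(probb, c(2L, 4L)))
})

test_that("annealing respects statuses and zero targets", {
  prob <- random_problem(seed = 21, n_pu_rows = 3, n_pu_cols = 3,
                         n_species = 3, lock_in = 2, lock_out = 2)
  locked_in <- prob$pu$pu_id[prob$pu$status == 2L]
  locked_out <- prob$pu$pu_id[prob$pu$status == 3L]
  # zero out all targets: any PU beyond the locked set only adds cost
  prob$targets$prop <- 0
  res <- anneal(prob, anneal_config(n_iter = 5000), run_seed = 4)
  expect_setequal(res$selected, locked_in)

  prob2 <- random_problem(seed = 22, n_pu_rows = 3, n_pu_cols = 4,
                          n_species = 4, lock_in = 1, lock_out = 3)
  cfg <- anneal_config(n_runs = 15, n_iter = 4000, seed = 9)
  rr <- run_repeats(prob2, cfg)
  lo <- prob2$pu$pu_id[prob2$pu$status == 3L]
  li <- prob2$pu$pu_id[prob2$pu$status == 2L]
  for (run in rr$runs) {
    expect_length(intersect(run, lo), 0)
    expect_true(all(li %in% run))
  }
  counts <- setNames(rr$summed_solution$count, rr$summed_solution$pu_id)
  expect_true(all(counts[as.character(li)] == 15))
  expect_true(all(counts[as.character(lo)] == 0))
  expect_true(all(rr$summed_solution$count >= 0 &
                    rr$summed_solution$count <= 15))
})

test_that("repeat runs are reproducible from the master seed", {
  prob <- random_problem(seed = 23, n_species = 4)
  cfg <- anneal_config(n_runs = 8, n_iter = 3000, seed = 77)
  a <- run_repeats(prob, cfg)
  b <- run_repeats(prob, cfg)
  expect_identical(a$runs, b$runs)
  expect_identical(a$objectives, b$objectives)
  expect_identical(a$summed_solution, b$summed_solution)
  c <- run_repeats(prob, anneal_config(n_runs = 8, n_iter = 3000, seed = 78))
  expect_false(identical(a$summed_solution, c$summed_solution))
})

test_that("incremental bookkeeping matches the from-scratch objective", {
  prob <- random_problem(seed = 24, n_pu_rows = 4, n_pu_cols = 4,
                         n_species = 5, blm = 0.01)
  res <- anneal(prob, anneal_config(n_iter = 20000), run_seed = 3,
                audit = TRUE)
  expect_gt(res$n_accepted, 100)
  expect_lt(res$max_rel_err, 1e-9)
  # final annealer objective equals the independent R recomputation
  expect_equal(res$objective, objective_value(prob, res$selected),
               tolerance = 1e-9)
})

test_that("an essential PU appears in every run's solution", {
  grid <- make_test_grid(2, 4, side_km = 2)
  set.seed(31)
  amounts <- dplyr::bind_rows(
    tibble::tibble(species_id = "rare", pu = 7L, amount = 1),
    tibble::tibble(species_id = "common", pu = 1:8, amount = 2)
  )
  targets <- tibble::tibble(species_id = c("rare", "common"),
                            prop = c(1, 0.25), spf = 1e4)
  prob <- conservation_problem(grid, amounts, targets, blm = 0)

  # enumeration confirms PU 7 is in every optimal (and near-optimal) subset
  opt <- exhaustive_optimum(prob)
  expect_true(7L %in% opt$selected)
  best_without_7 <- Inf
  for (code in 0:(2^8 - 1)) {
    sel <- which(bitwAnd(bitwShiftR(code, 0:7), 1L) == 1L)
    if (!(7L %in% sel)) {
      best_without_7 <- min(best_without_7, objective_value(prob, sel))
    }
  }
  expect_gt(best_without_7, opt$objective + 100) # essential by a wide margin

  rr <- run_repeats(prob, anneal_config(n_runs = 12, n_iter = 4000, seed = 5))
  counts <- setNames(rr$summed_solution$count, rr$summed_solution$pu_id)
  expect_equal(unname(counts["7"]), 12L)
})

test_that("with large SPF every feasible target is met in the best solution", {
  for (s in 1:5) {
    prob <- random_problem(seed = 100 + s, n_pu_rows = 3, n_pu_cols = 3,
                           n_species = 4, spf_range = c(1e4, 1e4))
    # feasibility: selecting everything meets every target by construction
    held_all <- tapply(prob$amounts$amount, prob$amounts$species_id, sum)
    target <- setNames(prob$targets$prop * prob$targets$range_area,
                       prob$targets$species_id)
    expect_true(all(held_all[names(target)] >= target - 1e-12))

    rr <- run_repeats(prob, anneal_config(n_runs = 20, n_iter = 5000,
                                          seed = s))
    best <- rr$best_solution
    held <- tapply(prob$amounts$amount[prob$amounts$pu %in% best],
                   prob$amounts$species_id[prob$amounts$pu %in% best], sum)
    held <- held[names(target)]
    held[is.na(held)] <- 0
    expect_true(all(held >= target - 1e-9))
  }
})
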