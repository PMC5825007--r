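test_that("area capping follows the nearest-prefix, don't-exceed rule", {
  grid <- make_test_grid(1, 3, side_km = 2) # three 4 km^2 PUs
  summed <- tibble::tibble(pu_id = 1:3, count = c(9, 7, 4))
  net <- area_cap_selection(summed, grid, extent_target = 10)
  # cumulative areas 4, 8, 12: |8-10| == |12-10|, don't exceed -> 2 PUs
  expect_equal(net$rank_cutoff, 2)
  expect_equal(net$achieved_km2, 8)
  expect_setequal(net$selected, 1:2)

  # ties in count break by ascending PU id
  summed_tie <- tibble::tibble(pu_id = 1:3, count = c(5, 9, 5))
  net_tie <- area_cap_selection(summed_tie, grid, extent_target = 8)
  expect_setequal(net_tie$selected, c(2L, 1L))

  # locked-in PUs rank first even with a low count
  grid_l <- grid
  grid_l$status[3] <- 2L
  net_l <- area_cap_selection(summed_tie, grid_l, extent_target = 4)
  expect_equal(net_l$selected, 3L)
  expect_error(area_cap_selection(summed_tie, grid_l, extent_target = 2),
               "below the locked-in area")

  # raising the target never drops a previously selected PU
  prev <- integer(0)
  for (target in seq(4, 12, 4)) {
    sel <- area_cap_selection(summed, grid, target)$selected
    expect_true(all(prev %in% sel))
    prev <- sel
  }
})

test_that("scenario runs hit their extent and lock-in contracts", {
  tw <- tiny_study()
  species_tbl <- tw$species_set$species[
    tw$species_set$species$species_id %in% names(tw$ranges),
    c("species_id", "endangered", "endemic", "bio_resource")]
  inputs <- list(planning_grid = tw$planning_grid, amounts = tw$amounts,
                 species = species_tbl, pa_mask = tw$pa_mask, env = tw$env)
  cfg <- anneal_config(n_runs = 10, n_iter = 5000, seed = 11)

  eq <- run_scenario(inputs, scenario_equal_area(prop = 0.1), cfg)
  pa_area <- sum(tw$pa_mask) * tw$env$cell_area
  pu_area <- tw$planning_grid$area_km2[1]
  expect_lte(abs(eq$network$achieved_km2 - pa_area), pu_area)
  expect_true(all(eq$problem$pu$status == 0L)) # nothing locked in

  add <- run_scenario(inputs, scenario_additional(prop = 0.15,
                                                  lock_in = TRUE), cfg)
  locked <- add$problem$pu$pu_id[add$problem$pu$status == 2L]
  expect_true(all(locked %in% add$network$selected))
  expect_lte(abs(add$network$achieved_km2 - add$network$extent_target),
             pu_area)

  free <- run_scenario(inputs, scenario_additional(prop = 0.15,
                                                   lock_in = FALSE), cfg)
  expect_true(all(free$problem$pu$status == 0L))

  # a 10-30% target sweep in 5% steps yields five scenario runs
  sweep <- lapply(seq(0.10, 0.30, by = 0.05), function(p)
    scenario_additional(prop = p, lock_in = TRUE))
  expect_length(sweep, 5)
})

test_that("common selection is an exact intersection", {
  grid <- make_test_grid(3, 3)
  a <- c(1L, 2L, 5L, 9L)
  b <- c(2L, 5L, 7L)
  cs <- common_selection(list(a, b), grid)
  expect_setequal(cs$selected, c(2L, 5L))
  expect_equal(cs$area_km2, 2 * 4)

  expect_setequal(common_selection(list(a, a), grid)$selected, a)
  expect_length(common_selection(list(a, setdiff(1:9, a)), grid)$selected, 0)

  set.seed(41)
  nets <- lapply(1:3, function(i) sample(1:9, 5))
  cs3 <- common_selection(nets, grid)
  oracle <- 1:9
  for (n in nets) oracle <- oracle[oracle %in% n]
  expect_setequal(cs3$selected, oracle)

  expect_error(common_selection(list(a), grid), "at least 2")
  expect_error(common_selection(list(a, c(2L, 99L)), grid), "outside")
})

test_that("PU selections expand to the fine grid consistently", {
  tw <- tiny_study()
  sel <- tw$planning_grid$pu_id[c(2, 5)]
  mask <- pu_selection_to_mask(sel, tw$planning_grid)
  expect_equal(dim(mask), c(tw$env$n_rows, tw$env$n_cols))
  k <- attr(tw$planning_grid, "pu_side_cells")
  expect_equal(sum(mask), 2 * k^2)
})
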