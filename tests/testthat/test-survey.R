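test_that("an exhaustive, perfect-detection survey records every range cell", {
  env <- make_landscape(10, 10, seed = 51)
  sp <- simulate_species(env, n_species = 4, seed = 52)
  # transects covering all cells: 10 west-east transects of length 10 would
  # need directed placement; instead a dense net of many transects plus
  # detection 1 must record each species wherever suitability = 1. We check
  # the exact contract on the surveyed sites themselves.
  occ <- suppressWarnings(
    sample_occurrences(sp, env, seed = 53,
                       survey_spec = list(n_transects = 400,
                                          transect_length = 10,
                                          detection_prob = 1))
  )
  sites <- attr(occ, "sites")
  expect_gt(nrow(sites), 0)
  for (id in unique(occ$species_id)) {
    suit <- sp$suitability[[id]][cbind(sites$row, sites$col)]
    recorded <- paste(occ$row[occ$species_id == id],
                      occ$col[occ$species_id == id])
    # every surveyed site with suitability 1 must carry a record
    sure <- sites[suit >= 1, , drop = FALSE]
    expect_true(all(paste(sure$row, sure$col) %in% recorded))
  }
})

test_that("unbiased site placement matches the landscape elevation distribution", {
  env <- make_landscape(30, 30, seed = 61)
  sp <- simulate_species(env, n_species = 3, seed = 62)
  # transect placement is biased only through start-cell selection, and start
  # cells are iid, so the rank-sum comparison runs on start elevations
  pvals <- vapply(1:20, function(s) {
    occ <- suppressWarnings(
      sample_occurrences(sp, env, seed = 600 + s,
                         survey_spec = list(n_transects = 12,
                                            elevation_bias = 0)))
    st <- attr(occ, "transect_starts")
    start_elev <- env$layers$elevation[cbind(st$row, st$col)]
    suppressWarnings(
      wilcox.test(start_elev, as.vector(env$layers$elevation))$p.value)
  }, 0)
  # with no bias, rejections at alpha = 0.01 should be rare: allow 2/20
  expect_lte(sum(pvals < 0.01), 2)

  # and the default (biased) survey sits above the landscape mean
  occ_b <- suppressWarnings(sample_occurrences(sp, env, seed = 63))
  sites_b <- attr(occ_b, "sites")
  expect_gt(mean(env$layers$elevation[cbind(sites_b$row, sites_b$col)]),
            mean(env$layers$elevation))
})

test_that("occurrence sampling is deterministic and validates its inputs", {
  env <- make_landscape(16, 16, seed = 71)
  sp <- simulate_species(env, n_species = 6, seed = 72)
  a <- suppressWarnings(sample_occurrences(sp, env, seed = 73))
  b <- suppressWarnings(sample_occurrences(sp, env, seed = 73))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(sample_occurrences(sp, env, seed = 1,
                                  survey_spec = list(n_transects = 0)),
               "n_transects")
  # all records on grid, >= 2 per surviving species
  expect_true(all(a$row >= 1 & a$row <= 16 & a$col >= 1 & a$col <= 16))
  expect_true(all(table(a$species_id) >= 2))
})

test_that("PA masks hit their extent target and respond to elevation bias", {
  env <- make_landscape(100, 100, seed = 81, relief_params = list(noise_sd = 80))
  pa <- make_existing_pas(env, target_fraction = 0.057, seed = 82)
  expect_equal(sum(pa), round(0.057 * 100 * 100)) # 570 cells, exact
  expect_gt(mean(env$layers$elevation[pa]), mean(env$layers$elevation))

  # elevation-blind growth: mask mean elevation within 2 SE of landscape mean
  env_s <- make_landscape(40, 40, seed = 83)
  means <- vapply(1:20, function(s) {
    m <- make_existing_pas(env_s, 0.06, elevation_bias = 0, seed = 800 + s)
    mean(env_s$layers$elevation[m])
  }, 0)
  grand <- mean(means)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(grand - mean(env_s$layers$elevation)), 2 * se + 25)

  expect_error(make_existing_pas(env_s, 1.2, seed = 1), "infeasible")
  expect_error(make_existing_pas(env_s, 0, seed = 1), "infeasible")
})
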