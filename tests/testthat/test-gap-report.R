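toy_species <- tibble::tibble(
  species_id = c("a", "b", "c"),
  endangered = c(TRUE, FALSE, FALSE),
  endemic = c(FALSE, TRUE, FALSE),
  bio_resource = c(FALSE, FALSE, TRUE)
)
toy_amounts <- tibble::tibble(
  species_id = c("a", "a", "b", "c", "c", "c"),
  pu = c(1L, 2L, 2L, 1L, 3L, 4L),
  amount = c(2, 2, 4, 1, 1, 2)
)

test_that("representation percentages match hand computation", {
  r <- representation(toy_amounts, c(1L, 2L), toy_species)
  pct <- setNames(r$species$percent_inside, r$species$species_id)
  expect_equal(unname(pct["a"]), 100) # both PUs inside
  expect_equal(unname(pct["b"]), 100)
  expect_equal(unname(pct["c"]), 100 * 1 / 4)
  gm <- setNames(r$group_means$mean_percent, r$group_means$group)
  expect_equal(unname(gm["all"]), mean(c(100, 100, 25)))
  expect_equal(unname(gm["endangered"]), 100)

  none <- representation(toy_amounts, 9L, toy_species)
  expect_true(all(none$species$percent_inside == 0))

  # monotone: adding PUs never decreases any species' percent
  r3 <- representation(toy_amounts, c(1L, 2L, 3L), toy_species)
  expect_true(all(r3$species$percent_inside >= r$species$percent_inside))

  # group-mean consistency: all = weighted mean of disjoint subgroups
  w <- r$group_means
  sub <- w[w$group != "all", ]
  expect_equal(w$mean_percent[w$group == "all"],
               sum(sub$mean_percent * sub$n_species) / sum(sub$n_species))
})

test_that("equal-width stratification matches a histogram oracle", {
  cls <- stratify(1:10, n_classes = 10)
  expect_equal(as.integer(table(cls)), rep(1L, 10))

  expect_warning(one <- stratify(rep(3.3, 5)), "degenerate")
  expect_true(all(one == 1L))

  set.seed(13)
  v <- runif(200, 10, 50)
  cls10 <- stratify(v, 10)
  breaks <- attr(cls10, "breaks")
  oracle <- as.integer(cut(v, breaks, include.lowest = TRUE, right = TRUE))
  expect_equal(as.integer(cls10), oracle)
  expect_equal(as.integer(table(factor(cls10, levels = 1:10))),
               as.integer(hist(v, breaks = breaks, plot = FALSE)$counts))
  expect_error(stratify(c(1, NA)), "finite")
})

test_that("wilcoxon rank-sum reproduces exact enumeration", {
  const <- wilcoxon_rank_sum(rep(2, 3), rep(2, 3))
  expect_equal(const$p_value, 1)
  expect_equal(const$method, "exact permutation")

  # {1,2} vs {3,4}: most extreme of the 6 labelings, doubled -> 1/3
  ex <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(ex$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(ex$statistic, 0) # no a > b pairs

  # exact path matches stats::wilcox.test where the latter can be exact
  set.seed(14)
  for (i in 1:10) {
    a <- runif(sample(2:6, 1)) # continuous, no ties
    b <- runif(sample(2:6, 1))
    ours <- wilcoxon_rank_sum(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("the exact path handles ties that wilcox.test cannot, coherently", {
  # heavily tied data: wilcox.test refuses an exact p; our enumeration is the
  # reference, and the tie-corrected approximation should stay in its
  # neighbourhood (the approximation is known to drift a few percent here)
  set.seed(15)
  for (i in 1:20) {
    n_a <- sample(4:8, 1)
    n_b <- 12 - n_a
    a <- sample(seq(0, 5, 0.5), n_a, replace = TRUE)
    b <- sample(seq(0, 5, 0.5), n_b, replace = TRUE) + i %% 2
    exact <- wilcoxon_rank_sum(a, b)$p_value
    approx <- wilcoxon_rank_sum(a, b, exact_max = 0)$p_value
    expect_gte(exact, 0)
    expect_lte(exact, 1)
    expect_lt(abs(exact - approx), 0.1)
    # the W statistic itself is identical on both paths
    expect_equal(wilcoxon_rank_sum(a, b)$statistic,
                 wilcoxon_rank_sum(a, b, exact_max = 0)$statistic)
  }
})

test_that("perimeter/area ratios match closed forms", {
  grid <- make_test_grid(4, 4, side_km = 2)
  b <- build_boundary_list(grid)
  expect_equal(perimeter_area_ratio(6L, grid, b), 8 / 4) # one 2x2 km PU
  expect_equal(perimeter_area_ratio(c(6L, 7L), grid, b), 12 / 8) # adjacent pair
  # growing compact blocks decreases the ratio like 1/k
  one <- perimeter_area_ratio(6L, grid, b)
  four <- perimeter_area_ratio(c(6L, 7L, 10L, 11L), grid, b) # 2x2 block
  expect_equal(four, one / 2)
  expect_error(perimeter_area_ratio(integer(0), grid, b), "empty")
})

test_that("network overlap and elevation summaries are exact", {
  grid <- make_test_grid(3, 3)
  expect_equal(network_overlap(c(1L, 2L), c(1L, 2L), grid), 100)
  expect_equal(network_overlap(c(1L, 2L), c(5L, 6L), grid), 0)
  set.seed(16)
  a <- sample(1:9, 4); b <- sample(1:9, 5)
  expect_equal(network_overlap(a, b, grid),
               100 * length(intersect(a, b)) / length(a))
  expect_error(network_overlap(integer(0), b, grid), "empty")

  # hand-computed elevation summary on a 2-cell network
  env <- make_landscape(8, 8, seed = 17)
  env$layers$elevation <- matrix(0, 8, 8)
  env$layers$elevation[1, 1] <- 100
  env$layers$elevation[1, 2] <- 300
  agg <- aggregate_to_planning_units(list(), env, pu_side_cells = 1)
  es <- elevation_summary(c(1L, 2L), agg$planning_grid, env)
  expect_equal(es$mean_elevation_m, 200)
  expect_equal(es$sd_elevation_m, sqrt((100^2 + 100^2) / 1), tolerance = 1e-6)
  expect_equal(es$sd_elevation_m, 141.42, tolerance = 1e-2)
})

test_that("stratified comparisons report per-class tests", {
  tw <- tiny_study()
  ids <- unique(tw$amounts$species_id)
  sp_tbl <- tibble::tibble(species_id = ids, endangered = FALSE,
                           endemic = FALSE, bio_resource = FALSE)
  net_a <- tw$planning_grid$pu_id[1:10]
  net_b <- tw$planning_grid$pu_id[11:30]
  ra <- representation(tw$amounts, net_a, sp_tbl)
  rb <- representation(tw$amounts, net_b, sp_tbl)
  vals <- setNames(ra$species$range_area_km2, ra$species$species_id)
  sc <- stratified_comparison(ra, rb, vals, n_classes = 4,
                              class_var = "range size")
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1))
  expect_equal(sum(sc$n_species), length(vals))
  # class means agree with direct recomputation for the first class
  in1 <- names(vals)[stratify(unname(vals), 4) == sc$class[1]]
  expect_equal(sc$mean_percent_a[1],
               mean(ra$species$percent_inside[ra$species$species_id %in% in1]))
  p <- autoplot(sc)
  expect_s3_class(p, "ggplot")
})
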