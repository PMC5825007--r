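make_xy <- function(x, y, xname = "x") {
  list(predictors = matrix(x, ncol = 1, dimnames = list(NULL, xname)),
       responses = matrix(y, ncol = 1, dimnames = list(NULL, "sp1")))
}

test_that("a noiseless single-hinge model is recovered exactly", {
  x <- seq(0, 1, length.out = 50)
  y <- pmax(0, x - 0.5)
  fit <- fit_mars_multiresponse(make_xy(x, y))
  hinge_knots <- unlist(lapply(fit$terms, function(t)
    vapply(t, `[[`, 0, "knot")))
  expect_true(any(abs(hinge_knots - 0.5) < 0.05))
  expect_lt(fit$rss, 1e-10)
  # predictions reproduce the generating function
  p <- predict(fit, matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  expect_equal(unname(p[, 1]), y, tolerance = 1e-6)
})

test_that("the first forward-pass basis matches exhaustive enumeration", {
  set.seed(42)
  n <- 12
  X <- cbind(x1 = runif(n), x2 = runif(n))
  y <- 0.3 + 1.2 * pmax(0, X[, "x2"] - 0.4) + rnorm(n, 0, 0.05)
  m <- list(predictors = X, responses = matrix(y, ncol = 1,
                                               dimnames = list(NULL, "s")))

  # oracle: enumerate every (variable, knot) and fit intercept + mirrored pair
  best <- list(rss = Inf)
  for (v in colnames(X)) {
    for (k in sort(unique(X[, v]))) {
      h1 <- pmax(0, X[, v] - k)
      h2 <- pmax(0, k - X[, v])
      B <- cbind(1, h1, h2)
      rss <- sum(qr.resid(qr(B), y)^2)
      if (rss < best$rss - 1e-12) best <- list(rss = rss, var = v, knot = k)
    }
  }

  fit <- fit_mars_multiresponse(m, max_basis = 3)
  first <- fit$terms[[2]][[1]]
  expect_equal(first$var, best$var)
  expect_equal(first$knot, best$knot, tolerance = 1e-12)
})

test_that("forward RSS is monotone and huge GCV penalties prune to the intercept", {
  set.seed(7)
  X <- cbind(a = runif(60), b = runif(60))
  Y <- cbind(s1 = as.numeric(X[, 1] + rnorm(60, 0, 0.3) > 0.5),
             s2 = as.numeric(X[, 2] > 0.4))
  fit <- fit_mars_multiresponse(list(predictors = X, responses = Y))
  expect_true(all(diff(fit$forward_rss) <= 1e-9))

  pruned <- fit_mars_multiresponse(list(predictors = X, responses = Y),
                                   gcv_penalty = 1e12)
  expect_equal(length(pruned$terms), 1) # intercept only
  expect_equal(pruned$coefficients[1, ], colMeans(Y), tolerance = 1e-9)
})

test_that("identical response columns reduce to the single-response fit", {
  # a generating model inside the hypothesis class keeps candidate choices
  # well separated, so the shared forward path must pick the same knots
  set.seed(8)
  x <- runif(40)
  y <- 0.2 + 2 * pmax(0, x - 0.55)
  single <- fit_mars_multiresponse(make_xy(x, y))
  multi <- fit_mars_multiresponse(list(
    predictors = matrix(x, ncol = 1, dimnames = list(NULL, "x")),
    responses = matrix(y, 40, 4, dimnames = list(NULL, paste0("s", 1:4)))
  ))
  # same basis expansion ...
  expect_equal(length(multi$terms), length(single$terms))
  expect_equal(
    lapply(multi$terms, function(t) lapply(t, `[`, c("var", "knot", "sign"))),
    lapply(single$terms, function(t) lapply(t, `[`, c("var", "knot", "sign")))
  )
  # ... and per-species coefficients identical across columns
  for (j in 2:4) {
    expect_equal(multi$coefficients[, 1], multi$coefficients[, j],
                 tolerance = 1e-9)
  }
  expect_equal(unname(multi$coefficients[, 1]), unname(single$coefficients[, 1]),
               tolerance = 1e-9)
})

test_that("prediction clamps to [0,1] and reproduces the basis identity", {
  fit0 <- structure(list(
    terms = list(list()),
    coefficients = matrix(0.3, 1, 1, dimnames = list(NULL, "s")),
    selected_predictors = character(0), species = "s",
    predictor_names = "x", n = 10, n_species = 1
  ), class = "mars_model")
  env <- make_landscape(8, 8, seed = 1)
  p <- predict_probabilities(fit0, env)
  expect_true(all(p$s == 0.3))

  fit_neg <- fit0
  fit_neg$coefficients[1, 1] <- -0.2
  expect_true(all(predict_probabilities(fit_neg, env)$s == 0))
  fit_hi <- fit0
  fit_hi$coefficients[1, 1] <- 1.4
  expect_true(all(predict_probabilities(fit_hi, env)$s == 1))

  # training-site identity: clamp-free prediction equals B %*% beta
  tw <- tiny_study()
  B <- reserveplanr:::mars_basis(tw$fit, tw$ssm$predictors)
  raw <- B %*% tw$fit$coefficients
  pred <- predict(tw$fit, tw$ssm$predictors, clamp = FALSE)
  expect_equal(unname(pred), unname(raw), tolerance = 1e-12)

  expect_error(predict_probabilities(tw$fit, env_stack(
    list(annual_precip = matrix(1, 8, 8)))), "lacks")
})

test_that("model JSON serialization round-trips", {
  tw <- tiny_study()
  path <- withr::local_tempfile(fileext = ".json")
  write_mars_model(tw$fit, path)
  back <- read_mars_model(path)
  expect_equal(back$coefficients, tw$fit$coefficients, ignore_attr = TRUE)
  expect_equal(back$terms, tw$fit$terms)
  nd <- tw$ssm$predictors
  expect_equal(predict(back, nd), predict(tw$fit, nd), tolerance = 1e-12)
})
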