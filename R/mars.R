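#' Fit a multi-response MARS model
#'
#' Multivariate adaptive regression splines fitted jointly to every species
#' column of a site-by-species matrix. The model is a shared expansion in
#' hinge functions `h(x; k, s) = max(0, s * (x - k))` (products of up to
#' `max_degree` hinges form interaction terms), with one coefficient vector
#' per species estimated by least squares on the 0/1 responses.
#'
#' The forward pass greedily adds mirrored hinge pairs -- a parent basis
#' function times `max(0, x_v - k)` and times `max(0, k - x_v)` -- choosing
#' the (parent, variable, knot) whose addition most reduces the residual sum
#' of squares summed over all species, until `max_basis` terms (including the
#' intercept) are reached. Candidate knots are the observed values of each
#' variable on the parent's support, subsampled to at most `max_knots`
#' quantiles. The backward pass deletes one term at a time, accepting the
#' deletion that minimises the multi-response generalised cross-validation
#' score `GCV = (RSS / (n S)) / (1 - C(M)/n)^2` with effective parameters
#' `C(M) = M + gcv_penalty * (M - 1) / 2`, and stops when no deletion keeps
#' GCV from rising. Collinear candidate columns are dropped (with a message)
#' rather than entering a rank-deficient fit.
#'
#' @param matrix a `site_species_matrix` from [build_site_species_matrix()],
#'   or a list with elements `predictors` (n x p matrix) and `responses`
#'   (n x S matrix).
#' @param max_basis maximum number of basis functions including the
#'   intercept (default 21).
#' @param max_degree maximum hinges per term (default 2; 1 = additive model).
#' @param gcv_penalty per-knot penalty in the GCV cost (default 3).
#' @param max_knots maximum candidate knots per variable (default 50).
#' @return A `mars_model`: list with `terms` (each a list of
#'   `(var, knot, sign)` hinge components; the first term is the intercept),
#'   `coefficients` (M x S matrix, intercept row first), `gcv`, `rss`,
#'   `selected_predictors`, `forward_rss` (training RSS after each forward
#'   step) and the fit dimensions.
#' @examples
#' x <- matrix(seq(0, 1, length.out = 50), ncol = 1,
#'             dimnames = list(NULL, "x"))
#' y <- matrix(pmax(0, x - 0.5), ncol = 1, dimnames = list(NULL, "sp1"))
#' fit <- fit_mars_multiresponse(list(predictors = x, responses = y))
#' fit$selected_predictors
#' @export
fit_mars_multiresponse <- function(matrix, max_basis = 21, max_degree = 2,
                                   gcv_penalty = 3, max_knots = 50) {
  X <- matrix$predictors
  Y <- matrix$responses
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X); S <- ncol(Y)
  if (n < 2) stop("need at least 2 sites to fit", call. = FALSE)
  if (!all(is.finite(X))) stop("predictors must be finite", call. = FALSE)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"

  fwd <- mars_forward(X, Y, max_basis, max_degree, max_knots)
  terms <- fwd$terms
  B <- fwd$B

  bwd <- mars_backward(B, Y, terms, gcv_penalty)
  terms <- bwd$terms
  fit <- ls_fit(bwd$B, Y)

  vars <- unique(unlist(lapply(terms, function(t) vapply(t, `[[`, "", "var"))))
  structure(
    list(
      terms = terms,
      coefficients = fit$coef,
      gcv = bwd$gcv,
      rss = fit$rss,
      selected_predictors = vars %||% character(0),
      forward_rss = fwd$rss_trace,
      species = colnames(Y),
      predictor_names = colnames(X),
      n = n, n_species = S,
      config = list(max_basis = max_basis, max_degree = max_degree,
                    gcv_penalty = gcv_penalty, max_knots = max_knots)
    ),
    class = "mars_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

term_vars <- function(term) vapply(term, `[[`, "", "var")

# least squares of Y on B with aliased-column handling; returns coefficients
# padded with zeros for dropped columns plus total RSS
ls_fit <- function(B, Y) {
  qr_b <- qr(B)
  r <- qr_b$rank
  coef <- matrix(0, ncol(B), ncol(Y), dimnames = list(NULL, colnames(Y)))
  keep <- qr_b$pivot[seq_len(r)]
  cf <- qr.coef(qr(B[, keep, drop = FALSE]), Y)
  coef[keep, ] <- cf
  resid <- Y - B %*% coef
  list(coef = coef, rss = sum(resid^2), rank = r)
}

candidate_knots <- function(x, max_knots) {
  v <- sort(unique(x))
  if (length(v) <= 1) return(numeric(0))
  v <- v[-length(v)] # a knot at the max leaves the rising hinge identically 0
  if (length(v) > max_knots) {
    v <- unique(quantile(v, probs = seq(0, 1, length.out = max_knots),
                         names = FALSE, type = 1))
  }
  v
}

mars_forward <- function(X, Y, max_basis, max_degree, max_knots) {
  n <- nrow(X)
  terms <- list(list()) # intercept
  B <- matrix(1, n, 1)
  Q <- matrix(1 / sqrt(n), n, 1)
  Rres <- Y - Q %*% crossprod(Q, Y)
  rss <- sum(Rres^2)
  rss_trace <- rss
  tol <- 1e-10
  scale0 <- max(rss, 1e-300)

  while (ncol(B) + 1 <= max_basis) {
    best <- list(red = 0)
    for (m in seq_along(terms)) {
      if (length(terms[[m]]) >= max_degree) next
      parent <- B[, m]
      support <- parent != 0
      if (sum(support) < 3) next
      used <- term_vars(terms[[m]])
      for (v in setdiff(colnames(X), used)) {
        xv <- X[, v]
        knots <- candidate_knots(xv[support], max_knots)
        if (length(knots) == 0) next
        D <- outer(xv, knots, "-")
        A <- parent * pmax(D, 0)
        Bn <- parent * pmax(-D, 0)
        Ap <- A - Q %*% crossprod(Q, A)
        Bp <- Bn - Q %*% crossprod(Q, Bn)
        g11 <- colSums(Ap^2); g22 <- colSums(Bp^2); g12 <- colSums(Ap * Bp)
        CA <- crossprod(Ap, Rres); CB <- crossprod(Bp, Rres)
        s11 <- rowSums(CA^2); s22 <- rowSums(CB^2); s12 <- rowSums(CA * CB)
        det <- g11 * g22 - g12^2
        ok <- det > 1e-10 * (g11 * g22 + 1e-300)
        red_pair <- rep(-Inf, length(knots))
        red_pair[ok] <- (g22[ok] * s11[ok] - 2 * g12[ok] * s12[ok] +
                           g11[ok] * s22[ok]) / det[ok]
        red_a <- ifelse(g11 > tol * scale0 / n, s11 / pmax(g11, 1e-300), -Inf)
        red_b <- ifelse(g22 > tol * scale0 / n, s22 / pmax(g22, 1e-300), -Inf)
        red <- pmax(red_pair, red_a, red_b)
        j <- which.max(red)
        if (red[j] > best$red) {
          kind <- c("pair", "a", "b")[which.max(c(red_pair[j], red_a[j], red_b[j]))]
          best <- list(red = red[j], parent = m, var = v, knot = knots[j],
                       kind = kind)
        }
      }
    }
    if (!is.finite(best$red) || best$red <= 1e-12 * scale0) break

    parent <- B[, best$parent]
    xv <- X[, best$var]
    new_cols <- list()
    if (best$kind %in% c("pair", "a")) {
      new_cols <- c(new_cols, list(list(
        col = parent * pmax(xv - best$knot, 0),
        comp = list(var = best$var, knot = best$knot, sign = 1))))
    }
    if (best$kind %in% c("pair", "b")) {
      new_cols <- c(new_cols, list(list(
        col = parent * pmax(best$knot - xv, 0),
        comp = list(var = best$var, knot = best$knot, sign = -1))))
    }
    added <- 0
    for (nc in new_cols) {
      if (ncol(B) >= max_basis) break
      q <- nc$col - Q %*% crossprod(Q, nc$col)
      nq <- sqrt(sum(q^2))
      if (nq <= 1e-9 * max(sqrt(sum(nc$col^2)), 1e-300)) {
        message("dropping collinear hinge on '", best$var, "' at knot ",
                signif(nc$comp$knot, 6))
        next
      }
      q <- q / nq
      Q <- cbind(Q, q)
      B <- cbind(B, nc$col)
      terms <- c(terms, list(c(terms[[best$parent]], list(nc$comp))))
      Rres <- Rres - q %*% crossprod(q, Y)
      added <- added + 1
    }
    if (added == 0) break
    rss <- sum(Rres^2)
    rss_trace <- c(rss_trace, rss)
  }
  list(terms = terms, B = B, rss_trace = rss_trace)
}

gcv_score <- function(rss, n, S, M, penalty) {
  C <- M + penalty * (M - 1) / 2
  if (C >= n) return(Inf)
  (rss / (n * S)) / (1 - C / n)^2
}

mars_backward <- function(B, Y, terms, gcv_penalty) {
  n <- nrow(B); S <- ncol(Y)
  cur_rss <- ls_fit(B, Y)$rss
  cur_gcv <- gcv_score(cur_rss, n, S, ncol(B), gcv_penalty)
  repeat {
    if (ncol(B) == 1) break
    cand_gcv <- vapply(2:ncol(B), function(m) {
      rss_m <- ls_fit(B[, -m, drop = FALSE], Y)$rss
      gcv_score(rss_m, n, S, ncol(B) - 1, gcv_penalty)
    }, 0)
    m_best <- which.min(cand_gcv) + 1L # intercept (column 1) is never deleted
    # accept ties: Inf <= Inf still prunes toward the intercept
    if (!(cand_gcv[m_best - 1L] <= cur_gcv)) break
    B <- B[, -m_best, drop = FALSE]
    terms <- terms[-m_best]
    cur_gcv <- cand_gcv[m_best - 1L]
  }
  list(B = B, terms = terms, gcv = cur_gcv)
}

#' Evaluate the hinge-basis expansion on new data
#'
#' @param model a `mars_model`.
#' @param newdata numeric matrix with named columns covering the model's
#'   selected predictors.
#' @return The basis matrix (rows of `newdata` x model terms).
#' @keywords internal
mars_basis <- function(model, newdata) {
  need <- setdiff(model$selected_predictors, colnames(newdata))
  if (length(need) > 0) {
    stop("newdata lacks predictor(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(newdata)
  B <- matrix(1, n, length(model$terms))
  for (m in seq_along(model$terms)) {
    for (cmp in model$terms[[m]]) {
      B[, m] <- B[, m] * pmax(cmp$sign * (newdata[, cmp$var] - cmp$knot), 0)
    }
  }
  B
}

#' Predict per-species occurrence probabilities
#'
#' Evaluates the fitted basis expansion and clamps predictions to `[0, 1]`,
#' the convention for least-squares fits to 0/1 responses.
#'
#' @param model a `mars_model`.
#' @param env an [env_stack] supplying every selected predictor (or a numeric
#'   matrix of predictor columns).
#' @param clamp clamp predictions into `[0,1]`? Default `TRUE`.
#' @return If `env` is an `env_stack`: a named list of probability matrices,
#'   one per species. If a matrix: a rows x species matrix.
#' @export
predict_probabilities <- function(model, env, clamp = TRUE) {
  stopifnot(inherits(model, "mars_model"))
  if (inherits(env, "env_stack")) {
    need <- model$selected_predictors
    missing_layers <- setdiff(need, names(env$layers))
    if (length(missing_layers) > 0) {
      stop("env lacks layer(s): ", paste(missing_layers, collapse = ", "),
           call. = FALSE)
    }
    n_cells <- env$n_rows * env$n_cols
    nd <- matrix(0, n_cells, length(need), dimnames = list(NULL, need))
    for (nm in need) nd[, nm] <- as.vector(env$layers[[nm]])
    P <- mars_basis(model, nd) %*% model$coefficients
    if (clamp) P <- pmin(pmax(P, 0), 1)
    out <- lapply(seq_len(ncol(P)),
                  function(j) matrix(P[, j], env$n_rows, env$n_cols))
    names(out) <- model$species
    out
  } else {
    P <- mars_basis(model, env) %*% model$coefficients
    if (clamp) P <- pmin(pmax(P, 0), 1)
    colnames(P) <- model$species
    P
  }
}

#' @export
predict.mars_model <- function(object, newdata, clamp = TRUE, ...) {
  predict_probabilities(object, newdata, clamp = clamp)
}

#' @export
print.mars_model <- function(x, ...) {
  cat("<mars_model> ", length(x$terms), " terms (incl. intercept), ",
      x$n_species, " species, n = ", x$n, "\n", sep = "")
  cat("selected predictors:",
      paste(x$selected_predictors, collapse = ", "), "\n")
  cat("GCV:", signif(x$gcv, 6), " training RSS:", signif(x$rss, 6), "\n")
  invisible(x)
}

#' @export
tidy.mars_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$terms), function(m) {
    lbl <- if (length(x$terms[[m]]) == 0) "(Intercept)" else
      paste(vapply(x$terms[[m]], function(cmp) {
        if (cmp$sign > 0) sprintf("h(%s-%.4g)", cmp$var, cmp$knot)
        else sprintf("h(%.4g-%s)", cmp$knot, cmp$var)
      }, ""), collapse = "*")
    tibble::tibble(term = lbl, degree = length(x$terms[[m]]),
                   species_id = x$species,
                   estimate = x$coefficients[m, ])
  })
}

#' @export
glance.mars_model <- function(x, ...) {
  tibble::tibble(
    n_terms = length(x$terms),
    n_species = x$n_species,
    n_sites = x$n,
    gcv = x$gcv,
    rss = x$rss,
    n_predictors = length(x$selected_predictors)
  )
}

#' Serialize / restore a MARS model as JSON
#'
#' @param model a `mars_model`.
#' @param path file path.
#' @return `write_mars_model` returns `path` invisibly; `read_mars_model`
#'   the restored `mars_model`.
#' @export
write_mars_model <- function(model, path) {
  obj <- unclass(model)
  obj$coefficients <- list(values = as.vector(model$coefficients),
                           dim = dim(model$coefficients))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mars_model
#' @export
read_mars_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- matrix(obj$coefficients$values, obj$coefficients$dim[1],
                  obj$coefficients$dim[2])
  colnames(coefs) <- obj$species
  terms <- lapply(obj$terms, function(t) {
    if (length(t) == 0) return(list())
    lapply(seq_len(nrow(t)), function(i)
      list(var = t$var[i], knot = t$knot[i], sign = t$sign[i]))
  })
  structure(
    list(terms = terms, coefficients = coefs, gcv = obj$gcv, rss = obj$rss,
         selected_predictors = as.character(obj$selected_predictors),
         forward_rss = obj$forward_rss, species = obj$species,
         predictor_names = obj$predictor_names,
         n = obj$n, n_species = obj$n_species, config = obj$config),
    class = "mars_model"
  )
}
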