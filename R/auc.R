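#' Area under the ROC curve by the Mann-Whitney formulation
#'
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (n1 * n0)` over all
#' presence/absence score pairs, computed via midranks so ties are handled
#' exactly.
#'
#' @param presence_scores scores at presence sites.
#' @param absence_scores scores at (pseudo-)absence sites.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when either side is
#'   empty.
#' @examples
#' compute_auc(c(0.9, 0.8), c(0.1, 0.2)) # 1
#' compute_auc(c(0.8, 0.4), c(0.6, 0.2)) # 0.75
#' @export
compute_auc <- function(presence_scores, absence_scores) {
  n1 <- length(presence_scores); n0 <- length(absence_scores)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: one side has no scores", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(c(presence_scores, absence_scores), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Per-species model evaluation on the fitting data
#'
#' Scores each species by AUC using its presence sites against all
#' pseudo-absence sites of its group matrix (fit-data evaluation; there is no
#' hold-out by default because many species have too few records to spare).
#'
#' @param model a `mars_model`.
#' @param matrix the `site_species_matrix` the model was fitted on.
#' @return A tibble `(species_id, n_records, auc)`.
#' @export
evaluate_sdm <- function(model, matrix) {
  P <- mars_basis(model, matrix$predictors) %*% model$coefficients
  P <- pmin(pmax(P, 0), 1)
  purrr::map_dfr(seq_along(model$species), function(j) {
    pres <- matrix$responses[, model$species[j]] == 1
    tibble::tibble(
      species_id = model$species[j],
      n_records = sum(pres),
      auc = compute_auc(P[pres, j], P[!pres, j])
    )
  })
}
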