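# RDA offset engine: the adaptive index of a climate vector on each retained
# constrained axis is its dot product with the axis's climate coefficients;
# the offset between two climate vectors is the eigenvalue-weighted
# Euclidean distance between their index vectors.

#' Fit an RDA adaptive-index offset model
#'
#' Fits an RDA (optionally partial) of candidate-locus dosages on climate.
#' Climate is standardized internally; the standardization is stored and
#' re-applied at prediction time.
#'
#' @param allele_data samples x candidate loci dosage matrix (or
#'   [genotype_matrix()]).
#' @param climate_at_samples samples x variables climate table (raw scale).
#' @param condition optional conditioning matrix (geography, structure).
#' @param n_axes retained constrained axes (default 2).
#' @return Object of class `rda_offset_model`: `coef` (climate coefficients
#'   per retained axis), `weights` (eigenvalue fractions over retained axes,
#'   positive, summing to 1), `stats` (standardization), `variables`,
#'   `train_range`, `eig`, `rda`.
#' @export
fit_rda_offset <- function(allele_data, climate_at_samples, condition = NULL,
                           n_axes = 2) {
  Y <- if (inherits(allele_data, "genotype_matrix")) allele_data$dosages
       else as.matrix(allele_data)
  X <- as.matrix(climate_at_samples)
  st <- climate_stats(X)
  Xs <- standardize_climate(X, st)
  fit <- rda_fit(Y, Xs, condition)
  K <- min(n_axes, length(fit$eig))
  w <- fit$eig[seq_len(K)] / sum(fit$eig[seq_len(K)])
  structure(list(coef = fit$coef[, seq_len(K), drop = FALSE],
                 weights = w, stats = st, variables = colnames(X),
                 train_range = apply(X, 2, range),
                 eig = fit$eig, rda = fit),
            class = "rda_offset_model")
}

#' @export
print.rda_offset_model <- function(x, ...) {
  cat("rda_offset_model:", length(x$weights), "retained axes; weights",
      paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' @export
climate_transform.rda_offset_model <- function(model, climate) {
  m <- as.matrix(climate)[, model$variables, drop = FALSE]
  xs <- standardize_climate(m, model$stats)
  idx <- xs %*% model$coef
  sweep(idx, 2, sqrt(model$weights), "*")
}

#' RDA offset surface between two scenarios
#'
#' Per cell, `sqrt(sum_k w_k (index_now_k - index_future_k)^2)` with `w_k`
#' the eigenvalue fraction of retained axis k; adaptedness is -1 x offset.
#'
#' @param model an `rda_offset_model`.
#' @param grid_now,grid_future [climate_grid()]s sharing cells.
#' @return An [adaptedness_surface()].
#' @export
offset_rda <- function(model, grid_now, grid_future) {
  stopifnot(inherits(model, "rda_offset_model"))
  predict_offset(model, grid_now, grid_future)
}

#' @export
variable_importance.rda_offset_model <- function(model) {
  imp <- rowSums(sweep(model$coef^2, 2, model$weights, "*"))
  sort_importance(setNames(imp, rownames(model$coef)))
}
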