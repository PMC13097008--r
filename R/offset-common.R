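# Shared machinery of the genomic-offset engines: the adaptedness surface
# container, the transform/offset generics each engine implements, and
# variable-importance ranking.

#' Construct an adaptedness surface
#'
#' Per-cell genomic offset between a current and a future scenario, and the
#' adaptedness index defined as -1 x offset (larger, i.e. closer to zero,
#' means a better predicted match to future climate).
#'
#' @param cells cell data frame (`cell_id`, `x`, `y`, `lon`, `lat`).
#' @param offset non-negative per-cell offset.
#' @param method engine tag (`"gf"`, `"rda"`, `"gdm"`).
#' @param scenario_from,scenario_to [scenario_key()]s of the pair.
#' @return Object of class `adaptedness_surface`: a data frame with columns
#'   `cell_id`, `lon`, `lat`, `offset`, `adaptedness`.
#' @export
adaptedness_surface <- function(cells, offset, method,
                                scenario_from, scenario_to) {
  if (length(offset) != nrow(cells)) abort_ctx("offset length != cell count")
  if (any(offset < -1e-12)) abort_ctx("offsets must be non-negative")
  offset <- pmax(offset, 0)
  out <- data.frame(cell_id = cells$cell_id, lon = cells$lon, lat = cells$lat,
                    offset = offset, adaptedness = -offset)
  structure(out, class = c("adaptedness_surface", "data.frame"),
            method = method, scenario_from = scenario_from,
            scenario_to = scenario_to)
}

#' @export
print.adaptedness_surface <- function(x, ...) {
  cat("adaptedness_surface [", attr(x, "method"), "] ",
      attr(x, "scenario_from")$id, " -> ", attr(x, "scenario_to")$id, ": ",
      nrow(x), " cells; mean offset ", sprintf("%.4f", mean(x$offset)),
      "\n", sep = "")
  invisible(x)
}

#' Write an adaptedness surface to CSV
#' @param surface an [adaptedness_surface()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  write.csv(as.data.frame(surface), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Transform climate vectors into an engine's adaptive-composition space
#'
#' For vector-space engines (gradient forest, RDA) the offset between two
#' climate vectors is the Euclidean distance between their transforms. The
#' GDM engine has no such embedding; use [offset_between()] or
#' [pairwise_offset()] directly.
#'
#' @param model a fitted offset engine.
#' @param climate matrix/data frame of climate vectors (rows), variables
#'   matching the model.
#' @return Numeric matrix, one transformed row per input row.
#' @export
climate_transform <- function(model, climate) UseMethod("climate_transform")

#' Row-wise offsets between two aligned sets of climate vectors
#'
#' @param model a fitted offset engine.
#' @param clim_a,clim_b climate matrices with the same number of rows
#'   (`clim_a` plays "current", `clim_b` "future").
#' @return Non-negative numeric vector of offsets, one per row.
#' @export
offset_between <- function(model, clim_a, clim_b) UseMethod("offset_between")

#' @export
offset_between.default <- function(model, clim_a, clim_b) {
  ta <- climate_transform(model, clim_a)
  tb <- climate_transform(model, clim_b)
  sqrt(rowSums((ta - tb)^2))
}

#' Dense offsets between all donor/recipient climate-vector pairs
#'
#' @param model a fitted offset engine.
#' @param clim_a donor climate matrix (rows).
#' @param clim_b recipient climate matrix (rows).
#' @return Matrix of offsets, donors x recipients.
#' @export
pairwise_offset <- function(model, clim_a, clim_b) UseMethod("pairwise_offset")

#' @export
pairwise_offset.default <- function(model, clim_a, clim_b) {
  ta <- climate_transform(model, clim_a)
  tb <- climate_transform(model, clim_b)
  d2 <- outer(rowSums(ta^2), rowSums(tb^2), "+") - 2 * tcrossprod(ta, tb)
  sqrt(pmax(d2, 0))
}

check_grid_pair <- function(model, grid_now, grid_future) {
  if (!identical(grid_now$cells$cell_id, grid_future$cells$cell_id))
    abort_ctx("current and future grids must share cells")
  miss <- setdiff(model_variables(model), grid_now$variables)
  if (length(miss))
    abort_ctx("grid lacks model variables: ", paste(miss, collapse = ", "))
}

model_variables <- function(model) model$variables

# Clamp climate values to the model's training range, messaging the count
# (extrapolation beyond the fitted range is not meaningful for any engine).
clamp_to_train <- function(model, climate, quiet = FALSE) {
  m <- as.matrix(climate)[, model$variables, drop = FALSE]
  rng <- model$train_range
  n_clamped <- 0L
  for (v in colnames(m)) {
    below <- m[, v] < rng[1, v]; above <- m[, v] > rng[2, v]
    n_clamped <- n_clamped + sum(below) + sum(above)
    m[below, v] <- rng[1, v]; m[above, v] <- rng[2, v]
  }
  if (n_clamped > 0 && !quiet)
    message("clamped ", n_clamped,
            " climate values to the model's training range")
  m
}

#' Predict a genomic-offset / adaptedness surface
#'
#' Per cell, the engine's offset between the cell's current and future
#' climate; adaptedness is -1 x offset. Climate values outside the engine's
#' training range are clamped (with a message reporting the count).
#'
#' @param model a fitted offset engine (`gf_model`, `rda_offset_model` or
#'   `gdm_model`).
#' @param grid_now,grid_future [climate_grid()]s sharing cell geometry.
#' @return An [adaptedness_surface()].
#' @export
predict_offset <- function(model, grid_now, grid_future) {
  check_grid_pair(model, grid_now, grid_future)
  a <- clamp_to_train(model, grid_now$values, quiet = TRUE)
  b <- clamp_to_train(model, grid_future$values, quiet = TRUE)
  n_out <- sum(a != as.matrix(grid_now$values)[, model$variables]) +
    sum(b != as.matrix(grid_future$values)[, model$variables])
  if (n_out > 0)
    message("predict_offset: clamped ", n_out,
            " out-of-range climate values")
  off <- offset_between(model, a, b)
  adaptedness_surface(grid_now$cells, off, method = engine_tag(model),
                      scenario_from = grid_now$scenario,
                      scenario_to = grid_future$scenario)
}

engine_tag <- function(model) {
  switch(class(model)[1], gf_model = "gf", rda_offset_model = "rda",
         gdm_model = "gdm", class(model)[1])
}

#' Rank climate variables by engine importance
#'
#' Gradient forest: R-squared-weighted total cumulative importance; RDA:
#' eigenvalue-weighted squared climate coefficients over retained axes;
#' GDM: total spline-curve height (sum of I-spline coefficients). Ties are
#' broken alphabetically.
#'
#' @param model a fitted offset engine.
#' @return Named numeric vector of importances, sorted decreasing.
#' @export
variable_importance <- function(model) UseMethod("variable_importance")

sort_importance <- function(imp) {
  imp[order(-imp, names(imp))]
}
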