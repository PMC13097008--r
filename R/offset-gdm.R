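# Generalized dissimilarity modelling engine: pairwise genetic distance
# between sites regressed on I-spline-transformed climate differences under
# the link dissimilarity = 1 - exp(-eta), with non-negative coefficients so
# fitted turnover is monotone.

# --- monotone I-spline basis -------------------------------------------------
# Order-2 M-splines (piecewise linear, integrating to 1) on breakpoints
# (min, interior..., max) with doubled boundary knots; I-splines are their
# exact integrals (piecewise quadratic, non-decreasing, 0 at the lower
# boundary and 1 at the upper). With the default 3 knots each variable gets
# 3 basis functions.

mspline2_eval <- function(x, knots) {
  t <- c(knots[1], knots, knots[length(knots)])  # doubled boundary knots
  L <- length(t)
  n1 <- L - 1
  top <- t[L]
  M1 <- vapply(seq_len(n1), function(i) {
    den <- t[i + 1] - t[i]
    if (den <= 0) return(rep(0, length(x)))
    inb <- (x >= t[i] & x < t[i + 1]) | (t[i + 1] == top & x == top)
    ifelse(inb, 1 / den, 0)
  }, numeric(length(x)))
  M1 <- matrix(M1, nrow = length(x))
  n2 <- L - 2
  M2 <- vapply(seq_len(n2), function(i) {
    den <- t[i + 2] - t[i]
    if (den <= 0) return(rep(0, length(x)))
    2 * ((x - t[i]) * M1[, i] + (t[i + 2] - x) * M1[, i + 1]) / den
  }, numeric(length(x)))
  matrix(M2, nrow = length(x))
}

#' Evaluate a monotone I-spline basis
#'
#' Each basis function is non-decreasing, 0 at or below the first knot and 1
#' at or above the last; inputs are clamped to the knot range. With `k`
#' knots there are `k` basis functions.
#'
#' @param x numeric vector of evaluation points.
#' @param knots sorted breakpoints (length >= 2), typically
#'   min/median/max of the variable's distribution.
#' @return Matrix, `length(x)` rows x `length(knots)` basis columns.
#' @export
ispline_basis <- function(x, knots) {
  knots <- sort(knots)
  if (length(unique(knots)) < 2) abort_ctx("ispline_basis: knots must span a range")
  a <- knots[1]; c_ <- knots[length(knots)]
  x <- pmin(pmax(x, a), c_)
  # exact integration of the piecewise-linear M-splines: trapezoid over
  # complete knot intervals plus an exact partial trapezoid to x
  brk <- unique(knots)
  Mb <- mspline2_eval(brk, knots)           # M at interval boundaries
  n_basis <- ncol(Mb)
  # cumulative integral at each breakpoint
  widths <- diff(brk)
  cum <- rbind(0, apply((Mb[-nrow(Mb), , drop = FALSE] +
                           Mb[-1, , drop = FALSE]) / 2 * widths, 2, cumsum))
  j <- pmin(pmax(findInterval(x, brk), 1L), length(brk) - 1L)
  Mx <- mspline2_eval(x, knots)
  Ml <- Mb[j, , drop = FALSE]
  out <- cum[j, , drop = FALSE] + (Ml + Mx) / 2 * (x - brk[j])
  # normalize: M-splines integrate to 1 over the support by construction,
  # but guard against round-off at the top
  pmin(pmax(out, 0), 1)
}

build_gdm_design <- function(site_basis, pairs) {
  # |f(v_i) - f(v_j)| for every basis column
  abs(site_basis[pairs[, 1], , drop = FALSE] -
        site_basis[pairs[, 2], , drop = FALSE])
}

site_basis_matrix <- function(climate, knots_list) {
  cols <- lapply(names(knots_list), function(v)
    ispline_basis(climate[, v], knots_list[[v]]))
  out <- do.call(cbind, cols)
  colnames(out) <- unlist(lapply(names(knots_list), function(v)
    paste0(v, ".s", seq_along(knots_list[[v]]))))
  out
}

#' Fit a generalized dissimilarity model on site allele frequencies
#'
#' Response: pairwise Euclidean genetic distance between sites on
#' candidate-locus allele frequencies, rescaled to `[0, 1)`. Predictors:
#' per-variable I-spline basis differences summed into the linear predictor
#' `eta`, fitted with intercept and non-negative spline coefficients by
#' iteratively reweighted non-negative least squares under the link
#' `dissimilarity = 1 - exp(-eta)`.
#'
#' @param site_allele_freqs sites x loci matrix of allele frequencies.
#' @param site_climate sites x variables climate table (raw scale).
#' @param n_knots knots per variable (default 3: min/median/max).
#' @param knots optional named list of knot vectors per variable (e.g.
#'   quantiles of the recent grid) overriding `n_knots`.
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @return Object of class `gdm_model`: `intercept` (>= 0), `coef`
#'   (non-negative I-spline coefficients, basis x variable), `knots`,
#'   `deviance_explained`, `deviance_trace`, `variables`, `train_range`,
#'   `y_scale`.
#' @export
fit_gdm <- function(site_allele_freqs, site_climate, n_knots = 3,
                    knots = NULL, max_iter = 50, tol = 1e-9) {
  Fq <- as.matrix(site_allele_freqs)
  X <- as.matrix(site_climate)
  if (nrow(Fq) < 4) abort_ctx("fit_gdm: need at least 4 sites")
  if (nrow(Fq) != nrow(X)) abort_ctx("site frequencies and climate must align")
  vars <- colnames(X)
  if (is.null(knots)) {
    knots <- lapply(vars, function(v)
      unname(quantile(X[, v], probs = seq(0, 1, length.out = n_knots))))
    names(knots) <- vars
  }
  if (length(unique(lengths(knots))) != 1)
    abort_ctx("fit_gdm: all variables must use the same number of knots")
  d <- as.matrix(dist(Fq))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  y_raw <- d[upper.tri(d)]
  if (max(y_raw) <= 0) abort_ctx("fit_gdm: all site frequency vectors identical")
  y_scale <- max(y_raw) * (1 + 1e-6)
  fit <- fit_gdm_on_dissim(y_raw / y_scale, pairs, X, knots,
                           max_iter = max_iter, tol = tol)
  fit$y_scale <- y_scale
  fit
}

# IRLS core: fit intercept and non-negative I-spline coefficients to
# pairwise dissimilarities in [0, 1) under the 1 - exp(-eta) link.
fit_gdm_on_dissim <- function(y, pairs, site_climate, knots,
                              max_iter = 50, tol = 1e-9) {
  X <- as.matrix(site_climate)
  vars <- colnames(X)
  sb <- site_basis_matrix(X, knots)
  D <- cbind(intercept = 1, build_gdm_design(sb, pairs))

  beta <- rep(0, ncol(D))
  eta <- as.numeric(D %*% beta)
  dev_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- 1 - exp(-eta)
    deriv <- exp(-eta)
    z <- eta + (y - mu) / deriv
    w <- deriv
    fit <- pracma::lsqnonneg(D * w, z * w)
    beta_new <- fit$x
    eta <- as.numeric(D %*% beta_new)
    dev <- sum((y - (1 - exp(-eta)))^2)
    dev_trace <- c(dev_trace, dev)
    if (it > 1 && abs(dev_trace[it - 1] - dev) <=
        tol * max(dev_trace[it - 1], 1e-12)) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  if (!converged)
    abort_ctx("fit_gdm: IRLS did not converge in ", max_iter,
              " iterations; deviance trace: ",
              paste(sprintf("%.3g", dev_trace), collapse = ", "))
  coef_mat <- matrix(beta[-1], ncol = length(vars),
                     dimnames = list(paste0("s", seq_len(length(knots[[1]]))),
                                     vars))
  tss <- sum((y - mean(y))^2)
  structure(list(intercept = beta[1], coef = coef_mat, knots = knots,
                 deviance_explained = 1 - dev_trace[length(dev_trace)] / tss,
                 deviance_trace = dev_trace, variables = vars,
                 train_range = apply(X, 2, range), y_scale = 1,
                 link = "1 - exp(-eta)"),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat("gdm_model:", length(x$variables), "variables,",
      nrow(x$coef), "I-splines each; deviance explained",
      sprintf("%.1f%%", 100 * x$deviance_explained), "\n")
  invisible(x)
}

# eta between two aligned climate matrices (spline terms only: the intercept
# is a between-site sampling effect and is excluded from the within-cell
# current -> future prediction so that offset(current, current) = 0)
gdm_eta <- function(model, clim_a, clim_b) {
  a <- site_basis_matrix(as.matrix(clim_a)[, model$variables, drop = FALSE],
                         model$knots)
  b <- site_basis_matrix(as.matrix(clim_b)[, model$variables, drop = FALSE],
                         model$knots)
  coefs <- as.numeric(model$coef)
  as.numeric(abs(a - b) %*% coefs)
}

#' Predict GDM dissimilarity between paired climate vectors
#'
#' @param model a `gdm_model`.
#' @param clim_a,clim_b climate matrices with aligned rows.
#' @return Predicted dissimilarities in `[0, 1)`, one per row.
#' @export
predict_gdm_dissimilarity <- function(model, clim_a, clim_b) {
  1 - exp(-gdm_eta(model, clim_a, clim_b))
}

#' @export
offset_between.gdm_model <- function(model, clim_a, clim_b) {
  predict_gdm_dissimilarity(model, clim_a, clim_b)
}

#' @export
climate_transform.gdm_model <- function(model, climate) {
  abort_ctx("the GDM engine has no vector-space transform; use offset_between()")
}

#' @export
pairwise_offset.gdm_model <- function(model, clim_a, clim_b) {
  a <- site_basis_matrix(as.matrix(clim_a)[, model$variables, drop = FALSE],
                         model$knots)
  b <- site_basis_matrix(as.matrix(clim_b)[, model$variables, drop = FALSE],
                         model$knots)
  coefs <- as.numeric(model$coef)
  eta <- matrix(0, nrow(a), nrow(b))
  for (q in seq_along(coefs)) {
    if (coefs[q] == 0) next
    eta <- eta + coefs[q] * abs(outer(a[, q], b[, q], "-"))
  }
  1 - exp(-eta)
}

#' GDM offset surface between two scenarios
#'
#' Per cell, the predicted dissimilarity between the cell's current and
#' future climate vectors (spline terms only); adaptedness is -1 x offset.
#'
#' @param model a `gdm_model`.
#' @param grid_now,grid_future [climate_grid()]s sharing cells.
#' @return An [adaptedness_surface()].
#' @export
offset_gdm <- function(model, grid_now, grid_future) {
  stopifnot(inherits(model, "gdm_model"))
  predict_offset(model, grid_now, grid_future)
}

#' @export
variable_importance.gdm_model <- function(model) {
  sort_importance(colSums(model$coef))
}

#' Site allele frequencies from a genotype matrix
#'
#' @param gm a [genotype_matrix()] (missing dosages allowed; frequencies use
#'   non-missing genotypes).
#' @param loci optional locus ids to restrict to (e.g. candidate adaptive
#'   loci).
#' @return Matrix of alternate-allele frequencies, sites x loci.
#' @export
site_allele_freqs <- function(gm, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  dos <- gm$dosages
  if (!is.null(loci)) dos <- dos[, loci, drop = FALSE]
  sites <- gm$samples$site
  if (all(is.na(sites))) abort_ctx("samples carry no site labels")
  out <- do.call(rbind, lapply(split(seq_len(nrow(dos)), sites), function(idx)
    colMeans(dos[idx, , drop = FALSE], na.rm = TRUE) / 2))
  out
}
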