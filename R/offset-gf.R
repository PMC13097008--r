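# Gradient-forest offset engine: per-locus regression forests of allele
# dosage on climate; split impurity reductions are aggregated across loci
# (weighted by out-of-bag R-squared), binned along each variable,
# density-standardized, and accumulated into monotone cumulative-importance
# turnover curves that map climate into adaptive-composition space.

# Walk one randomForest regression tree with its in-bag sample and record,
# for every split, (variable, split value, impurity reduction). Impurity is
# the in-bag weighted sum of squared deviations.
tree_split_improvements <- function(tree, x, y, inbag_w) {
  use <- which(inbag_w > 0)
  n_nodes <- nrow(tree)
  out_var <- integer(0); out_point <- numeric(0); out_imp <- numeric(0)
  node_members <- vector("list", n_nodes)
  node_members[[1]] <- use
  stack <- 1L
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    v <- tree[nd, 3L]
    if (v == 0L) next  # terminal
    idx <- node_members[[nd]]
    if (length(idx) == 0) next
    w <- inbag_w[idx]; yy <- y[idx]
    sp <- tree[nd, 4L]
    left <- x[idx, v] <= sp
    sse <- function(yv, wv) {
      if (!length(yv) || sum(wv) == 0) return(0)
      mu <- sum(wv * yv) / sum(wv)
      sum(wv * (yv - mu)^2)
    }
    imp <- sse(yy, w) - sse(yy[left], w[left]) - sse(yy[!left], w[!left])
    if (imp > 0) {
      out_var <- c(out_var, v)
      out_point <- c(out_point, sp)
      out_imp <- c(out_imp, imp)
    }
    l <- tree[nd, 1L]; r <- tree[nd, 2L]
    node_members[[l]] <- idx[left]
    node_members[[r]] <- idx[!left]
    node_members[nd] <- list(NULL)  # release without shifting indices
    stack <- c(stack, l, r)
  }
  list(var = out_var, point = out_point, imp = out_imp)
}

#' Fit a gradient-forest turnover model
#'
#' For each locus a regression forest of allele value on climate is grown;
#' every split's impurity reduction is recorded against the split variable
#' and split value. Loci are weighted by their out-of-bag R-squared (floored
#' at zero; loci with no predictive power are excluded). Split importances
#' are binned along each variable's observed range, standardized by the
#' density of observed values (with a small floor), rescaled to conserve
#' total importance, and accumulated into a non-decreasing
#' cumulative-importance curve per variable.
#'
#' @param allele_data samples x loci matrix of dosages (or site allele
#'   frequencies), loci named; or a [genotype_matrix()].
#' @param climate_at_samples samples x variables climate table (at least 2
#'   variables, 10 samples).
#' @param n_trees trees per locus forest (default 500).
#' @param mtry variables tried per split; default `max(floor(p/3), 1)`.
#' @param seed optional integer seed.
#' @param nodesize minimum terminal-node size of the forests; the default
#'   `max(5, n/12)` keeps trees shallow enough that splits reflect the
#'   climate signal rather than residual binomial sampling noise of the
#'   0/1/2 dosage response.
#' @param n_bins bins per variable for the turnover curves (default 101).
#' @param density_floor floor on the data density used in standardization.
#' @return Object of class `gf_model`: `curves` (per variable: `breaks`,
#'   `cum_importance`), `importance`, `locus_r2`, `retained_loci`,
#'   `variables`, `train_range`, `params`.
#' @export
fit_gradient_forest <- function(allele_data, climate_at_samples,
                                n_trees = 500, mtry = NULL, seed = NULL,
                                nodesize = NULL, n_bins = 101,
                                density_floor = 1e-6) {
  Y <- if (inherits(allele_data, "genotype_matrix")) allele_data$dosages
       else as.matrix(allele_data)
  X <- as.matrix(climate_at_samples)
  if (ncol(X) < 2) abort_ctx("fit_gradient_forest: need at least 2 climate variables")
  if (nrow(X) < 10) abort_ctx("fit_gradient_forest: need at least 10 samples")
  if (nrow(Y) != nrow(X)) abort_ctx("allele data and climate rows must align")
  if (anyNA(Y)) abort_ctx("fit_gradient_forest: impute missing dosages first")
  vars <- colnames(X)
  loci <- colnames(Y) %||% paste0("locus", seq_len(ncol(Y)))
  mtry <- mtry %||% max(floor(ncol(X) / 3), 1)
  nodesize <- nodesize %||% max(5, round(nrow(X) / 12))

  with_seed(seed, {
    r2 <- setNames(numeric(ncol(Y)), loci)
    splits <- list(var = integer(0), point = numeric(0), w_imp = numeric(0))
    for (j in seq_len(ncol(Y))) {
      yj <- as.numeric(Y[, j])
      if (var(yj) == 0) next
      rf <- randomForest::randomForest(x = X, y = yj, ntree = n_trees,
                                       mtry = mtry, nodesize = nodesize,
                                       keep.inbag = TRUE)
      r2[j] <- rf$rsq[n_trees]
      if (r2[j] <= 0) next
      sv <- integer(0); sp <- numeric(0); si <- numeric(0)
      for (k in seq_len(n_trees)) {
        tr <- randomForest::getTree(rf, k, labelVar = FALSE)
        s <- tree_split_improvements(tr, X, yj, rf$inbag[, k])
        sv <- c(sv, s$var); sp <- c(sp, s$point); si <- c(si, s$imp)
      }
      tot <- sum(si)
      if (tot <= 0) next
      # distribute the locus's OOB R-squared across its splits
      splits$var <- c(splits$var, sv)
      splits$point <- c(splits$point, sp)
      splits$w_imp <- c(splits$w_imp, r2[j] * si / tot)
    }
    retained <- loci[r2 > 0]
    if (length(retained) == 0)
      abort_ctx("fit_gradient_forest: no predictive loci (all out-of-bag R-squared <= 0)")

    curves <- list()
    importance <- setNames(numeric(length(vars)), vars)
    for (vi in seq_along(vars)) {
      v <- vars[vi]
      rng <- range(X[, v])
      breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
      sel <- splits$var == vi
      imp_b <- numeric(n_bins)
      if (any(sel)) {
        b <- findInterval(splits$point[sel], breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
        imp_b <- vapply(seq_len(n_bins), function(i)
          sum(splits$w_imp[sel][b == i]), 0)
      }
      dens <- tabulate(findInterval(X[, v], breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE), n_bins) / nrow(X)
      std <- imp_b / pmax(dens, density_floor)
      if (sum(std) > 0) std <- std * sum(imp_b) / sum(std)
      curves[[v]] <- list(breaks = breaks, cum_importance = cumsum(std))
      importance[v] <- sum(imp_b)
    }
    structure(list(curves = curves, importance = importance,
                   locus_r2 = r2, retained_loci = retained,
                   variables = vars,
                   train_range = apply(X, 2, range),
                   params = list(n_trees = n_trees, mtry = mtry,
                                 nodesize = nodesize, n_bins = n_bins,
                                 density_floor = density_floor, seed = seed)),
              class = "gf_model")
  })
}

#' @export
print.gf_model <- function(x, ...) {
  cat("gf_model:", length(x$retained_loci), "predictive loci of",
      length(x$locus_r2), ";", x$params$n_trees, "trees/locus\n")
  cat("importance:", paste(sprintf("%s=%.3g", names(sort_importance(x$importance)),
                                   sort_importance(x$importance)), collapse = " "), "\n")
  invisible(x)
}

# Evaluate one cumulative-importance step curve: zero at or below the
# variable's minimum, saturating at the curve total above the maximum; a
# value interior to bin i returns the importance accumulated through bin i.
eval_gf_curve <- function(curve, x) {
  n_bins <- length(curve$cum_importance)
  j <- findInterval(x, curve$breaks, left.open = TRUE)
  j <- pmin(pmax(j, 0L), n_bins)
  c(0, curve$cum_importance)[j + 1L]
}

#' Transform climate vectors with fitted gradient-forest turnover curves
#'
#' Component `v` of the transform is variable `v`'s cumulative-importance
#' curve evaluated at the input value; inputs beyond the fitted range clamp
#' to the curve's end values.
#'
#' @param model a `gf_model`.
#' @param climate matrix/data frame of climate vectors.
#' @return Matrix, rows transformed, one column per variable.
#' @export
gf_transform <- function(model, climate) climate_transform(model, climate)

#' @export
climate_transform.gf_model <- function(model, climate) {
  m <- as.matrix(climate)[, model$variables, drop = FALSE]
  out <- vapply(model$variables,
                function(v) eval_gf_curve(model$curves[[v]], m[, v]),
                numeric(nrow(m)))
  matrix(out, nrow = nrow(m), dimnames = list(rownames(m), model$variables))
}

#' Gradient-forest offset surface between two scenarios
#'
#' Per cell, the Euclidean distance between the turnover-transformed current
#' and future climate vectors; adaptedness is -1 x offset.
#'
#' @param model a `gf_model`.
#' @param grid_now,grid_future [climate_grid()]s sharing cells.
#' @return An [adaptedness_surface()].
#' @export
offset_gf <- function(model, grid_now, grid_future) {
  stopifnot(inherits(model, "gf_model"))
  predict_offset(model, grid_now, grid_future)
}

#' @export
variable_importance.gf_model <- function(model) sort_importance(model$importance)
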