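# Cross-method concordance: Procrustes superimposition of PCA-reduced
# method configurations, Spearman rank correlations between offset maps,
# and the protection-status nested ANOVA with Tukey HSD.

#' Procrustes residuals between two method configurations
#'
#' Centers, scales and optimally rotates `configB` onto `configA`
#' (orthogonal Procrustes via SVD, symmetric scaling) and returns the
#' per-cell residual distances after superimposition, with an optional
#' permutation test of the fit.
#'
#' @param configA,configB cells x k coordinate matrices over the same cells.
#' @param n_perm permutations for the significance test (default 999; 0
#'   skips the test).
#' @param seed optional integer seed.
#' @return Object of class `procrustes_result`: `residuals` (per cell, >=
#'   0), `ss` (sum of squared residuals), `correlation`
#'   (correlation-in-configuration statistic), `p_value`, `rotation`,
#'   `scale`.
#' @export
procrustes_residuals <- function(configA, configB, n_perm = 999, seed = NULL) {
  A <- as.matrix(configA); B <- as.matrix(configB)
  if (ncol(A) == 0 || ncol(B) == 0) abort_ctx("empty configuration")
  if (nrow(A) != nrow(B)) abort_ctx("configurations must share cells")
  pr <- vegan::procrustes(A, B, symmetric = TRUE)
  res <- sqrt(rowSums((pr$Yrot - pr$X)^2))
  p <- NA_real_; corr <- sqrt(max(0, 1 - pr$ss))
  if (n_perm > 0) {
    pt <- with_seed(seed, vegan::protest(A, B, permutations = n_perm))
    p <- pt$signif; corr <- pt$t0
  }
  structure(list(residuals = res, ss = pr$ss, correlation = corr,
                 p_value = p, rotation = pr$rotation, scale = pr$scale),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat("procrustes_result: ss =", sprintf("%.4g", x$ss),
      "correlation =", sprintf("%.4f", x$correlation),
      if (!is.na(x$p_value)) paste("p =", format(x$p_value)) else "", "\n")
  invisible(x)
}

#' Reduce a method's transformed grid to a k-dimensional configuration
#'
#' Principal-component reduction of a cells x m matrix (a turnover-space
#' transform or dissimilarity embedding) to `k` components, prior to
#' Procrustes comparison.
#'
#' @param mat cells x m numeric matrix.
#' @param k components to keep (default 3, capped at the matrix rank).
#' @return Matrix of cells x k scores; attribute `"variance_retained"`
#'   carries the retained variance fraction.
#' @export
reduce_for_procrustes <- function(mat, k = 3) {
  mat <- as.matrix(mat)
  p <- prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(p$x))
  out <- p$x[, seq_len(k), drop = FALSE]
  attr(out, "variance_retained") <-
    sum(p$sdev[seq_len(k)]^2) / sum(p$sdev^2)
  out
}

#' A method's spatial configuration for Procrustes comparison
#'
#' Gradient forest and RDA: PCA-reduced turnover transform of the grid's
#' climate. GDM: classical-scaling embedding of the predicted pairwise
#' dissimilarities among cells (subsampled when the grid is large).
#'
#' @param model a fitted offset engine.
#' @param grid a [climate_grid()] (current scenario).
#' @param k configuration dimensions (default 3).
#' @param max_cells cap on cells used for the GDM embedding (default 400).
#' @param seed optional seed for the subsample.
#' @return Cells x k configuration matrix (row names are cell ids; for GDM
#'   a subsample, whose ids are in the row names).
#' @export
method_configuration <- function(model, grid, k = 3, max_cells = 400,
                                 seed = NULL) {
  if (inherits(model, "gdm_model")) {
    ids <- grid$cells$cell_id
    if (length(ids) > max_cells)
      ids <- with_seed(seed, sort(sample(ids, max_cells)))
    g <- subset_grid(grid, ids)
    dmat <- pairwise_offset(model, g$values, g$values)
    emb <- cmdscale(as.dist((dmat + t(dmat)) / 2), k = k)
    rownames(emb) <- ids
    emb
  } else {
    tr <- climate_transform(model, clamp_to_train(model, grid$values,
                                                  quiet = TRUE))
    out <- reduce_for_procrustes(tr, k)
    rownames(out) <- grid$cells$cell_id
    out
  }
}

#' Pairwise Spearman rank correlations between offset maps
#'
#' @param maps named list of per-cell offset (or adaptedness) vectors over
#'   the same cells, or [adaptedness_surface()]s.
#' @return Symmetric matrix of Spearman rho with unit diagonal.
#' @export
spearman_table <- function(maps) {
  vecs <- lapply(maps, function(m)
    if (inherits(m, "adaptedness_surface")) setNames(m$offset, m$cell_id)
    else m)
  ids <- names(vecs[[1]])
  if (!is.null(ids)) {
    for (v in vecs) if (!identical(names(v), ids))
      abort_ctx("spearman_table: maps must share cells (and order)")
  }
  n <- lengths(vecs)
  if (length(unique(n)) != 1) abort_ctx("spearman_table: maps differ in length")
  cor(do.call(cbind, vecs), method = "spearman")
}

#' Nested ANOVA of adaptedness on land-protection status
#'
#' Fixed-effects ANOVA `adaptedness ~ protection * model / rcp / year` (the
#' nesting expands to model, model:rcp, model:rcp:year and their protection
#' interactions), followed by Tukey's HSD with studentized-range
#' adjustment. Grid cells are treated as independent observations.
#'
#' @param values data frame with numeric `adaptedness` and factors
#'   `protection` (protected/unprotected), `model`, `rcp`, `year`.
#' @param tukey_which terms to run Tukey HSD on (default: the protection
#'   main effect and the full nested interaction).
#' @return Object of class `anova_table`: `table` (data frame of df, sum of
#'   squares, F, p per term), `tukey`, `fit`.
#' @export
protection_anova <- function(values,
                             tukey_which = c("protection",
                                             "protection:model:rcp:year")) {
  needed <- c("adaptedness", "protection", "model", "rcp", "year")
  if (!all(needed %in% names(values)))
    abort_ctx("values must have columns ", paste(needed, collapse = ", "))
  for (f in needed[-1]) {
    values[[f]] <- factor(values[[f]])
    if (nlevels(values[[f]]) < 2 && f %in% c("protection"))
      abort_ctx("factor '", f, "' needs at least 2 levels")
  }
  empty <- with(values, table(protection, model, rcp, year)) == 0
  if (any(empty))
    abort_ctx("empty factor cell(s) in protection x model x rcp x year design")
  fit <- aov(adaptedness ~ protection * model / rcp / year, data = values)
  tab <- as.data.frame(summary(fit)[[1]])
  tab <- cbind(term = trimws(rownames(tab)), tab)
  rownames(tab) <- NULL
  tukey_which <- intersect(tukey_which, attr(fit$terms, "term.labels"))
  tk <- tryCatch(TukeyHSD(fit, which = tukey_which),
                 error = function(e) NULL)
  structure(list(table = tab, tukey = tk, fit = fit),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("anova_table (adaptedness ~ protection * model/rcp/year):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write an ANOVA (or any) table as TSV
#' @param tab data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
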