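# Population-structure diagnostics and genotype-environment association:
# dosage PCA, Haversine distances, (partial) Mantel tests, RDA with
# conditioning, variance partitioning, and pRDA outlier detection with
# genomic-inflation-factor calibration.

#' Principal components analysis of a dosage matrix
#'
#' Column-centered PCA of imputed dosages; axes ordered by variance.
#'
#' @param x a [genotype_matrix()] without missing dosages, or a plain numeric
#'   matrix (individuals x loci).
#' @param n_axes number of axes to retain in the output (default all).
#' @return Object of class `pca_result`: `scores`, `explained_fraction`,
#'   `loadings`.
#' @export
pca_genotypes <- function(x, n_axes = NULL) {
  Y <- if (inherits(x, "genotype_matrix")) x$dosages else as.matrix(x)
  if (anyNA(Y)) abort_ctx("pca_genotypes: missing dosages; impute first")
  p <- prcomp(Y, center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_axes %||% length(expl), length(expl))
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 explained_fraction = expl[seq_len(k)],
                 loadings = p$rotation[, seq_len(k), drop = FALSE]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "individuals,", ncol(x$scores), "axes;",
      "PC1-3 explain", paste(sprintf("%.2f%%",
        100 * head(x$explained_fraction, 3)), collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise great-circle distances between sample points
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords data frame with `lon`, `lat` in degrees (and optionally
#'   `sample_id`/`id` used as dimnames), or a two-column lon/lat matrix.
#' @return Symmetric matrix of distances in km, zero diagonal.
#' @export
haversine_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    ids <- coords[["sample_id"]] %||% coords[["id"]]
    m <- as.matrix(coords[, c("lon", "lat")])
  } else {
    ids <- rownames(coords)
    m <- as.matrix(coords)
  }
  d <- geosphere::distm(m, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(d) <- list(ids, ids)
  d
}

as_square <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    abort_ctx("expected a square symmetric distance matrix")
  m
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of lower triangles; one-sided permutation p-value
#' (`p = (count(r_perm >= r) + 1) / (n_perm + 1)`) by row/column shuffling of
#' one matrix.
#'
#' @param dA,dB square symmetric distance matrices of equal size.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return Object of class `mantel_result`: `statistic`, `n_perm`,
#'   `p_value`, `partial`.
#' @export
mantel_test <- function(dA, dB, n_perm = 999, seed = NULL) {
  dA <- as_square(dA); dB <- as_square(dB)
  stopifnot(all(dim(dA) == dim(dB)))
  res <- with_seed(seed, vegan::mantel(as.dist(dA), as.dist(dB),
                                       permutations = n_perm))
  structure(list(statistic = unname(res$statistic), n_perm = n_perm,
                 p_value = res$signif, partial = FALSE),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation of the lower triangles of `dA` and `dB` after each is
#' regressed on that of `dC`; a degenerate (constant) conditioning matrix
#' reduces the statistic to the simple Mantel correlation, and a residual
#' with zero variance (one matrix fully explained by `dC`) gives statistic
#' 0. Significance by row/column permutation of `dA`, residualizing anew
#' each time; one-sided as in [mantel_test()].
#'
#' @inheritParams mantel_test
#' @param dC conditioning distance matrix.
#' @return Object of class `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel_test <- function(dA, dB, dC, n_perm = 999, seed = NULL) {
  dA <- as_square(dA); dB <- as_square(dB); dC <- as_square(dC)
  stopifnot(all(dim(dA) == dim(dB)), all(dim(dA) == dim(dC)))
  lower <- lower.tri(dA)
  c_vec <- dC[lower]
  res_on <- function(x) {
    if (sd(c_vec) == 0) return(x - mean(x))
    b <- cov(x, c_vec) / var(c_vec)
    x - mean(x) - b * (c_vec - mean(c_vec))
  }
  rb <- res_on(dB[lower])
  pcor <- function(avec) {
    ra <- res_on(avec)
    if (sd(ra) == 0 || sd(rb) == 0) return(0)
    cor(ra, rb)
  }
  obs <- pcor(dA[lower])
  p <- with_seed(seed, {
    count <- 0
    n <- nrow(dA)
    for (b in seq_len(n_perm)) {
      pe <- sample(n)
      count <- count + (pcor(dA[pe, pe][lower]) >= obs - 1e-12)
    }
    (count + 1) / (n_perm + 1)
  })
  structure(list(statistic = obs, n_perm = n_perm, p_value = p,
                 partial = TRUE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(if (x$partial) "partial " else "", "mantel: r = ",
      sprintf("%.4f", x$statistic), ", p = ", format(x$p_value),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Redundancy analysis with optional conditioning (partial RDA)
#'
#' Column-centers the response, optionally residualizes response and
#' predictors on the conditioning matrix, and decomposes the fitted values of
#' the multivariate least-squares regression by SVD. Eigenvalues are
#' non-negative and non-increasing; with an empty conditioning matrix this is
#' a plain RDA.
#'
#' @param Y response matrix (individuals x loci), no missing values.
#' @param X predictor matrix (individuals x predictors).
#' @param Z optional conditioning matrix.
#' @return Object of class `rda_result`: `eig` (constrained eigenvalues),
#'   `loadings` (loci x axes), `site_scores` (constrained axis scores),
#'   `coef` (predictor coefficients per axis), `inertia` (total,
#'   conditioned, constrained, unconstrained), plus internals used by the
#'   permutation machinery.
#' @export
rda_fit <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (anyNA(Y) || anyNA(X)) abort_ctx("rda_fit: missing values not allowed")
  if (nrow(Y) != nrow(X)) abort_ctx("rda_fit: Y and X rows must align")
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  total <- sum(Yc^2) / (n - 1)
  conditioned <- 0
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != n) abort_ctx("rda_fit: Z rows must align")
    Zc <- scale(Z, center = TRUE, scale = FALSE)
    qz <- qr(Zc)
    Yres <- qr.resid(qz, Yc)
    Xres <- qr.resid(qz, Xc)
    conditioned <- (sum(Yc^2) - sum(Yres^2)) / (n - 1)
  } else {
    Yres <- Yc; Xres <- Xc
  }
  # orthonormal basis of the residualized predictor space; directions that
  # survive conditioning only as numerical noise are discarded
  sx <- svd(Xres)
  tol <- max(svd(Xc, nu = 0, nv = 0)$d[1], 1) * 1e-9
  r <- sum(sx$d > tol)
  if (r == 0) {
    return(structure(list(eig = numeric(0), loadings = NULL,
                          site_scores = NULL, coef = NULL,
                          inertia = list(total = total,
                                         conditioned = conditioned,
                                         constrained = 0,
                                         unconstrained = sum(Yres^2) / (n - 1)),
                          Q = matrix(0, n, 0), Yres = Yres),
                     class = "rda_result"))
  }
  Q <- sx$u[, seq_len(r), drop = FALSE]
  proj <- crossprod(Q, Yres)
  fitted <- Q %*% proj
  sv <- svd(fitted)
  eig <- sv$d^2 / (n - 1)
  keep <- eig > max(eig[1], .Machine$double.eps) * 1e-9
  if (!any(keep)) keep <- 1
  eig <- eig[keep]
  V <- sv$v[, keep, drop = FALSE]
  rownames(V) <- colnames(Y)
  site_scores <- fitted %*% V
  # predictor coefficients per axis: axis score = Xres_centered %*% coef
  B <- sx$v[, seq_len(r), drop = FALSE] %*% (proj / sx$d[seq_len(r)])
  C <- B %*% V
  rownames(C) <- colnames(X)
  colnames(C) <- colnames(V) <- colnames(site_scores) <-
    paste0("RDA", seq_along(eig))
  structure(list(eig = eig, loadings = V, site_scores = site_scores,
                 coef = C,
                 inertia = list(total = total, conditioned = conditioned,
                                constrained = sum(eig),
                                unconstrained = sum(Yres^2) / (n - 1) - sum(eig)),
                 centers = list(X = attr(Xc, "scaled:center")),
                 Q = Q, Yres = Yres),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat("rda_result:", length(x$eig), "constrained axes; proportions",
      paste(sprintf("%.3f", x$eig / x$inertia$total), collapse = ", "), "\n")
  invisible(x)
}

# Sequential (forward) permutation test of constrained eigenvalues. Axis k
# is tested after removing the previously established constrained axes from
# the residualized response: its observed leading eigenvalue is compared
# with leading eigenvalues of row-permuted copies of that remainder.
# Testing stops at the first non-significant axis.
rda_axis_test <- function(fit, n_perm = 250, seed = NULL, loci_subset = NULL,
                          alpha = 0.05) {
  Ys <- fit$Yres
  if (!is.null(loci_subset)) Ys <- Ys[, loci_subset, drop = FALSE]
  n <- nrow(Ys)
  Q <- fit$Q
  k_max <- min(ncol(Q), ncol(Ys), n - 1)
  if (k_max == 0) return(list(eig = numeric(0), p = numeric(0)))
  with_seed(seed, {
    p <- rep(NA_real_, k_max)
    eig <- rep(NA_real_, k_max)
    M <- Ys
    for (k in seq_len(k_max)) {
      sv <- svd(crossprod(Q, M), nu = 0)
      eig[k] <- sv$d[1]^2 / (n - 1)
      count <- 0
      for (b in seq_len(n_perm)) {
        d1 <- svd(crossprod(Q, M[sample(n), , drop = FALSE]),
                  nu = 0, nv = 0)$d[1]
        count <- count + (d1^2 / (n - 1) >= eig[k] - 1e-12)
      }
      p[k] <- (count + 1) / (n_perm + 1)
      if (p[k] >= alpha) break
      # remove the established axis from the remainder
      v1 <- sv$v[, 1]
      M <- M - (M %*% v1) %*% t(v1)
    }
    list(eig = eig, p = p)
  })
}

# Deterministic robust squared Mahalanobis distances: iteratively trimmed
# covariance (keep the `trim` fraction with smallest distances), with the
# multivariate-normal consistency factor so the distances are chi-squared
# calibrated when there are no outliers. Quantile-based, hence invariant to
# row order and free of RNG.
trimmed_mahalanobis <- function(V, trim = 0.75, iters = 3) {
  V <- as.matrix(V)
  K <- ncol(V)
  ctr <- apply(V, 2, median)
  sc <- apply(V, 2, mad)
  sc[sc == 0] <- apply(V, 2, sd)[sc == 0]
  d2 <- rowSums(sweep(sweep(V, 2, ctr), 2, sc, "/")^2)
  kappa <- pchisq(qchisq(trim, K), K + 2) / trim
  for (it in seq_len(iters)) {
    keep <- d2 <= quantile(d2, trim)
    mu <- colMeans(V[keep, , drop = FALSE])
    S <- cov(V[keep, , drop = FALSE]) / kappa
    d2 <- stats::mahalanobis(V, mu, S)
  }
  d2
}

#' Build the geography predictor matrix
#'
#' Latitude, longitude, and their product, with coordinates standardized
#' before the product is taken.
#'
#' @param coords data frame with `lon`, `lat`.
#' @return Matrix with columns `lat`, `lon`, `latxlon`.
#' @export
geography_matrix <- function(coords) {
  lat <- as.numeric(scale(coords$lat))
  lon <- as.numeric(scale(coords$lon))
  cbind(lat = lat, lon = lon, latxlon = lat * lon)
}

#' Partition genomic variance among climate, geography and structure
#'
#' Fits the full constrained model plus the three partial RDAs each
#' conditioned on the other two factors, and reports the fraction of total
#' genomic variance explained uniquely by each factor, their confounded
#' (joint) fraction, and the unexplained remainder, with permutation
#' p-values on each partial model's constrained variance.
#'
#' @param Y imputed dosage matrix (individuals x loci).
#' @param climate climate predictor matrix (standardized).
#' @param geography geography matrix, e.g. [geography_matrix()].
#' @param structure structure covariate matrix (default expectation: PC1 of
#'   the dosage PCA).
#' @param n_perm permutations per test (default 99).
#' @param seed optional integer seed.
#' @return Object of class `variance_partition`: `fractions` (named numeric
#'   summing to 1), `p_values`, `table` (data frame mirror).
#' @export
variance_partition <- function(Y, climate, geography, structure,
                               n_perm = 99, seed = NULL) {
  climate <- as.matrix(climate); geography <- as.matrix(geography)
  structure_m <- as.matrix(structure)
  full <- rda_fit(Y, cbind(climate, geography, structure_m))
  total <- full$inertia$total
  parts <- list(
    climate = rda_fit(Y, climate, cbind(geography, structure_m)),
    geography = rda_fit(Y, geography, cbind(climate, structure_m)),
    structure = rda_fit(Y, structure_m, cbind(climate, geography)))
  test_one <- function(fit, s) {
    res <- with_seed(s, {
      n <- nrow(fit$Yres)
      Q <- fit$Q
      if (ncol(Q) == 0) return(1)
      obs <- sum(crossprod(Q, fit$Yres)^2)
      count <- 0
      for (b in seq_len(n_perm))
        count <- count + (sum(crossprod(Q, fit$Yres[sample(n), ])^2) >= obs - 1e-12)
      (count + 1) / (n_perm + 1)
    })
    res
  }
  seeds <- lapply(c("climate", "geography", "structure"), function(l)
    child_seed(seed, l))
  p_values <- vapply(seq_along(parts), function(i)
    test_one(parts[[i]], seeds[[i]]), 0)
  names(p_values) <- names(parts)
  uniq <- vapply(parts, function(f) f$inertia$constrained / total, 0)
  frac_full <- full$inertia$constrained / total
  fractions <- c(uniq,
                 confounded = frac_full - sum(uniq),
                 unexplained = 1 - frac_full)
  tab <- data.frame(component = c(names(uniq), "confounded", "unexplained",
                                  "full_model"),
                    fraction = c(fractions, frac_full),
                    p_value = c(p_values, NA, NA, NA))
  structure(list(fractions = fractions, p_values = p_values,
                 total_explained = frac_full, table = tab),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("variance_partition (fractions of total genomic variance):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Detect candidate adaptive loci with a partial RDA
#'
#' Fits a partial RDA of loci on climate conditioned on `condition`
#' (geography and population structure), retains constrained axes found
#' significant by an eigenvalue permutation test (or a fixed count), scales
#' each locus's loadings on the retained axes, computes Mahalanobis
#' distances (robust covariance, so the neutral bulk sets the scale),
#' recalibrates them by the genomic inflation factor (median
#' distance over the chi-squared median with df = retained axes), and flags
#' loci with chi-squared p-values below the Bonferroni threshold
#' `alpha_scale / n_loci`.
#'
#' @param Y imputed dosage matrix (individuals x loci), loci named.
#' @param climate standardized climate matrix at sample locations.
#' @param condition conditioning matrix (geography columns plus structure
#'   PCs).
#' @param alpha_scale numerator of the Bonferroni threshold (default 0.01,
#'   giving `alpha = 0.01 / n`).
#' @param n_axes fixed number of retained axes; `NULL` (default) retains the
#'   leading axes significant at `axis_alpha` by permutation.
#' @param axis_alpha significance level of the axis permutation test.
#' @param n_axis_perm permutations for the axis test (default 250).
#' @param axis_test_subset maximum number of loci used in the axis test
#'   (random subset; default 100000).
#' @param seed optional integer seed.
#' @return Object of class `outlier_result`: `retained_axes`,
#'   `locus_scores`, `mahalanobis_d2`, `gif`, `p_values`, `alpha`,
#'   `outlier_ids`, `axis_p`.
#' @export
prda_outliers <- function(Y, climate, condition, alpha_scale = 0.01,
                          n_axes = NULL, axis_alpha = 0.05,
                          n_axis_perm = 250, axis_test_subset = 100000,
                          seed = NULL) {
  Y <- as.matrix(Y)
  n_loci <- ncol(Y)
  locus_ids <- colnames(Y) %||% paste0("locus", seq_len(n_loci))
  fit <- rda_fit(Y, climate, condition)
  axis_p <- NULL
  if (is.null(n_axes)) {
    subset <- if (n_loci > axis_test_subset)
      with_seed(child_seed(seed, "axis_subset"),
                sort(sample(n_loci, axis_test_subset))) else NULL
    tst <- rda_axis_test(fit, n_perm = n_axis_perm,
                         seed = child_seed(seed, "axis_perm"),
                         loci_subset = subset, alpha = axis_alpha)
    axis_p <- tst$p
    sig <- !is.na(axis_p) & axis_p < axis_alpha
    K <- if (any(sig)) max(which(cumsum(!sig) == 0)) else 0L
  } else {
    K <- min(n_axes, length(fit$eig))
  }
  alpha <- alpha_scale / n_loci
  if (K == 0) {
    warning("prda_outliers: no significant constrained axes; empty outlier set")
    return(structure(list(retained_axes = 0L, locus_scores = NULL,
                          mahalanobis_d2 = setNames(rep(NA_real_, n_loci), locus_ids),
                          gif = NA_real_,
                          p_values = setNames(rep(NA_real_, n_loci), locus_ids),
                          alpha = alpha, outlier_ids = character(0),
                          axis_p = axis_p, rda = fit),
                     class = "outlier_result"))
  }
  V <- fit$loadings[, seq_len(K), drop = FALSE]
  # robust Mahalanobis distance of axis loadings: the bulk of (neutral) loci
  # sets the scale, so true outliers do not mask themselves
  d2 <- trimmed_mahalanobis(V)
  gif <- median(d2) / qchisq(0.5, df = K)
  p <- pchisq(d2 / gif, df = K, lower.tail = FALSE)
  names(p) <- names(d2) <- locus_ids
  structure(list(retained_axes = K, locus_scores = V, mahalanobis_d2 = d2,
                 gif = gif, p_values = p, alpha = alpha,
                 outlier_ids = locus_ids[p < alpha], axis_p = axis_p,
                 rda = fit),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat("outlier_result:", length(x$outlier_ids), "outliers of",
      length(x$p_values), "loci at alpha =", format(x$alpha),
      "| retained axes:", x$retained_axes,
      "| GIF:", sprintf("%.3f", x$gif), "\n")
  invisible(x)
}

#' Write an outlier table as TSV
#' @param outliers an `outlier_result`.
#' @param variants variant metadata (`id`, `chrom`, `pos`) aligned to loci.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outlier_table <- function(outliers, variants, path) {
  ids <- names(outliers$p_values)
  idx <- match(ids, variants$id)
  tab <- data.frame(locus_id = ids, chrom = variants$chrom[idx],
                    pos = variants$pos[idx],
                    d2 = unname(outliers$mahalanobis_d2),
                    p_value = unname(outliers$p_values),
                    outlier = ids %in% outliers$outlier_ids)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
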