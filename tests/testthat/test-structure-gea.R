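test_that("dosage PCA behaves like a centered PCA should", {
  set.seed(3)
  Y <- matrix(rbinom(20 * 50, 2, 0.4), 20, 50)
  p <- pca_genotypes(Y)
  expect_lte(sum(p$explained_fraction), 1 + 1e-12)
  expect_true(all(diff(p$explained_fraction) <= 1e-12))

  # duplicated individuals get identical scores
  Y2 <- rbind(Y, Y[3, ])
  p2 <- pca_genotypes(Y2)
  expect_equal(p2$scores[21, ], p2$scores[3, ], tolerance = 1e-10)

  # two individuals: a single nonzero axis with symmetric scores
  p3 <- pca_genotypes(Y[1:2, ])
  expect_equal(p3$scores[1, 1], -p3$scores[2, 1], tolerance = 1e-10)
  expect_equal(p3$explained_fraction[1], 1, tolerance = 1e-12)
  expect_error(pca_genotypes(matrix(c(0, NA, 1, 2), 2)), "impute")
})

test_that("Haversine distances match the closed form on the 6371 km sphere", {
  co <- data.frame(sample_id = c("a", "b", "c"),
                   lon = c(0, 0, 12), lat = c(0, 1, -34))
  d <- haversine_matrix(co)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d, t(d))
  expect_equal(d["a", "b"], pi * 6371 / 180, tolerance = 1e-6)  # 111.195 km
})

test_that("Mantel tests are calibrated at their permutation resolution", {
  set.seed(10)
  pts <- matrix(rnorm(30), 15, 2)
  dA <- as.matrix(dist(pts))
  m <- mantel_test(dA, dA, n_perm = 99, seed = 1)
  expect_equal(m$statistic, 1)
  expect_equal(m$p_value, 1 / 100)
  expect_gte(m$p_value, 1 / (m$n_perm + 1))

  # independent matrices: r near zero on average, null p super-uniform
  rs <- ps <- numeric(30)
  for (i in 1:30) {
    set.seed(100 + i)
    d1 <- as.matrix(dist(rnorm(12)))
    d2 <- as.matrix(dist(rnorm(12)))
    mt <- mantel_test(d1, d2, n_perm = 99, seed = i)
    rs[i] <- mt$statistic; ps[i] <- mt$p_value
  }
  expect_lt(abs(mean(rs)), 0.15)
  expect_lte(mean(ps <= 0.1), 0.3)  # no gross anti-conservatism

  # conditioning on a constant off-diagonal matrix reduces the partial
  # Mantel statistic to the simple one
  dC <- matrix(1, 15, 15); diag(dC) <- 0
  set.seed(11)
  dB <- as.matrix(dist(rnorm(15)))
  pm <- partial_mantel_test(dA, dB, dC, n_perm = 99, seed = 2)
  sm <- mantel_test(dA, dB, n_perm = 99, seed = 2)
  expect_equal(pm$statistic, sm$statistic, tolerance = 1e-10)
  expect_true(pm$partial)

  # environment fully explained by geography: partial r collapses
  pm2 <- partial_mantel_test(dA, dB, dB, n_perm = 99, seed = 3)
  expect_lt(abs(pm2$statistic), 0.1)
})

test_that("rda_fit agrees with an independent constrained-ordination oracle", {
  set.seed(21)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  Z <- matrix(rnorm(n * 2), n, 2)
  B <- matrix(rnorm(3 * 25, sd = 0.4), 3, 25)
  Y <- X %*% B + matrix(rnorm(n * 25), n, 25)
  colnames(Y) <- paste0("L", 1:25)

  fit <- rda_fit(Y, X)
  ref <- vegan::rda(Y ~ X)
  expect_equal(unname(fit$eig), unname(ref$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$inertia$total, ref$tot.chi, tolerance = 1e-8)

  fitp <- rda_fit(Y, X, Z)
  refp <- vegan::rda(Y ~ X + Condition(Z))
  expect_equal(unname(fitp$eig), unname(refp$CCA$eig), tolerance = 1e-8)
  expect_equal(fitp$inertia$conditioned, refp$pCCA$tot.chi, tolerance = 1e-8)

  # eigenvalues non-negative, non-increasing
  expect_true(all(fit$eig >= 0))
  expect_true(all(diff(fit$eig) <= 1e-12))

  # fully conditioned out: Z = X leaves no constrained variance
  fit0 <- rda_fit(Y, X, X)
  expect_lt(fit0$inertia$constrained / fit0$inertia$total, 1e-10)

  # single predictor: constrained variance equals the fitted-value variance
  # of a direct multivariate least-squares regression
  x1 <- X[, 1, drop = FALSE]
  f1 <- rda_fit(Y, x1)
  fitted_direct <- x1 %*% solve(crossprod(scale(x1, scale = FALSE)),
                                crossprod(scale(x1, scale = FALSE),
                                          scale(Y, scale = FALSE)))
  expect_equal(sum(f1$eig), sum(scale(fitted_direct, scale = FALSE)^2) / (n - 1),
               tolerance = 1e-8)
})

test_that("variance partitioning adds up and isolates unique contributions", {
  set.seed(31)
  n <- 60
  clim <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("tmx", "cwd")))
  geo <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("lat", "lon")))
  struct <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "PC1"))
  Y <- clim %*% matrix(rnorm(2 * 30, sd = 0.5), 2, 30) +
    geo %*% matrix(rnorm(2 * 30, sd = 0.3), 2, 30) +
    matrix(rnorm(n * 30), n, 30)
  vp <- variance_partition(Y, clim, geo, struct, n_perm = 49, seed = 5)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-10)
  # independent predictors: unique fractions sum approximately to the full model
  expect_equal(unname(vp$fractions["climate"] + vp$fractions["geography"] +
                        vp$fractions["structure"]),
               vp$total_explained, tolerance = 0.02)
  expect_lt(vp$p_values[["climate"]], 0.05)

  # climate duplicated into geography: unique climate contribution collapses
  vp2 <- variance_partition(Y, clim, cbind(geo, clim), struct,
                            n_perm = 49, seed = 6)
  expect_lt(unname(vp2$fractions["climate"]), 0.01)
})

test_that("robust Mahalanobis distances are chi-squared calibrated on clean data", {
  set.seed(41)
  V <- matrix(rnorm(4000), 2000, 2)
  d2 <- adaptscape:::trimmed_mahalanobis(V)
  gif <- median(d2) / qchisq(0.5, 2)
  expect_equal(gif, 1, tolerance = 0.1)
})

test_that("pRDA outlier detection is calibrated, powerful and order-invariant", {
  fx <- small_fixture()
  ad <- fx$sim$truth$adaptive_locus_ids
  cond <- geography_matrix(fx$gmi$samples)
  o <- prda_outliers(fx$gmi$dosages, fx$X, cond, n_axes = 2)

  expect_equal(o$alpha, 0.01 / ncol(fx$gmi$dosages))  # Bonferroni exactly
  expect_setequal(o$outlier_ids, names(o$p_values)[o$p_values < o$alpha])
  expect_gt(o$gif, 0)
  # planted loci dominate the distance ranking and the flagged set
  rk <- rank(-o$mahalanobis_d2)
  expect_lte(max(rk[ad]), length(ad))
  expect_gte(length(intersect(o$outlier_ids, ad)), 5)
  expect_lte(length(setdiff(o$outlier_ids, ad)), 2)

  # locus order does not matter
  perm <- sample(ncol(fx$gmi$dosages))
  o2 <- prda_outliers(fx$gmi$dosages[, perm], fx$X, cond, n_axes = 2)
  expect_setequal(o2$outlier_ids, o$outlier_ids)

  # pure-noise response: empty set under the permutation axis test
  set.seed(50)
  Ynull <- matrix(rbinom(60 * 200, 2, 0.5), 60, 200,
                  dimnames = list(NULL, paste0("N", 1:200)))
  expect_warning(o3 <- prda_outliers(Ynull, fx$X, cond, seed = 51),
                 "no significant")
  expect_length(o3$outlier_ids, 0)
  expect_equal(o3$retained_axes, 0L)
})
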