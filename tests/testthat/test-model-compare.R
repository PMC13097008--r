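test_that("Procrustes superimposition is invariant to rotation, scale and shift", {
  set.seed(44)
  A <- matrix(rnorm(60), 20, 3)
  p0 <- procrustes_residuals(A, A, n_perm = 0)
  expect_equal(max(p0$residuals), 0, tolerance = 1e-12)

  theta <- 0.7
  R <- diag(3); R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                                        -sin(theta), cos(theta)), 2)
  B <- 2.5 * A %*% R + matrix(rep(c(3, -1, 2), each = 20), 20)
  p1 <- procrustes_residuals(A, B, n_perm = 99, seed = 1)
  expect_lt(max(p1$residuals), 1e-10)
  expect_equal(p1$correlation, 1, tolerance = 1e-6)
  expect_equal(p1$p_value, 1 / 100)

  # symmetric: residual sum does not depend on argument order
  set.seed(45)
  C <- A + matrix(rnorm(60, sd = 0.3), 20, 3)
  expect_equal(procrustes_residuals(A, C, n_perm = 0)$ss,
               procrustes_residuals(C, A, n_perm = 0)$ss, tolerance = 1e-10)

  expect_error(procrustes_residuals(A, B[1:10, ]), "share cells")
})

test_that("PCA reduction for Procrustes keeps the configured variance", {
  set.seed(46)
  M <- matrix(rnorm(200), 50, 4)
  r <- reduce_for_procrustes(M, k = 4)
  expect_equal(attr(r, "variance_retained"), 1, tolerance = 1e-12)
  # full-rank reduction is lossless up to rotation: distances preserved
  expect_equal(as.matrix(dist(r)), as.matrix(dist(scale(M, scale = FALSE))),
               tolerance = 1e-8, ignore_attr = TRUE)
  r2 <- reduce_for_procrustes(M, k = 2)
  expect_equal(ncol(r2), 2)
  expect_lt(attr(r2, "variance_retained"), 1)

  # identical inputs give identical configurations
  expect_identical(reduce_for_procrustes(M, 3), reduce_for_procrustes(M, 3))
})

test_that("Spearman tables match the tie-corrected rank formula", {
  maps <- list(a = c(x1 = 1, x2 = 5, x3 = 2, x4 = 2, x5 = 9),
               b = c(x1 = 3, x2 = 1, x3 = 3, x4 = 7, x5 = 2))
  tab <- spearman_table(maps)
  expect_equal(diag(tab), c(a = 1, b = 1))
  expect_equal(tab, t(tab))
  # brute-force: Pearson correlation of mid-ranks
  oracle <- cor(rank(maps$a), rank(maps$b))
  expect_equal(tab["a", "b"], oracle, tolerance = 1e-12)

  expect_equal(spearman_table(list(a = maps$a, neg = -maps$a))["a", "neg"], -1)
  expect_error(spearman_table(list(a = maps$a, b = maps$b[1:3])),
               "share cells|differ")
})

test_that("the nested protection ANOVA reproduces closed-form sums of squares", {
  # balanced design over protection x model x rcp x year with a pure
  # protection effect
  des <- expand.grid(protection = c("protected", "unprotected"),
                     model = c("m1", "m2"), rcp = c("4.5", "8.5"),
                     year = c("y1", "y2"), rep = 1:10)
  set.seed(47)
  delta <- 1.5
  des$adaptedness <- rnorm(nrow(des), sd = 1) +
    ifelse(des$protection == "protected", delta, 0)
  res <- protection_anova(des)

  # df bookkeeping: term dfs plus residual df give N - 1
  expect_equal(sum(res$table$Df), nrow(des) - 1)

  # protection sum of squares equals the two-group closed form
  m1 <- mean(des$adaptedness[des$protection == "protected"])
  m2 <- mean(des$adaptedness[des$protection == "unprotected"])
  n_half <- nrow(des) / 2
  ss_oracle <- n_half * (m1 - m2)^2 / 2
  got <- res$table[res$table$term == "protection", "Sum Sq"]
  expect_equal(got, ss_oracle, tolerance = 1e-8)

  # the planted effect is detected, and Tukey intervals cover it
  expect_lt(res$table[res$table$term == "protection", "Pr(>F)"], 1e-6)
  tk <- res$tukey$protection
  expect_equal(abs(tk[1, "diff"]), abs(m1 - m2), tolerance = 1e-10)

  # all-equal response carries no between-group sum of squares
  des0 <- des; des0$adaptedness <- 1
  res0 <- protection_anova(des0)
  expect_equal(res0$table[res0$table$term == "protection", "Sum Sq"], 0,
               tolerance = 1e-12)

  # empty design cells are refused with a clear message
  broken <- des[!(des$protection == "protected" & des$model == "m2"), ]
  expect_error(protection_anova(broken), "empty factor cell")
})

test_that("no planted effect keeps the protection term at nominal significance", {
  hits <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    des <- expand.grid(protection = c("protected", "unprotected"),
                       model = c("m1", "m2"), rcp = c("4.5", "8.5"),
                       year = c("y1", "y2"), rep = 1:5)
    des$adaptedness <- rnorm(nrow(des))
    res <- protection_anova(des)
    hits <- hits + (res$table[res$table$term == "protection", "Pr(>F)"] < 0.05)
  }
  expect_lte(hits, 4)  # ~5% type-I rate, generous binomial bound
})

test_that("method configurations feed Procrustes comparably across engines", {
  eng <- small_engines()
  fx <- small_fixture()
  cfg_gf <- method_configuration(eng$gf, fx$grids$recent, k = 3)
  cfg_rda <- method_configuration(eng$rda, fx$grids$recent, k = 2)
  expect_equal(nrow(cfg_gf), nrow(fx$grids$recent$cells))
  expect_equal(ncol(cfg_rda), 2)
  cfg_gdm <- method_configuration(eng$gdm, fx$grids$recent, k = 2,
                                  max_cells = 60, seed = 3)
  expect_lte(nrow(cfg_gdm), 60)
  shared <- intersect(rownames(cfg_gf), rownames(cfg_gdm))
  pr <- procrustes_residuals(cfg_gf[shared, 1:2], cfg_gdm[shared, ],
                             n_perm = 49, seed = 4)
  expect_true(all(pr$residuals >= 0))
})

test_that("offset maps of the three engines are spatially concordant", {
  # engines fitted on the true clinal loci of a reference landscape and
  # predicted under a displacement with strong spatial structure (real
  # downscaled scenarios displace coastal and inland cells very differently;
  # a spatially flat displacement would leave the linear RDA engine's map
  # without any rank signal)
  lc <- landscape_config(seed = 3, scenarios = list())
  grids <- make_climate_grids(lc)
  sim <- suppressMessages(simulate_genotypes(lc, grids))
  gmi <- impute_major(sim$gm)
  ext <- extract_at_points(grids$recent, sim$coords)
  X <- as.matrix(ext[, grids$recent$variables])
  Y <- gmi$dosages[, sim$truth$adaptive_locus_ids]
  gf <- suppressWarnings(fit_gradient_forest(Y, X, n_trees = 200, seed = 3))
  rda <- fit_rda_offset(Y, X, n_axes = 1)
  fr <- site_allele_freqs(gmi, sim$truth$adaptive_locus_ids)
  sc <- t(sapply(rownames(fr), function(s)
    colMeans(X[gmi$samples$site == s, , drop = FALSE])))
  gdm <- fit_gdm(fr, sc)

  rec <- grids$recent
  fut <- rec; fut$scenario <- scenario_key("grad", "8.5", "p")
  dx <- (rec$cells$x - min(rec$cells$x)) / diff(range(rec$cells$x))
  fut$values[, "tmx"] <- rec$values[, "tmx"] + 0.3 + 1.2 * dx

  maps <- lapply(list(gf = gf, rda = rda, gdm = gdm), function(m)
    suppressMessages(predict_offset(m, rec, fut))$offset)
  rho <- cor(do.call(cbind, maps), method = "spearman")
  # the nonlinear pair tracks closely; the linear engine agrees in rank but
  # more loosely, as expected from its translation-invariant offsets
  expect_gt(rho["gf", "gdm"], 0.7)
  expect_gt(min(rho[upper.tri(rho)]), 0.3)
})
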