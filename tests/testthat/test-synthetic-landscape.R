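test_that("climate grids are deterministic and displacement behaves as configured", {
  lc <- landscape_config(n_cells_x = 8, n_cells_y = 8, seed = 11,
                         scenarios = list(
                           list(model = "null", rcp = "4.5", period = "p",
                                shift = c(tmx = 0)),
                           list(model = "warm", rcp = "8.5", period = "p",
                                shift = c(tmx = 2))))
  g1 <- make_climate_grids(lc)
  g2 <- make_climate_grids(lc)
  expect_identical(g1, g2)

  # recent grid standardized to mean 0 / SD 1 per variable
  expect_equal(unname(colMeans(g1$recent$values)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(apply(g1$recent$values, 2, sd)), rep(1, 6),
               tolerance = 1e-10)

  # zero displacement: future grid equals recent grid exactly
  expect_identical(g1[["null_4.5_p"]]$values, g1$recent$values)

  # +2 SD tmx shift: the perturbation field is centered, so the cell-mean
  # displacement equals the configured shift (direct averaging oracle)
  d <- g1[["warm_8.5_p"]]$values[, "tmx"] - g1$recent$values[, "tmx"]
  expect_equal(mean(d), 2, tolerance = 1e-9)
  expect_gt(sd(d), 0)  # but cells are genuinely perturbed
  # untouched variables unchanged
  expect_identical(g1[["warm_8.5_p"]]$values[, "cwd"], g1$recent$values[, "cwd"])
})

test_that("degenerate landscapes are rejected", {
  expect_error(make_climate_grids(landscape_config(n_cells_x = 1, n_cells_y = 1)),
               "degenerate")
  expect_error(landscape_config(missing_rate = 1), "missing_rate")
  expect_error(landscape_config(n_adaptive_loci = 5, driver_vars = character(0)),
               "driver_vars")
})

test_that("simulated genotypes carry the configured signal structure", {
  fx <- small_fixture()
  sim <- fx$sim
  truth <- sim$truth

  # truth covers all loci, disjointly
  expect_length(intersect(truth$adaptive_locus_ids, truth$neutral_locus_ids), 0)
  expect_setequal(c(truth$adaptive_locus_ids, truth$neutral_locus_ids),
                  sim$gm$variants$id)

  # determinism, bit for bit
  sim2 <- suppressMessages(simulate_genotypes(fx$lc, fx$grids))
  expect_identical(sim$gm$dosages, sim2$gm$dosages)
  expect_identical(sim$coords, sim2$coords)

  # injected signal: adaptive loci correlate with their driver far above the
  # neutral background (brute-force rank of correlations)
  cors <- abs(suppressWarnings(cor(fx$gmi$dosages, fx$X[, "tmx"])))
  ad <- truth$adaptive_locus_ids
  neut <- truth$neutral_locus_ids
  expect_gt(median(cors[ad, ]), quantile(cors[neut, ], 0.95))

  # no missingness when disabled; configured rate otherwise
  lc0 <- landscape_config(n_cells_x = 8, n_cells_y = 8, n_individuals = 30,
                          n_sites = 3, n_neutral_loci = 50,
                          n_adaptive_loci = 0, missing_rate = 0, seed = 2)
  g0 <- make_climate_grids(lc0)
  s0 <- suppressMessages(simulate_genotypes(lc0, g0))
  expect_false(anyNA(s0$gm$dosages))
})

test_that("null (zero-effect) adaptive loci are indistinguishable from neutral", {
  lc <- landscape_config(n_cells_x = 10, n_cells_y = 10, n_individuals = 60,
                         n_sites = 6, n_neutral_loci = 150,
                         n_adaptive_loci = 10, adaptive_effect = 0, seed = 8)
  g <- make_climate_grids(lc)
  s <- suppressMessages(simulate_genotypes(lc, g))
  gmi <- impute_major(s$gm)
  ext <- extract_at_points(g$recent, s$coords)
  cors <- abs(suppressWarnings(cor(gmi$dosages, ext$tmx)))
  ad <- s$truth$adaptive_locus_ids
  neut <- s$truth$neutral_locus_ids
  expect_lt(median(cors[ad, ]), quantile(cors[neut, ], 0.9))
})

test_that("the default design matches the reference sampling scale", {
  lc <- landscape_config()
  expect_equal(lc$n_individuals, 171)
  expect_equal(lc$n_sites, 10)
  sizes <- adaptscape:::site_size_design(lc)
  expect_equal(sum(sizes), 171)
  expect_equal(sort(sizes, decreasing = TRUE)[1:3], c(48, 48, 48))
})

test_that("fixtures round-trip losslessly through the loaders", {
  fx <- small_fixture()
  out <- withr::local_tempdir()
  paths <- write_fixture(fx$sim$gm, fx$grids, fx$sim$coords, out,
                         truth = fx$sim$truth)

  # VCF header declares GT and DP
  head_lines <- readLines(paths$vcf, n = 10)
  expect_true(any(grepl("##FORMAT=<ID=GT", head_lines, fixed = TRUE)))
  expect_true(any(grepl("##FORMAT=<ID=DP", head_lines, fixed = TRUE)))

  gm2 <- load_genotypes(paths$vcf)
  expect_equal(unname(gm2$dosages), unname(fx$sim$gm$dosages))
  expect_equal(gm2$variants$id, fx$sim$gm$variants$id)

  g2 <- load_grid(paths$grids[["recent"]], scenario_key())
  expect_equal(g2$values, fx$grids$recent$values, tolerance = 1e-12)
  expect_equal(g2$cells$cell_id, fx$grids$recent$cells$cell_id)

  co <- read.csv(paths$coords)
  expect_equal(co$sample_id, fx$sim$coords$sample_id)
  tr <- read.csv(paths$truth)
  expect_equal(sum(tr$class == "adaptive"),
               length(fx$sim$truth$adaptive_locus_ids))
})
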