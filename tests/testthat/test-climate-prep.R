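test_that("grid CSV round-trips and drops incomplete cells", {
  fx <- small_fixture()
  g <- fx$grids$recent
  p <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, p)
  g2 <- load_grid(p, scenario_key())
  expect_equal(g2$values, g$values, tolerance = 1e-12)
  expect_equal(g2$cells$x, g$cells$x)
  expect_equal(g2$variables, g$variables)  # order of first appearance

  # a cell with one NaN layer is dropped entirely
  long <- read.csv(p)
  long$value[long$cell_id == g$cells$cell_id[3] & long$variable == "tmx"] <- NA
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, p2, row.names = FALSE)
  expect_message(g3 <- load_grid(p2, scenario_key()), "dropped 1 cells")
  expect_equal(nrow(g3$cells), nrow(g$cells) - 1)
  expect_false(g$cells$cell_id[3] %in% g3$cells$cell_id)

  # geometry mismatch across layer files errors
  bad <- long[long$variable == "tmx", ]
  bad$x <- bad$x + 1
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, p3, row.names = FALSE)
  p4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(long[long$variable == "cwd", ], p4, row.names = FALSE)
  expect_error(load_grid(c(p3, p4), scenario_key()), "geometry mismatch")
})

test_that("nearest-cell extraction honors bounds and the tie rule", {
  fx <- small_fixture()
  g <- fx$grids$recent
  # a point at a cell center gets exactly that cell's values
  i <- 17
  pt <- data.frame(sample_id = "a", lon = g$cells$lon[i], lat = g$cells$lat[i])
  got <- extract_at_points(g, pt)
  expect_equal(got$cell_id, g$cells$cell_id[i])
  expect_equal(unlist(got[1, g$variables]), g$values[i, ],
               tolerance = 1e-12, ignore_attr = TRUE)

  # two samples in one cell: identical vectors, same cell id
  two <- data.frame(sample_id = c("a", "b"),
                    lon = g$cells$lon[i] + c(0, 1e-5),
                    lat = g$cells$lat[i] + c(0, 1e-5))
  got2 <- extract_at_points(g, two)
  expect_equal(got2$cell_id[1], got2$cell_id[2])
  expect_equal(unlist(got2[1, g$variables]), unlist(got2[2, g$variables]))

  # equidistant between two centers -> lowest cell_id wins
  mid <- data.frame(sample_id = "m",
                    lon = mean(g$cells$lon[1:2]), lat = g$cells$lat[1])
  expect_equal(extract_at_points(g, mid)$cell_id, g$cells$cell_id[1])

  # out-of-bounds points are named
  far <- data.frame(sample_id = "far", lon = max(g$cells$lon) + 1,
                    lat = g$cells$lat[1])
  expect_error(extract_at_points(g, far), "far")
})

test_that("collinearity pruning respects the priority list and input order", {
  set.seed(2)
  n <- 200
  base <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(NULL, c("cwd", "rch", "run", "str", "tmn", "tmx")))
  # four redundant candidates highly correlated with retained variables
  extra <- cbind(tmean = base[, "tmn"] + rnorm(n, sd = 0.1),
                 aet = base[, "cwd"] + rnorm(n, sd = 0.1),
                 ppt = base[, "rch"] + rnorm(n, sd = 0.1),
                 pet = base[, "tmx"] + rnorm(n, sd = 0.1))
  tab <- cbind(base, extra)
  priority <- c("cwd", "rch", "run", "str", "tmn", "tmx")
  res <- prune_collinear(tab, r2_max = 0.7, keep_priority = priority)
  expect_setequal(res$retained, priority)  # 10 candidates reduce to the 6-set
  expect_equal(nrow(res$removed), 4)

  # duplicated variable: one copy removed, all-independent set untouched
  dup <- cbind(a = base[, 1], b = base[, 1], c = base[, 2])
  res2 <- prune_collinear(dup, keep_priority = c("a", "b", "c"))
  expect_equal(res2$retained, c("a", "c"))
  res3 <- prune_collinear(base, r2_max = 0.7)
  expect_setequal(res3$retained, colnames(base))

  # column order does not change the outcome under a fixed priority
  perm <- tab[, sample(ncol(tab))]
  res4 <- prune_collinear(perm, r2_max = 0.7, keep_priority = priority)
  expect_setequal(res4$retained, res$retained)
})

test_that("standardization uses recent statistics and inverts exactly", {
  fx <- small_fixture()
  rec <- fx$grids$recent
  fut <- fx$grids[["synth-hotdry_8.5_2070-2099"]]
  st <- climate_stats(rec)
  rec_s <- standardize_climate(rec, st)
  expect_equal(unname(colMeans(rec_s$values)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(rec_s$values, 2, sd)), rep(1, 6), tolerance = 1e-12)

  # future standardized with recent statistics keeps its displacement
  fut_s <- standardize_climate(fut, st)
  expect_gt(mean(fut_s$values[, "tmx"]), 1)

  # round trip and idempotence on already-standardized data
  back <- unstandardize_climate(fut_s, st)
  expect_equal(back$values, fut$values, tolerance = 1e-12)
  again <- standardize_climate(rec_s, climate_stats(rec_s))
  expect_equal(again$values, rec_s$values, tolerance = 1e-10)

  flat <- cbind(a = rep(1, 5), b = 1:5)
  expect_error(climate_stats(flat), "a")
})
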