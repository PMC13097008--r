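test_that("transfer matrices match per-pair oracles and directional summaries", {
  eng <- small_engines()
  fx <- small_fixture()
  fut <- fx$grids[["synth-hotdry_8.5_2070-2099"]]
  donors <- subset_grid(fx$grids$recent, fx$grids$recent$cells$cell_id[1:6])
  recips <- subset_grid(fut, fut$cells$cell_id[10:13])

  for (m in eng) {
    tm <- pairwise_transfer(m, donors, recips)
    expect_equal(dim(tm$offset), c(6, 4))
    expect_true(all(tm$offset >= 0))
    expect_identical(transfer_adaptedness(tm), -tm$offset)

    # every entry equals an independently recomputed single-pair offset
    for (i in c(1, 4)) for (j in c(2, 3)) {
      a <- adaptscape:::clamp_to_train(m, donors$values[i, , drop = FALSE], TRUE)
      b <- adaptscape:::clamp_to_train(m, recips$values[j, , drop = FALSE], TRUE)
      expect_equal(tm$offset[i, j], offset_between(m, a, b),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }

    # row means / column means are the reverse / forward summaries
    expect_equal(reverse_adaptedness(tm), rowMeans(-tm$offset))
    expect_equal(forward_adaptedness(tm), colMeans(-tm$offset))
  }

  # identical current and future climate for a pair gives entry 0
  same <- pairwise_transfer(eng$rda, donors, donors)
  expect_equal(unname(diag(same$offset)), rep(0, 6), tolerance = 1e-12)
})

test_that("hand-computed 3x2 summaries are reproduced exactly", {
  tm <- structure(list(offset = matrix(c(1, 2, 3, 4, 5, 6), 3, 2),
                       donors = c("d1", "d2", "d3"),
                       recipients = c("r1", "r2"),
                       method = "toy",
                       scenario_pair = list(from = scenario_key(),
                                            to = scenario_key("m", "8.5", "p"))),
                  class = "transfer_matrix")
  expect_equal(unname(reverse_adaptedness(tm)), c(-(1 + 4) / 2, -(2 + 5) / 2,
                                                  -(3 + 6) / 2))
  expect_equal(unname(forward_adaptedness(tm)), c(-2, -5))
})

test_that("seed source priority equals exhaustive enumeration with a strict tie rule", {
  set.seed(33)
  off <- matrix(runif(20), 5, 4, dimnames = list(paste0("d", 1:5),
                                                 paste0("r", 1:4)))
  tm <- structure(list(offset = off, donors = rownames(off),
                       recipients = colnames(off), method = "toy",
                       scenario_pair = NULL), class = "transfer_matrix")
  base <- setNames(-runif(4), colnames(off))
  pr <- seed_source_priority(tm, base)
  for (i in 1:5) {
    cnt <- sum(sapply(1:4, function(j) (-off[i, j]) > base[j]))
    expect_equal(pr$priority[i], cnt / 4)
  }
  expect_true(all(pr$priority >= 0 & pr$priority <= 1))

  # donor exactly at baseline everywhere: strict inequality gives zero
  tm2 <- tm; tm2$offset <- matrix(1, 5, 4, dimnames = dimnames(off))
  pr2 <- seed_source_priority(tm2, setNames(rep(-1, 4), colnames(off)))
  expect_equal(pr2$priority, rep(0, 5))

  # donor strictly better everywhere: priority 1
  pr3 <- seed_source_priority(tm2, setNames(rep(-2, 4), colnames(off)))
  expect_equal(pr3$priority, rep(1, 5))

  expect_error(seed_source_priority(tm, base[1:2]), "baseline missing")
})

test_that("baseline adaptedness is the engine surface restricted to focal cells", {
  eng <- small_engines()
  fx <- small_fixture()
  fut <- fx$grids[["synth-warmwet_8.5_2070-2099"]]
  cells <- fx$grids$recent$cells$cell_id[5:9]
  base <- baseline_adaptedness(eng$gf, fx$grids$recent, fut, cells = cells)
  surf <- suppressMessages(offset_gf(eng$gf, fx$grids$recent, fut))
  expect_equal(unname(base), surf$adaptedness[match(cells, surf$cell_id)],
               tolerance = 1e-12)
  base0 <- baseline_adaptedness(eng$gf, fx$grids$recent, fx$grids$recent,
                                cells = cells)
  expect_equal(unname(base0), rep(0, 5))
})

test_that("donor scopes follow the radius geometry", {
  # 1-D toy landscape with known spacing: cells every ~0.3 degrees of
  # latitude (about 33.36 km)
  n <- 11
  cells <- data.frame(cell_id = sprintf("c%02d", 1:n), lon = 0,
                      lat = seq(0, 3, length.out = n))
  step_km <- pi * 6371 / 180 * 0.3
  focal <- "c06"
  expect_setequal(radius_donors(cells, focal, scope = "site"), focal)
  expect_setequal(radius_donors(cells, focal, scope = "range"), cells$cell_id)
  got <- radius_donors(cells, focal, scope = "radius", radius_km = 50)
  expect_setequal(got, sprintf("c%02d", 5:7))  # floor(50 / 33.36) = 1 step
  got2 <- radius_donors(cells, focal, scope = "radius",
                        radius_km = 2.5 * step_km)
  expect_setequal(got2, sprintf("c%02d", 4:8))
  expect_setequal(radius_donors(cells, focal, scope = "radius",
                                radius_km = 1e5), cells$cell_id)
  expect_error(radius_donors(cells, "nope"), "focal cells")
})

test_that("self-donation under an unchanged climate never beats the baseline", {
  eng <- small_engines()
  fx <- small_fixture()
  g <- fx$grids$recent
  recips <- subset_grid(g, g$cells$cell_id[1:5])
  donors <- subset_grid(g, g$cells$cell_id[1:10])  # includes every recipient
  base <- baseline_adaptedness(eng$rda, g, g, cells = recips$cells$cell_id)
  tm <- pairwise_transfer(eng$rda, donors, recips)
  pr <- seed_source_priority(tm, base)
  expect_equal(pr$priority, rep(0, 10))  # nobody beats a zero-offset baseline
})

test_that("widening the donor scope can only improve the best donor", {
  eng <- small_engines()
  fx <- small_fixture()
  fut <- fx$grids[["synth-hotdry_8.5_2070-2099"]]
  cells <- fx$grids$recent$cells
  focal <- radius_donors(cells, cells$cell_id[40], scope = "radius",
                         radius_km = 8)
  recips <- subset_grid(fut, focal)
  best <- sapply(c("site", "radius", "range"), function(sc) {
    ids <- radius_donors(cells, focal, scope = sc, radius_km = 25)
    tm <- pairwise_transfer(eng$gf, subset_grid(fx$grids$recent, ids), recips)
    max(reverse_adaptedness(tm))
  })
  expect_true(all(diff(best) >= -1e-12))
})
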