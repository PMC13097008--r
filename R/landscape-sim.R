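# Synthetic landscape generator: clinal adaptive loci over a spatially
# autocorrelated neutral background, with current and displaced future
# climate grids. Every downstream stage of the package is testable on its
# output without any external data.

#' Default future-climate scenarios for the synthetic landscape
#'
#' Two contrasting climate models (a warm-wet and a hot-dry synthetic model)
#' crossed with two emission pathways and two 30-year periods; mid-century
#' displacements are 55% of the late-century ones. Shifts are per-variable
#' displacements in SD units of the recent grid.
#'
#' @return A list of scenario descriptors (`model`, `rcp`, `period`, `shift`).
#' @export
default_future_scenarios <- function() {
  late <- list(
    list(model = "synth-warmwet", rcp = "4.5",
         shift = c(cwd = 0.2, rch = 0.3, run = 0.3, str = 0.1, tmn = 0.8, tmx = 0.8)),
    list(model = "synth-warmwet", rcp = "8.5",
         shift = c(cwd = 0.5, rch = 0.5, run = 0.5, str = 0.2, tmn = 1.5, tmx = 1.5)),
    list(model = "synth-hotdry", rcp = "4.5",
         shift = c(cwd = 1.0, rch = -0.5, run = -0.5, str = -0.3, tmn = 1.0, tmx = 1.2)),
    list(model = "synth-hotdry", rcp = "8.5",
         shift = c(cwd = 1.8, rch = -1.0, run = -1.0, str = -0.6, tmn = 1.8, tmx = 2.2)))
  out <- list()
  for (sc in late) {
    out[[length(out) + 1]] <- list(model = sc$model, rcp = sc$rcp,
                                   period = "2040-2069", shift = 0.55 * sc$shift)
    out[[length(out) + 1]] <- list(model = sc$model, rcp = sc$rcp,
                                   period = "2070-2099", shift = sc$shift)
  }
  out
}

#' Configuration of a synthetic landscape
#'
#' Defaults emulate the sampling design of the emulated study system: 171
#' individuals over 10 sites (the unbalanced 4/4/4/3/4/4/48/4/48/48 design,
#' three intensively sampled focal sites), 20 clinal adaptive loci among 980
#' neutral loci, six climate variables, and four future scenarios.
#'
#' @param n_cells_x,n_cells_y grid dimensions in cells.
#' @param cell_size_km cell edge length (km).
#' @param n_individuals,n_sites sampling design counts.
#' @param site_sizes optional integer vector of per-site sample sizes summing
#'   to `n_individuals`; default is the unbalanced reference design when
#'   `n_individuals = 171` and `n_sites = 10`, otherwise a near-equal split.
#' @param n_neutral_loci,n_adaptive_loci locus counts.
#' @param adaptive_effect slope of logit allele frequency per SD of the
#'   driving climate variable.
#' @param driver_vars character subset of
#'   `c("cwd","rch","run","str","tmn","tmx")` driving adaptive loci.
#' @param site_radius_km half-width of the square neighborhood around a site
#'   center within which its individuals are scattered; spanning several
#'   cells emulates stratified within-preserve sampling across the local
#'   climate gradient.
#' @param ibd_scale_km autocorrelation range (km) of neutral site allele
#'   frequencies (isolation by distance).
#' @param ibd_sd standard deviation of the neutral logit-frequency field.
#' @param scenarios list of future scenarios as in
#'   [default_future_scenarios()].
#' @param perturb_sd SD of the mean-zero spatial perturbation multiplying the
#'   future shift (so the realized mean displacement equals the configured
#'   shift exactly).
#' @param missing_rate fraction of genotypes set missing, in `[0, 1)`.
#' @param origin_lon,origin_lat geographic anchor of the grid's south-west
#'   corner (degrees).
#' @param seed integer seed; the whole fixture is a deterministic function of
#'   the configuration including the seed.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(n_cells_x = 30, n_cells_y = 30, cell_size_km = 5,
                             n_individuals = 171, n_sites = 10,
                             site_sizes = NULL, site_radius_km = 15,
                             n_neutral_loci = 980, n_adaptive_loci = 20,
                             adaptive_effect = 2,
                             driver_vars = "tmx",
                             ibd_scale_km = 100, ibd_sd = 1.1,
                             scenarios = default_future_scenarios(),
                             perturb_sd = 0.1,
                             missing_rate = 0.05,
                             origin_lon = -121.5, origin_lat = 33.3,
                             seed = 1) {
  vars <- c("cwd", "rch", "run", "str", "tmn", "tmx")
  stopifnot(n_cells_x >= 1, n_cells_y >= 1, cell_size_km > 0,
            n_individuals >= 1, n_sites >= 1, n_neutral_loci >= 1,
            n_adaptive_loci >= 0, missing_rate >= 0, missing_rate < 1,
            ibd_scale_km > 0)
  if (n_adaptive_loci > 0 && length(driver_vars) == 0)
    abort_ctx("driver_vars must be non-empty when n_adaptive_loci > 0")
  if (!all(driver_vars %in% vars))
    abort_ctx("driver_vars must be a subset of ", paste(vars, collapse = ","))
  if (!is.null(site_sizes)) {
    stopifnot(length(site_sizes) == n_sites, sum(site_sizes) == n_individuals)
  }
  structure(list(n_cells_x = n_cells_x, n_cells_y = n_cells_y,
                 cell_size_km = cell_size_km, n_individuals = n_individuals,
                 n_sites = n_sites, site_sizes = site_sizes,
                 site_radius_km = site_radius_km,
                 n_neutral_loci = n_neutral_loci,
                 n_adaptive_loci = n_adaptive_loci,
                 adaptive_effect = adaptive_effect, driver_vars = driver_vars,
                 ibd_scale_km = ibd_scale_km, ibd_sd = ibd_sd,
                 scenarios = scenarios, perturb_sd = perturb_sd,
                 missing_rate = missing_rate, origin_lon = origin_lon,
                 origin_lat = origin_lat, variables = vars, seed = seed),
            class = "landscape_config")
}

# Cholesky factor of a Gaussian-kernel covariance over planar coordinates.
grf_chol <- function(xy, range_km, nugget = 1e-8) {
  d2 <- as.matrix(dist(xy))^2
  K <- exp(-d2 / (2 * range_km^2))
  diag(K) <- diag(K) + nugget
  chol(K)
}

grf_draw <- function(chol_up, n = 1) {
  z <- matrix(rnorm(nrow(chol_up) * n), nrow(chol_up), n)
  crossprod(chol_up, z)
}

landscape_cells <- function(config) {
  xs <- (seq_len(config$n_cells_x) - 0.5) * config$cell_size_km
  ys <- (seq_len(config$n_cells_y) - 0.5) * config$cell_size_km
  g <- expand.grid(x = xs, y = ys)
  lat <- config$origin_lat + g$y / KM_PER_DEG
  mid_lat <- config$origin_lat + mean(ys) / KM_PER_DEG
  lon <- config$origin_lon + g$x / (KM_PER_DEG * cos(mid_lat * pi / 180))
  data.frame(cell_id = sprintf("c%05d", seq_len(nrow(g))),
             x = g$x, y = g$y, lon = lon, lat = lat)
}

#' Generate recent and future climate grids for a synthetic landscape
#'
#' Each variable is a smooth spatial field (Gaussian random field plus a mild
#' linear trend plus white noise) standardized to mean 0 / SD 1 on the recent
#' grid. A future grid displaces each variable by the scenario's configured
#' shift multiplied by `1 + p`, where `p` is a mean-zero smooth perturbation
#' field of SD `perturb_sd`, so the cell-mean displacement equals the shift
#' exactly.
#'
#' @param config a [landscape_config()].
#' @return Named list of [climate_grid()] objects: `recent` plus one entry
#'   per future scenario, sharing cell geometry.
#' @export
make_climate_grids <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  if (config$n_cells_x == 1 && config$n_cells_y == 1)
    abort_ctx("degenerate 1x1 grid: spatial fields are undefined")
  cells <- landscape_cells(config)
  vars <- config$variables
  with_seed(child_seed(config$seed, "climate"), {
    domain <- max(diff(range(cells$x)), diff(range(cells$y)), config$cell_size_km)
    # regional gradient plus short-range "topographic" heterogeneity: fine
    # grained climate grids are far from a planar lat/lon surface
    L <- grf_chol(cells[, c("x", "y")], range_km = 0.30 * domain)
    L_short <- grf_chol(cells[, c("x", "y")], range_km = 0.08 * domain)
    xs <- as.numeric(scale(cells$x)); ys <- as.numeric(scale(cells$y))
    recent_vals <- sapply(vars, function(v) {
      ang <- runif(1, 0, 2 * pi)
      raw <- 0.6 * as.numeric(grf_draw(L)) +
        0.7 * as.numeric(grf_draw(L_short)) +
        0.3 * (cos(ang) * xs + sin(ang) * ys) +
        0.15 * rnorm(nrow(cells))
      as.numeric(scale(raw))
    })
    colnames(recent_vals) <- vars
    grids <- list(recent = climate_grid(cells, recent_vals, scenario_key(),
                                        config$cell_size_km))
    for (sc in config$scenarios) {
      key <- scenario_key(sc$model, sc$rcp, sc$period)
      shift <- setNames(rep(0, length(vars)), vars)
      shift[names(sc$shift)] <- sc$shift
      fut <- recent_vals
      for (v in vars) {
        if (shift[[v]] == 0) next  # zero displacement: future equals recent exactly
        p <- as.numeric(grf_draw(L))
        p <- (p - mean(p))
        p <- p / max(sd(p), 1e-12) * config$perturb_sd
        fut[, v] <- recent_vals[, v] + shift[[v]] * (1 + p)
      }
      grids[[key$id]] <- climate_grid(cells, fut, key, config$cell_size_km)
    }
    grids
  })
}

#' Ground truth of a simulated genotype matrix
#' @param adaptive_locus_ids,neutral_locus_ids disjoint locus id sets covering
#'   all loci.
#' @param driver_of_locus named character map locus -> driving variable.
#' @param effect_of_locus named numeric map locus -> signed logit slope.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(adaptive_locus_ids, neutral_locus_ids,
                            driver_of_locus, effect_of_locus) {
  if (length(intersect(adaptive_locus_ids, neutral_locus_ids)) > 0)
    abort_ctx("adaptive and neutral locus id sets must be disjoint")
  structure(list(adaptive_locus_ids = adaptive_locus_ids,
                 neutral_locus_ids = neutral_locus_ids,
                 driver_of_locus = driver_of_locus,
                 effect_of_locus = effect_of_locus),
            class = "synthetic_truth")
}

# Greedy maximin placement of site cells: spreads sites across the grid,
# deterministic given the RNG state (first site is a random cell).
place_sites <- function(cells, n_sites) {
  idx <- sample(nrow(cells), 1)
  xy <- as.matrix(cells[, c("x", "y")])
  while (length(idx) < n_sites) {
    d <- sapply(seq_len(nrow(cells)), function(i)
      min(sqrt(rowSums((xy[idx, , drop = FALSE] -
                          matrix(xy[i, ], length(idx), 2, byrow = TRUE))^2))))
    idx <- c(idx, which.max(d))
  }
  idx
}

site_size_design <- function(config) {
  if (!is.null(config$site_sizes)) return(config$site_sizes)
  if (config$n_individuals == 171 && config$n_sites == 10)
    return(c(4L, 4L, 4L, 3L, 4L, 4L, 48L, 4L, 48L, 48L))  # reference unbalanced design
  n <- config$n_individuals; k <- config$n_sites
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  sizes
}

#' Simulate genotypes with clinal adaptive loci on an IBD neutral background
#'
#' Individuals are placed in `n_sites` clusters across the grid, scattered
#' within `site_radius_km` of the site center so that a site's trees span
#' several climate cells (stratified within-preserve sampling). A neutral
#' locus draws its site allele frequencies from a spatially autocorrelated
#' logit-normal field (range `ibd_scale_km`) around a Beta-distributed global
#' frequency; part of that field is shared across loci through two common
#' spatial factors with locus-specific loadings, emulating the
#' low-dimensional neutral structure that shared demographic history imposes
#' on all loci (so the leading genotype PCs are neutral, as in real data).
#' An adaptive locus is locally adapted at cell scale:
#' `logit p(individual) = logit(p0) + effect * driver(cell of individual)`
#' with the driver value taken from the standardized recent grid. Dosages
#' are Binomial(2, p); frequencies are clamped to `[0.01, 0.99]` (clamps are
#' messaged) so loci stay polymorphic; missingness is applied uniformly.
#'
#' @param config a [landscape_config()].
#' @param grids output of [make_climate_grids()] (must contain `recent`).
#' @return A list with elements `gm` ([genotype_matrix()]), `truth`
#'   ([synthetic_truth()]), `coords` (data frame `sample_id`, `lon`, `lat`,
#'   `site_id`) and `site_cells` (cell id per site).
#' @export
simulate_genotypes <- function(config, grids) {
  stopifnot(inherits(config, "landscape_config"))
  if (!"recent" %in% names(grids)) abort_ctx("grids must contain the recent scenario")
  recent <- grids$recent
  with_seed(child_seed(config$seed, "genotypes"), {
    site_idx <- place_sites(recent$cells, config$n_sites)
    site_cells <- recent$cells$cell_id[site_idx]
    sizes <- site_size_design(config)
    site_of_ind <- rep(seq_len(config$n_sites), sizes)
    n_ind <- config$n_individuals

    # scatter individuals around their site center (clamped to the grid) and
    # assign each to the cell containing it
    ext_x <- config$n_cells_x * config$cell_size_km
    ext_y <- config$n_cells_y * config$cell_size_km
    jit <- config$site_radius_km
    px <- pmin(pmax(recent$cells$x[site_idx[site_of_ind]] +
                      runif(n_ind, -jit, jit), 1e-6), ext_x - 1e-6)
    py <- pmin(pmax(recent$cells$y[site_idx[site_of_ind]] +
                      runif(n_ind, -jit, jit), 1e-6), ext_y - 1e-6)
    xi <- pmin(pmax(ceiling(px / config$cell_size_km), 1L), config$n_cells_x)
    yi <- pmin(pmax(ceiling(py / config$cell_size_km), 1L), config$n_cells_y)
    cell_of_ind <- (yi - 1L) * config$n_cells_x + xi

    n_total <- config$n_neutral_loci + config$n_adaptive_loci
    locus_ids <- sprintf("L%05d", seq_len(n_total))
    adaptive_pos <- if (config$n_adaptive_loci > 0)
      sort(sample(n_total, config$n_adaptive_loci)) else integer(0)
    is_adaptive <- seq_len(n_total) %in% adaptive_pos

    # site-level logit frequency fields
    Ls <- if (config$n_sites > 1)
      grf_chol(recent$cells[site_idx, c("x", "y")], config$ibd_scale_km,
               nugget = 1e-6) else NULL
    p0 <- pmin(pmax(rbeta(n_total, 1.2, 1.2), 0.05), 0.95)
    # adaptive loci start at intermediate frequencies so the configured
    # clinal effect is realizable across the landscape instead of being
    # truncated by the polymorphism clamp
    p0[is_adaptive] <- runif(sum(is_adaptive), 0.25, 0.75)
    drivers <- rep_len(config$driver_vars, max(config$n_adaptive_loci, 1))
    driver_of <- character(0); effect_of <- numeric(0)

    # two shared neutral spatial factors (common demographic axes, the first
    # dominant so the leading genotype PC is neutral structure) plus a
    # locus-specific field; half of the neutral logit variance is shared
    g_shared <- if (is.null(Ls)) matrix(0, config$n_sites, 2)
                else matrix(as.numeric(grf_draw(Ls, 2)), ncol = 2)
    w_shared <- c(sqrt(0.35), sqrt(0.15)); w_own <- sqrt(0.5)

    prob <- matrix(0, n_ind, n_total)
    k_ad <- 0
    for (j in seq_len(n_total)) {
      if (is_adaptive[j]) {
        k_ad <- k_ad + 1
        v <- drivers[k_ad]
        beta <- config$adaptive_effect * sample(c(-1, 1), 1)
        driver_of[locus_ids[j]] <- v
        effect_of[locus_ids[j]] <- beta
        prob[, j] <- plogis(qlogis(p0[j]) + beta * recent$values[cell_of_ind, v])
      } else {
        z <- if (is.null(Ls)) 0 else as.numeric(grf_draw(Ls))
        a <- rnorm(2)
        dev <- config$ibd_sd *
          (as.numeric(g_shared %*% (w_shared * a)) + w_own * z)
        prob[, j] <- plogis(qlogis(p0[j]) + dev)[site_of_ind]
      }
    }
    n_clamped <- sum(prob < 0.01 | prob > 0.99)
    if (n_clamped > 0)
      message("simulate_genotypes: clamped ", n_clamped,
              " allele frequencies to [0.01, 0.99]")
    prob <- pmin(pmax(prob, 0.01), 0.99)

    dos <- matrix(rbinom(n_ind * n_total, 2L, prob), n_ind, n_total)
    depth <- matrix(5L + rpois(n_ind * n_total, 10), n_ind, n_total)
    if (config$missing_rate > 0) {
      miss <- matrix(runif(n_ind * n_total) < config$missing_rate, n_ind, n_total)
      dos[miss] <- NA
      depth[miss] <- sample(0:4, sum(miss), replace = TRUE)
    }

    # variant metadata across 12 chromosomes, positions strictly increasing
    chrom <- sprintf("chr%02d", as.integer(cut(seq_len(n_total), 12, labels = FALSE)))
    pos <- integer(n_total)
    for (ch in unique(chrom)) {
      n_ch <- sum(chrom == ch)
      pos[chrom == ch] <- cumsum(sample(200:2000, n_ch, replace = TRUE))
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_total, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    variants <- data.frame(id = locus_ids, chrom = chrom, pos = pos,
                           ref = ref, alt = unname(alt),
                           mean_depth = colMeans(depth))

    # geographic coordinates of the scattered individuals (same
    # equirectangular mapping as the grid cells)
    mid_lat <- mean(recent$cells$lat)
    coords <- data.frame(
      sample_id = sprintf("ind%03d", seq_len(n_ind)),
      lon = config$origin_lon + px / (KM_PER_DEG * cos(mid_lat * pi / 180)),
      lat = config$origin_lat + py / KM_PER_DEG,
      site_id = sprintf("site%02d", site_of_ind))

    samples <- data.frame(id = coords$sample_id, lon = coords$lon,
                          lat = coords$lat, site = coords$site_id)
    gm <- genotype_matrix(dos, variants, samples, depth = depth)
    truth <- synthetic_truth(locus_ids[is_adaptive], locus_ids[!is_adaptive],
                             driver_of, effect_of)
    list(gm = gm, truth = truth, coords = coords, site_cells = site_cells)
  })
}

#' Write a synthetic fixture to disk
#'
#' Emits a VCF 4.2 file (GT and DP per genotype), one long-format CSV per
#' climate scenario, a sample-coordinate table and (optionally) a truth
#' table. The files round-trip losslessly through [load_genotypes()] and
#' [load_grid()].
#'
#' @param gm a [genotype_matrix()].
#' @param grids named list of [climate_grid()] objects.
#' @param coords sample coordinate data frame (`sample_id`, `lon`, `lat`,
#'   `site_id`).
#' @param out_dir output directory (created if absent).
#' @param truth optional [synthetic_truth()].
#' @return Named list of file paths.
#' @export
write_fixture <- function(gm, grids, coords, out_dir, truth = NULL) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    abort_ctx("cannot create output directory: ", out_dir)
  paths <- list(vcf = file.path(out_dir, "genotypes.vcf"),
                coords = file.path(out_dir, "samples.csv"))
  write_genotypes_vcf(gm, paths$vcf)
  write.csv(coords, paths$coords, row.names = FALSE, quote = FALSE)
  paths$grids <- character(0)
  for (nm in names(grids)) {
    p <- file.path(out_dir, paste0("grid_", nm, ".csv"))
    write_grid_csv(grids[[nm]], p)
    paths$grids[nm] <- p
  }
  if (!is.null(truth)) {
    paths$truth <- file.path(out_dir, "truth.csv")
    tr <- data.frame(
      locus_id = c(truth$adaptive_locus_ids, truth$neutral_locus_ids),
      class = rep(c("adaptive", "neutral"),
                  c(length(truth$adaptive_locus_ids),
                    length(truth$neutral_locus_ids))),
      driver = NA_character_, effect = NA_real_)
    tr$driver[match(names(truth$driver_of_locus), tr$locus_id)] <-
      unname(truth$driver_of_locus)
    tr$effect[match(names(truth$effect_of_locus), tr$locus_id)] <-
      unname(truth$effect_of_locus)
    write.csv(tr, paths$truth, row.names = FALSE, quote = FALSE)
  }
  paths
}
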