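# Config-driven end-to-end orchestration: synthetic fixture (or user files)
# -> QC -> climate prep -> structure/GEA -> outlier detection -> offset
# engines -> per-scenario surfaces -> seed-transfer priorities -> method
# comparison, with a JSON run manifest of parameters, seeds and checksums.

#' Default pipeline configuration
#'
#' Synthetic-mode configuration reproducing the package's reference study
#' design end to end. Every field can be overridden via `...` (nested lists
#' are replaced wholesale).
#'
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @param ... overrides of top-level config entries.
#' @return A config list for [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, out_dir = tempfile("adaptscape_run_"),
                                    ...) {
  cfg <- list(
    mode = "synthetic",
    synthetic = list(),                 # overrides for landscape_config()
    qc = list(min_gt_depth = 5, min_maf = 0.01, max_missing = 0.10,
              min_mean_depth = 5, ld_window = 50, ld_step = 10,
              ld_r2_max = 0.1),
    climate = list(r2_max = 0.7,
                   keep_priority = c("cwd", "rch", "run", "str", "tmn", "tmx")),
    structure = list(mantel_perm = 999, partition_perm = 99),
    outliers = list(alpha_scale = 0.01, n_axes = NULL, axis_alpha = 0.05,
                    n_axis_perm = 250, axis_test_subset = 100000),
    engines = c("gf", "rda", "gdm"),
    gf = list(n_trees = 500),
    rda = list(n_axes = 2),
    gdm = list(n_knots = 3),
    transfer = list(engine = "gf", scenario = NULL,  # NULL: last scenario
                    scopes = c("site", "radius", "range"), radius_km = 50,
                    focal_radius_km = 15),
    compare = list(k = 3, protected_fraction = 0.4),
    seed = seed, out_dir = out_dir)
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema validation with actionable messages; does not run anything.
#'
#' @param config config list, or path to a YAML file holding one.
#' @return List with `valid` (logical) and `errors` (character vector,
#'   empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      return(list(valid = FALSE, errors = paste("config file not found:", config)))
    config <- yaml::read_yaml(config)
  }
  errors <- character(0)
  if (is.null(config$seed)) errors <- c(errors, "missing 'seed'")
  if (is.null(config$out_dir)) errors <- c(errors, "missing 'out_dir'")
  mode <- config$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "files"))
    errors <- c(errors, "mode must be 'synthetic' or 'files'")
  bad_engines <- setdiff(config$engines %||% "gf", c("gf", "rda", "gdm"))
  if (length(bad_engines))
    errors <- c(errors, paste0("unknown engine tag(s) ",
                               paste(bad_engines, collapse = ", "),
                               "; known engines: gf, rda, gdm"))
  if (mode == "files") {
    for (p in c("vcf", "coords")) {
      path <- config$inputs[[p]]
      if (is.null(path)) errors <- c(errors, paste0("missing input path '", p, "'"))
      else if (!file.exists(path))
        errors <- c(errors, paste0("input '", p, "' not found: ", path))
    }
    for (g in names(config$inputs$grids %||% list())) {
      path <- config$inputs$grids[[g]]$path
      if (is.null(path) || !file.exists(path))
        errors <- c(errors, paste0("grid '", g, "' path missing or not found"))
    }
  }
  tr_eng <- config$transfer$engine %||% "gf"
  if (!tr_eng %in% (config$engines %||% "gf"))
    errors <- c(errors, paste0("transfer engine '", tr_eng,
                               "' is not among the fitted engines"))
  list(valid = length(errors) == 0, errors = errors)
}

scenario_meta <- function(key) {
  list(model = key$model, rcp = key$rcp, period = key$period, id = key$id)
}

#' Run the full landscape-genomics pipeline
#'
#' Executes QC, climate preparation, structure diagnostics, pRDA outlier
#' detection, the configured offset engines over every future scenario, the
#' seed-transfer analysis for each focal site, and the cross-method
#' comparison, writing every intermediate artifact plus a JSON manifest
#' (parameters, seeds, file checksums). Fails fast with the stage name;
#' artifacts of completed stages remain on disk.
#'
#' @param config config list (see [default_pipeline_config()]) or YAML path.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  chk <- validate_config(config)
  if (!chk$valid)
    abort_ctx("invalid config:\n  ", paste(chk$errors, collapse = "\n  "))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  files <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort_ctx("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  # --- fixture / inputs ------------------------------------------------------
  if ((config$mode %||% "synthetic") == "synthetic") {
    sim <- stage("simulate", {
      lc <- do.call(landscape_config,
                    c(config$synthetic, list(seed = seed)))
      grids <- make_climate_grids(lc)
      s <- simulate_genotypes(lc, grids)
      fx <- file.path(out_dir, "fixture")
      paths <- write_fixture(s$gm, grids, s$coords, fx, truth = s$truth)
      c(s, list(grids = grids, paths = paths, lc = lc))
    })
    vcf_path <- sim$paths$vcf
    coords <- sim$coords
    grids <- sim$grids
    files <- c(files, unlist(sim$paths))
  } else {
    sim <- NULL
    vcf_path <- config$inputs$vcf
    coords <- read.csv(config$inputs$coords)
    grids <- stage("load_grids", {
      gl <- lapply(names(config$inputs$grids), function(g) {
        gi <- config$inputs$grids[[g]]
        load_grid(gi$path, scenario_key(gi$model %||% g, gi$rcp %||% "none",
                                        gi$period %||% "recent"))
      })
      names(gl) <- names(config$inputs$grids)
      gl
    })
  }

  # --- genotype QC -----------------------------------------------------------
  qc <- stage("genotype_qc", {
    gm <- load_genotypes(vcf_path, min_gt_depth = config$qc$min_gt_depth)
    gm <- attach_sample_coords(gm, coords)
    fv <- filter_variants(gm, min_maf = config$qc$min_maf,
                          max_missing = config$qc$max_missing,
                          min_mean_depth = config$qc$min_mean_depth)
    lp <- ld_prune(fv$gm, window = config$qc$ld_window,
                   step = config$qc$ld_step, r2_max = config$qc$ld_r2_max)
    dir.create(file.path(out_dir, "qc"), showWarnings = FALSE)
    files <- c(files,
                write_qc_report(fv$report, file.path(out_dir, "qc", "filter_report.json")),
                write_qc_report(lp$report, file.path(out_dir, "qc", "ld_report.json")))
    list(gm = impute_major(lp$gm),
         counts = list(loaded = ncol(gm$dosages),
                       filtered = ncol(fv$gm$dosages),
                       ld_pruned = ncol(lp$gm$dosages)))
  })
  gm <- qc$gm

  # --- climate preparation ---------------------------------------------------
  clim <- stage("climate_prep", {
    recent <- grids$recent
    pruned <- prune_collinear(recent$values, r2_max = config$climate$r2_max,
                              keep_priority = config$climate$keep_priority)
    vars <- pruned$retained
    st <- climate_stats(recent$values[, vars, drop = FALSE])
    std_grids <- lapply(grids, function(g) {
      g$values <- g$values[, vars, drop = FALSE]
      standardize_climate(g, st)
    })
    at_pts <- extract_at_points(std_grids$recent, coords)
    list(vars = vars, stats = st, grids = std_grids, at_points = at_pts,
         removed = pruned$removed)
  })
  X_clim <- as.matrix(clim$at_points[, clim$vars, drop = FALSE])

  # --- structure diagnostics -------------------------------------------------
  struct <- stage("structure", {
    pca <- pca_genotypes(gm, n_axes = 10)
    geo_d <- haversine_matrix(gm$samples)
    gen_d <- as.matrix(dist(gm$dosages))
    env_d <- as.matrix(dist(X_clim))
    ibd <- mantel_test(gen_d, geo_d, n_perm = config$structure$mantel_perm,
                       seed = child_seed(seed, "ibd"))
    ibe <- partial_mantel_test(gen_d, env_d, geo_d,
                               n_perm = config$structure$mantel_perm,
                               seed = child_seed(seed, "ibe"))
    vp <- variance_partition(gm$dosages, X_clim,
                             geography_matrix(gm$samples),
                             pca$scores[, 1, drop = FALSE],
                             n_perm = config$structure$partition_perm,
                             seed = child_seed(seed, "vp"))
    dir.create(file.path(out_dir, "structure"), showWarnings = FALSE)
    files <- c(files, write_tsv_table(vp$table,
                  file.path(out_dir, "structure", "variance_partition.tsv")))
    list(pca = pca, ibd = ibd, ibe = ibe, partition = vp)
  })

  # --- pRDA outlier detection ------------------------------------------------
  out <- stage("outliers", {
    cond <- cbind(geography_matrix(gm$samples),
                  PC1 = struct$pca$scores[, 1])
    o <- prda_outliers(gm$dosages, X_clim, cond,
                       alpha_scale = config$outliers$alpha_scale,
                       n_axes = config$outliers$n_axes,
                       axis_alpha = config$outliers$axis_alpha,
                       n_axis_perm = config$outliers$n_axis_perm,
                       axis_test_subset = config$outliers$axis_test_subset,
                       seed = child_seed(seed, "outliers"))
    if (length(o$outlier_ids) == 0)
      abort_ctx("no candidate adaptive loci detected")
    dir.create(file.path(out_dir, "outliers"), showWarnings = FALSE)
    files <- c(files, write_outlier_table(o, gm$variants,
                  file.path(out_dir, "outliers", "outliers.tsv")))
    o
  })
  candidates <- out$outlier_ids

  # --- offset engines --------------------------------------------------------
  Y_cand <- gm$dosages[, candidates, drop = FALSE]
  future_ids <- setdiff(names(clim$grids), "recent")
  recent_std <- clim$grids$recent
  models <- stage("engines", {
    m <- list()
    if ("gf" %in% config$engines)
      m$gf <- fit_gradient_forest(Y_cand, X_clim,
                                  n_trees = config$gf$n_trees,
                                  seed = child_seed(seed, "gf"))
    if ("rda" %in% config$engines)
      m$rda <- fit_rda_offset(Y_cand, X_clim, n_axes = config$rda$n_axes)
    if ("gdm" %in% config$engines) {
      freqs <- site_allele_freqs(gm, candidates)
      site_clim <- t(vapply(rownames(freqs), function(s) {
        idx <- which(gm$samples$site == s)
        colMeans(X_clim[idx, , drop = FALSE])
      }, numeric(ncol(X_clim))))
      kn <- lapply(clim$vars, function(v)
        unname(quantile(recent_std$values[, v],
                        probs = seq(0, 1, length.out = config$gdm$n_knots))))
      names(kn) <- clim$vars
      m$gdm <- fit_gdm(freqs, site_clim, knots = kn)
    }
    m
  })

  surfaces <- stage("offsets", {
    dir.create(file.path(out_dir, "offsets"), showWarnings = FALSE)
    s <- list()
    for (eng in names(models)) {
      s[[eng]] <- list()
      for (fid in future_ids) {
        surf <- suppressMessages(
          predict_offset(models[[eng]], recent_std, clim$grids[[fid]]))
        s[[eng]][[fid]] <- surf
        files <- c(files, write_surface_csv(surf,
          file.path(out_dir, "offsets", paste0(eng, "_", fid, ".csv"))))
      }
    }
    s
  })

  # --- seed transfer ---------------------------------------------------------
  transfer <- stage("seed_transfer", {
    tr_cfg <- config$transfer
    eng <- tr_cfg$engine
    fid <- tr_cfg$scenario %||% future_ids[length(future_ids)]
    dir.create(file.path(out_dir, "transfer"), showWarnings = FALSE)
    res <- list(scenario = fid, engine = eng)
    if (!is.null(sim)) {
      # focal sites: the intensively sampled sites (largest collections)
      sizes <- table(sim$coords$site_id)
      focal_sites <- names(sort(sizes, decreasing = TRUE))[
        seq_len(min(3, length(sizes)))]
      cellmap <- setNames(sim$site_cells,
                          sprintf("site%02d", seq_along(sim$site_cells)))
      for (fs in sort(focal_sites)) {
        focal_ids <- radius_donors(recent_std$cells, cellmap[[fs]],
                                   scope = "radius",
                                   radius_km = tr_cfg$focal_radius_km)
        recip <- subset_grid(clim$grids[[fid]], focal_ids)
        base <- baseline_adaptedness(models[[eng]], recent_std,
                                     clim$grids[[fid]], cells = focal_ids)
        for (sc in tr_cfg$scopes) {
          donor_ids <- radius_donors(recent_std$cells, focal_ids, scope = sc,
                                     radius_km = tr_cfg$radius_km)
          tm <- pairwise_transfer(models[[eng]],
                                  subset_grid(recent_std, donor_ids), recip)
          pr <- seed_source_priority(tm, base)
          p <- file.path(out_dir, "transfer",
                         paste0("priority_", fs, "_", sc, ".csv"))
          write.csv(as.data.frame(pr), p, row.names = FALSE, quote = FALSE)
          files <- c(files, p)
          res[[fs]][[sc]] <- pr
        }
      }
    }
    res
  })

  # --- model comparison ------------------------------------------------------
  comparison <- stage("compare", {
    dir.create(file.path(out_dir, "compare"), showWarnings = FALSE)
    res <- list()
    if (length(models) >= 2) {
      sp <- lapply(future_ids, function(fid)
        spearman_table(lapply(surfaces, `[[`, fid)))
      names(sp) <- future_ids
      res$spearman <- sp
      sp_long <- do.call(rbind, lapply(future_ids, function(fid) {
        m <- sp[[fid]]
        idx <- which(upper.tri(m), arr.ind = TRUE)
        data.frame(scenario = fid, method_a = rownames(m)[idx[, 1]],
                   method_b = colnames(m)[idx[, 2]], rho = m[idx])
      }))
      files <- c(files, write_tsv_table(sp_long,
                    file.path(out_dir, "compare", "spearman.tsv")))
      vec_engines <- intersect(names(models), c("gf", "rda"))
      cfgs <- lapply(models, method_configuration, grid = recent_std,
                     k = config$compare$k, seed = child_seed(seed, "procrustes"))
      prs <- list()
      pairs <- utils::combn(names(models), 2, simplify = FALSE)
      for (pp in pairs) {
        shared <- intersect(rownames(cfgs[[pp[1]]]), rownames(cfgs[[pp[2]]]))
        prs[[paste(pp, collapse = "_vs_")]] <- procrustes_residuals(
          cfgs[[pp[1]]][shared, , drop = FALSE],
          cfgs[[pp[2]]][shared, , drop = FALSE],
          n_perm = 199, seed = child_seed(seed, paste(pp, collapse = "-")))
      }
      res$procrustes <- prs
    }
    # protection ANOVA on the transfer engine's surfaces across scenarios
    eng <- config$transfer$engine
    if (eng %in% names(surfaces) && length(future_ids) >= 2 && !is.null(sim)) {
      prot_ids <- with_seed(child_seed(seed, "protection"), {
        L <- grf_chol(recent_std$cells[, c("x", "y")],
                      0.2 * max(recent_std$cells$x))
        f <- as.numeric(grf_draw(L))
        recent_std$cells$cell_id[
          f > quantile(f, 1 - config$compare$protected_fraction)]
      })
      av_data <- do.call(rbind, lapply(future_ids, function(fid) {
        key <- clim$grids[[fid]]$scenario
        s <- surfaces[[eng]][[fid]]
        data.frame(adaptedness = s$adaptedness,
                   protection = ifelse(s$cell_id %in% prot_ids,
                                       "protected", "unprotected"),
                   model = key$model, rcp = key$rcp, year = key$period)
      }))
      if (length(unique(av_data$rcp)) >= 2) {
        res$anova <- protection_anova(av_data)
        files <- c(files, write_tsv_table(res$anova$table,
                      file.path(out_dir, "compare", "protection_anova.tsv")))
      }
      res$protected_cells <- prot_ids
    }
    res
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("adaptscape")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    counts = c(qc$counts,
               list(n_candidates = length(candidates),
                    retained_axes = out$retained_axes,
                    gif = out$gif)),
    climate_variables = clim$vars,
    scenarios = lapply(clim$grids, function(g) scenario_meta(g$scenario)),
    files = {
      rel <- sub(paste0(normalizePath(out_dir), "/"), "",
                 normalizePath(files), fixed = TRUE)
      as.list(setNames(unname(tools::md5sum(files)), rel))
    })
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(manifest,
              list(results = list(qc = qc, structure = struct, outliers = out,
                                  models = models, surfaces = surfaces,
                                  transfer = transfer,
                                  comparison = comparison))))
}
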