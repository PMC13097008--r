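# Core data containers shared across the pipeline.

#' Construct a genotype matrix
#'
#' The central genotype container: an individuals x SNPs dosage matrix
#' (0/1/2 copies of the alternate allele, `NA` = missing) together with
#' per-variant and per-sample metadata.
#'
#' @param dosages integer matrix, individuals in rows, SNPs in columns.
#'   Row names are sample ids, column names are variant ids.
#' @param variants data frame with one row per SNP: `id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `mean_depth`.
#' @param samples data frame with one row per individual: `id` and optionally
#'   `lon`, `lat`, `site`.
#' @param depth optional integer matrix of per-genotype sequencing depths,
#'   same shape as `dosages` (kept for VCF round-trips).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples, depth = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(samples))
    abort_ctx("dosages rows (", nrow(dosages), ") != samples rows (", nrow(samples), ")")
  if (ncol(dosages) != nrow(variants))
    abort_ctx("dosages columns (", ncol(dosages), ") != variants rows (", nrow(variants), ")")
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) abort_ctx("dosages must be 0, 1, 2 or NA")
  if (any(grepl(",", variants$alt, fixed = TRUE)))
    abort_ctx("multi-allelic variant in metadata; one alt allele per retained variant")
  # positions strictly increasing within each chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      abort_ctx("variant positions not strictly increasing on ", ch)
  }
  rownames(dosages) <- samples$id
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, samples = samples,
                 depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat("genotype_matrix:", nrow(x$dosages), "individuals x", ncol(x$dosages),
      "SNPs;", sprintf("%.2f%%", 100 * miss), "missing\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Attach sample coordinates to a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param coords data frame with `sample_id` (or `id`), `lon`, `lat` and
#'   optionally `site_id` (or `site`).
#' @return The genotype matrix with `lon`, `lat`, `site` filled in.
#' @export
attach_sample_coords <- function(gm, coords) {
  idcol <- if ("sample_id" %in% names(coords)) "sample_id" else "id"
  sitecol <- if ("site_id" %in% names(coords)) "site_id" else "site"
  idx <- match(gm$samples$id, coords[[idcol]])
  if (anyNA(idx))
    abort_ctx("coordinates missing for samples: ",
              paste(head(gm$samples$id[is.na(idx)], 5), collapse = ", "))
  gm$samples$lon <- coords$lon[idx]
  gm$samples$lat <- coords$lat[idx]
  if (sitecol %in% names(coords)) gm$samples$site <- coords[[sitecol]][idx]
  gm
}

#' Construct a climate-scenario key
#'
#' @param model climate model label; `"recent"` for the contemporary baseline.
#' @param rcp representative concentration pathway label (`"none"`, `"4.5"`,
#'   `"8.5"`).
#' @param period period label, e.g. `"2070-2099"`.
#' @return An object of class `scenario_key`.
#' @export
scenario_key <- function(model = "recent", rcp = "none", period = "recent") {
  if (identical(model, "recent") && !identical(rcp, "none"))
    abort_ctx("the recent scenario has rcp = 'none'")
  structure(list(model = model, rcp = rcp, period = period,
                 id = if (identical(model, "recent")) "recent"
                      else paste(model, rcp, period, sep = "_")),
            class = "scenario_key")
}

#' @export
format.scenario_key <- function(x, ...) x$id

#' @export
print.scenario_key <- function(x, ...) {
  cat("scenario:", x$id, "\n"); invisible(x)
}

#' Construct a climate grid
#'
#' Cells x climate-variables for one scenario. `cells` carries the cell
#' geometry; the `values` matrix holds one column per climate variable.
#'
#' @param cells data frame with `cell_id`, `x`, `y` (planar km) and `lon`,
#'   `lat` (degrees).
#' @param values numeric matrix, cells in rows, variables in columns.
#' @param scenario a [scenario_key()].
#' @param cell_size cell edge length in km.
#' @param crs free-text note on the coordinate system.
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(cells, values, scenario, cell_size, crs = "synthetic equirectangular") {
  values <- as.matrix(values)
  if (nrow(values) != nrow(cells)) abort_ctx("values rows != cells rows")
  if (anyNA(values)) abort_ctx("climate grid contains NA in retained cells")
  if (is.null(colnames(values))) abort_ctx("climate variables must be named")
  rownames(values) <- cells$cell_id
  structure(list(cells = cells, values = values, variables = colnames(values),
                 scenario = scenario, cell_size = cell_size, crs = crs),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("climate_grid [", x$scenario$id, "]: ", nrow(x$cells), " cells x ",
      length(x$variables), " variables (", paste(x$variables, collapse = ", "),
      "); cell size ", x$cell_size, " km\n", sep = "")
  invisible(x)
}

#' Restrict a climate grid to a subset of cells
#' @param grid a [climate_grid()].
#' @param cell_ids cell ids to keep (order preserved as given).
#' @return A [climate_grid()] with only those cells.
#' @export
subset_grid <- function(grid, cell_ids) {
  idx <- match(cell_ids, grid$cells$cell_id)
  if (anyNA(idx)) abort_ctx("unknown cell ids: ",
                            paste(head(cell_ids[is.na(idx)], 5), collapse = ", "))
  climate_grid(grid$cells[idx, , drop = FALSE],
               grid$values[idx, , drop = FALSE],
               grid$scenario, grid$cell_size, grid$crs)
}
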