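# Climate scenario handling: long-CSV grid I/O, nearest-cell extraction at
# sample points, collinearity pruning, and recent-scenario standardization.

#' Write a climate grid as a long-format CSV
#'
#' Columns: `cell_id`, `x`, `y`, `lon`, `lat`, `variable`, `value`.
#'
#' @param grid a [climate_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  long <- do.call(rbind, lapply(grid$variables, function(v)
    data.frame(cell_id = grid$cells$cell_id, x = grid$cells$x,
               y = grid$cells$y, lon = grid$cells$lon, lat = grid$cells$lat,
               variable = v, value = grid$values[, v])))
  tryCatch(write.csv(long, path, row.names = FALSE, quote = FALSE),
           error = function(e) abort_ctx("cannot write grid '", path, "': ",
                                         conditionMessage(e)))
  invisible(path)
}

#' Load a climate grid from long-format CSV layers
#'
#' Accepts one long CSV holding all variables or several (e.g. one per
#' variable); all layers must share cell geometry exactly. Cells with any
#' missing variable value are dropped with a message.
#'
#' @param paths one or more CSV paths (columns `cell_id`, `x`, `y`, `lon`,
#'   `lat`, `variable`, `value`).
#' @param scenario a [scenario_key()].
#' @param variables optional variable ordering; default is order of first
#'   appearance.
#' @param cell_size cell edge length in km; inferred from the x spacing when
#'   omitted.
#' @return A [climate_grid()].
#' @export
load_grid <- function(paths, scenario, variables = NULL, cell_size = NULL) {
  longs <- lapply(paths, function(p) {
    if (!file.exists(p)) abort_ctx("grid file not found: ", p)
    read.csv(p, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, longs)
  needed <- c("cell_id", "x", "y", "variable", "value")
  if (!all(needed %in% names(long)))
    abort_ctx("grid CSV must have columns ", paste(needed, collapse = ", "))
  if (!"lon" %in% names(long)) long$lon <- NA_real_
  if (!"lat" %in% names(long)) long$lat <- NA_real_

  vars <- variables %||% unique(long$variable)
  cell_ids <- unique(long$cell_id)
  geom <- long[!duplicated(long$cell_id),
               c("cell_id", "x", "y", "lon", "lat")]
  # geometry must agree across layers
  chk <- unique(long[, c("cell_id", "x", "y")])
  if (nrow(chk) != length(cell_ids))
    abort_ctx("geometry mismatch across layers: same cell_id with different coordinates")
  per_var_cells <- table(long$variable)
  if (length(unique(per_var_cells)) > 1 ||
      any(!vars %in% names(per_var_cells)))
    abort_ctx("geometry mismatch: variables cover different cell sets")

  values <- matrix(NA_real_, length(cell_ids), length(vars),
                   dimnames = list(cell_ids, vars))
  for (v in vars) {
    sub <- long[long$variable == v, ]
    values[match(sub$cell_id, cell_ids), v] <- sub$value
  }
  ok <- complete.cases(values)
  if (!all(ok))
    message("load_grid: dropped ", sum(!ok), " cells with missing values")
  geom <- geom[match(cell_ids, geom$cell_id), ][ok, , drop = FALSE]
  rownames(geom) <- NULL
  if (is.null(cell_size)) {
    dx <- diff(sort(unique(geom$x)))
    cell_size <- if (length(dx)) min(dx[dx > 0]) else 1
  }
  climate_grid(geom, values[ok, , drop = FALSE], scenario, cell_size)
}

#' Extract climate values at sample points by nearest-cell assignment
#'
#' Each point is assigned the grid cell whose center is nearest (great-circle
#' distance on lon/lat); a point equidistant to several centers takes the
#' lowest `cell_id`. Points outside the grid's bounding box (cell centers
#' padded by half a cell) raise an error listing the offending samples.
#'
#' @param grid a [climate_grid()].
#' @param coords data frame with `sample_id` (or `id`), `lon`, `lat`.
#' @return Data frame: `sample_id`, `cell_id`, then one column per climate
#'   variable.
#' @export
extract_at_points <- function(grid, coords) {
  idcol <- if ("sample_id" %in% names(coords)) "sample_id" else "id"
  half <- grid$cell_size / 2 + 1e-9
  pad_lat <- half / KM_PER_DEG
  mid_lat <- mean(grid$cells$lat)
  pad_lon <- half / (KM_PER_DEG * cos(mid_lat * pi / 180))
  out_of_bounds <- coords$lon < min(grid$cells$lon) - pad_lon |
    coords$lon > max(grid$cells$lon) + pad_lon |
    coords$lat < min(grid$cells$lat) - pad_lat |
    coords$lat > max(grid$cells$lat) + pad_lat
  if (any(out_of_bounds))
    abort_ctx("points outside grid bounds: ",
              paste(head(coords[[idcol]][out_of_bounds], 10), collapse = ", "))
  cell_of <- vapply(seq_len(nrow(coords)), function(i) {
    dx <- (coords$lon[i] - grid$cells$lon) * KM_PER_DEG * cos(mid_lat * pi / 180)
    dy <- (coords$lat[i] - grid$cells$lat) * KM_PER_DEG
    d <- dx^2 + dy^2
    cand <- which(d <= min(d) + 1e-9)
    cand[order(grid$cells$cell_id[cand])][1]  # tie: lowest cell_id
  }, 0L)
  cbind(data.frame(sample_id = coords[[idcol]],
                   cell_id = grid$cells$cell_id[cell_of]),
        as.data.frame(grid$values[cell_of, , drop = FALSE], row.names = FALSE))
}

#' Prune collinear climate variables
#'
#' Iteratively, while any variable pair has squared Pearson correlation above
#' `r2_max` (computed over rows of `table`), the member ranked lower in
#' `keep_priority` is removed. Variables absent from `keep_priority` rank
#' below all listed ones (alphabetical among themselves). The retained set
#' never becomes empty and is independent of input column order.
#'
#' @param table matrix or data frame, observations (cells) x variables.
#' @param r2_max squared-correlation threshold (default 0.7).
#' @param keep_priority character vector, most-preferred first.
#' @return List with `retained` (character, in input order) and `removed`
#'   (data frame `variable`, `partner`, `r2`).
#' @export
prune_collinear <- function(table, r2_max = 0.7, keep_priority = character(0)) {
  tab <- as.matrix(table)
  vars <- colnames(tab)
  if (length(vars) < 2) abort_ctx("prune_collinear: need at least 2 variables")
  rank_of <- function(v) {
    r <- match(v, keep_priority)
    ifelse(is.na(r), length(keep_priority) + 1 + match(v, sort(vars)), r)
  }
  active <- vars
  removed <- data.frame(variable = character(0), partner = character(0),
                        r2 = numeric(0))
  repeat {
    if (length(active) < 2) break
    r2 <- suppressWarnings(cor(tab[, active, drop = FALSE]))^2
    r2[is.na(r2)] <- 1  # a zero-variance duplicate counts as fully collinear
    r2[lower.tri(r2, diag = TRUE)] <- -Inf
    # deterministic worst pair: max r2, ties by priority rank then name
    offending <- which(r2 > r2_max, arr.ind = TRUE)
    if (nrow(offending) == 0) break
    vals <- r2[offending]
    pick <- offending[order(-vals, pmin(rank_of(active[offending[, 1]]),
                                        rank_of(active[offending[, 2]])))[1], ]
    a <- active[pick[1]]; b <- active[pick[2]]
    drop <- if (rank_of(a) <= rank_of(b)) b else a
    removed <- rbind(removed,
                     data.frame(variable = drop, partner = setdiff(c(a, b), drop),
                                r2 = r2[pick[1], pick[2]]))
    active <- setdiff(active, drop)
  }
  list(retained = vars[vars %in% active], removed = removed)
}

#' Summarize climate means and SDs (the standardization reference)
#'
#' @param x a [climate_grid()] or a numeric matrix/data frame of
#'   observations x variables (typically the recent scenario).
#' @return An object of class `climate_stats` (`mean`, `sd` per variable).
#' @export
climate_stats <- function(x) {
  vals <- if (inherits(x, "climate_grid")) x$values else as.matrix(x)
  m <- colMeans(vals)
  s <- apply(vals, 2, sd)
  zero <- names(s)[s == 0]
  if (length(zero))
    abort_ctx("zero-variance variable(s): ", paste(zero, collapse = ", "))
  structure(list(mean = m, sd = s), class = "climate_stats")
}

#' Standardize climate values using reference statistics
#'
#' Applies `(v - mean_ref) / sd_ref` with statistics taken from `stats_from`
#' (typically the recent scenario), to a grid or a table of any scenario.
#'
#' @param x a [climate_grid()] or matrix/data frame (observations x
#'   variables).
#' @param stats_from a `climate_stats` object, or anything accepted by
#'   [climate_stats()]; default: statistics of `x` itself.
#' @return Object of the same type as `x`, standardized; the statistics used
#'   are attached as attribute `"climate_stats"`.
#' @export
standardize_climate <- function(x, stats_from = NULL) {
  st <- if (inherits(stats_from, "climate_stats")) stats_from
        else climate_stats(stats_from %||% x)
  apply_st <- function(vals) {
    vars <- colnames(vals)
    if (!all(vars %in% names(st$mean)))
      abort_ctx("standardization statistics missing for: ",
                paste(setdiff(vars, names(st$mean)), collapse = ", "))
    sweep(sweep(vals, 2, st$mean[vars]), 2, st$sd[vars], "/")
  }
  if (inherits(x, "climate_grid")) {
    x$values <- apply_st(x$values)
    attr(x, "climate_stats") <- st
    x
  } else {
    out <- apply_st(as.matrix(x))
    attr(out, "climate_stats") <- st
    out
  }
}

#' Invert a climate standardization
#' @param x standardized grid or matrix.
#' @param stats the `climate_stats` used to standardize (default: the
#'   attribute stored by [standardize_climate()]).
#' @return `x` on the original scale.
#' @export
unstandardize_climate <- function(x, stats = attr(x, "climate_stats")) {
  if (is.null(stats)) abort_ctx("no climate_stats supplied or attached")
  inv <- function(vals) {
    vars <- colnames(vals)
    sweep(sweep(vals, 2, stats$sd[vars], "*"), 2, stats$mean[vars], "+")
  }
  if (inherits(x, "climate_grid")) {
    x$values <- inv(x$values)
    attr(x, "climate_stats") <- NULL
    x
  } else {
    out <- inv(as.matrix(x))
    attr(out, "climate_stats") <- NULL
    out
  }
}
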