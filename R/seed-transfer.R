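# Donor-recipient seed-transfer analysis: dense transfer matrices of
# offsets between donor cells (current climate) and recipient cells (future
# climate), forward/reverse adaptedness summaries, the no-transfer baseline,
# seed-source priority, and radius-restricted donor search.

#' Dense donor x recipient transfer matrix
#'
#' Entry (d, r) is the engine's offset between donor cell d's current
#' climate and recipient cell r's future climate — the same pairwise
#' quantity underlies both the forward and the reverse adaptedness
#' summaries. Adaptedness is -1 x offset.
#'
#' @param model a fitted offset engine.
#' @param donors donor [climate_grid()] (current scenario), possibly a
#'   [subset_grid()] of the range.
#' @param recipients recipient [climate_grid()] (future scenario).
#' @return Object of class `transfer_matrix`: `offset` (donors x
#'   recipients), `donors`, `recipients` (cell ids), `method`,
#'   `scenario_pair`.
#' @export
pairwise_transfer <- function(model, donors, recipients) {
  if (nrow(donors$cells) == 0 || nrow(recipients$cells) == 0)
    abort_ctx("pairwise_transfer: empty donor or recipient set")
  a <- clamp_to_train(model, donors$values, quiet = TRUE)
  b <- clamp_to_train(model, recipients$values, quiet = TRUE)
  off <- pairwise_offset(model, a, b)
  dimnames(off) <- list(donors$cells$cell_id, recipients$cells$cell_id)
  structure(list(offset = off, donors = donors$cells$cell_id,
                 recipients = recipients$cells$cell_id,
                 donor_cells = donors$cells, method = engine_tag(model),
                 scenario_pair = list(from = donors$scenario,
                                      to = recipients$scenario)),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("transfer_matrix [", x$method, "] ", length(x$donors), " donors x ",
      length(x$recipients), " recipients (",
      x$scenario_pair$from$id, " -> ", x$scenario_pair$to$id, ")\n", sep = "")
  invisible(x)
}

#' Adaptedness values of a transfer matrix
#' @param tm a `transfer_matrix`.
#' @return Matrix of adaptedness (-1 x offset), donors x recipients.
#' @export
transfer_adaptedness <- function(tm) -tm$offset

#' Mean reverse adaptedness of each donor
#'
#' Each donor's adaptedness averaged across all recipient cells: how good
#' the donor would be, on average, as a seed source for the whole focal
#' site under future climate (0 is the maximum).
#'
#' @param tm a `transfer_matrix`.
#' @return Named numeric vector, one mean adaptedness per donor.
#' @export
reverse_adaptedness <- function(tm) {
  if (length(tm$offset) == 0) abort_ctx("empty transfer matrix")
  rowMeans(transfer_adaptedness(tm))
}

#' Mean forward adaptedness of each recipient
#'
#' Each recipient's adaptedness averaged across donor cells: how good the
#' recipient cell would be, on average, as a planting location for the
#' focal site's seeds.
#'
#' @param tm a `transfer_matrix`.
#' @return Named numeric vector, one mean adaptedness per recipient.
#' @export
forward_adaptedness <- function(tm) {
  if (length(tm$offset) == 0) abort_ctx("empty transfer matrix")
  colMeans(transfer_adaptedness(tm))
}

#' Baseline adaptedness of recipient cells (no seed transfer)
#'
#' For each focal cell, the adaptedness between its own current and future
#' climate — the diagonal concept of the transfer problem.
#'
#' @param model a fitted offset engine.
#' @param grid_now,grid_future [climate_grid()]s sharing cells.
#' @param cells optional cell ids restricting to the focal site.
#' @return Named numeric vector of baseline adaptedness per cell.
#' @export
baseline_adaptedness <- function(model, grid_now, grid_future, cells = NULL) {
  if (!is.null(cells)) {
    grid_now <- subset_grid(grid_now, cells)
    grid_future <- subset_grid(grid_future, cells)
  }
  surf <- suppressMessages(predict_offset(model, grid_now, grid_future))
  setNames(surf$adaptedness, surf$cell_id)
}

#' Seed-source priority of donor cells
#'
#' Builds the binary improvement matrix `B(d, r) = 1` iff the donor's
#' post-transfer adaptedness at recipient r is strictly higher than the
#' recipient's baseline adaptedness (ties count as no improvement), and
#' returns each donor's improved fraction `sum_r B(d, r) / n_recipients`.
#'
#' @param tm a `transfer_matrix`.
#' @param baseline named baseline adaptedness covering all recipients of
#'   `tm` (see [baseline_adaptedness()]).
#' @return Object of class `seed_priority`: data frame with `donor`,
#'   `priority` (fraction in `[0, 1]`), `mean_reverse_adaptedness`,
#'   `n_recipients`.
#' @export
seed_source_priority <- function(tm, baseline) {
  missing_r <- setdiff(tm$recipients, names(baseline))
  if (length(missing_r))
    abort_ctx("baseline missing for recipients: ",
              paste(head(missing_r, 5), collapse = ", "))
  A <- transfer_adaptedness(tm)
  B <- sweep(A, 2, baseline[tm$recipients], ">")
  out <- data.frame(donor = tm$donors,
                    priority = rowMeans(B),
                    mean_reverse_adaptedness = rowMeans(A),
                    n_recipients = length(tm$recipients))
  structure(out, class = c("seed_priority", "data.frame"),
            method = tm$method, scenario_pair = tm$scenario_pair)
}

#' Select donor cells for a focal site by scope
#'
#' `"site"`: the focal cells themselves; `"radius"`: all cells whose
#' Haversine distance to the nearest focal cell is at most `radius_km`
#' (which includes the focal cells); `"range"`: every cell.
#'
#' @param cells cell data frame (`cell_id`, `lon`, `lat`), typically a
#'   grid's `$cells` restricted to the species range.
#' @param focal_ids cell ids of the focal site.
#' @param scope `"site"`, `"radius"` or `"range"`.
#' @param radius_km search radius for the `"radius"` scope (default 50).
#' @return Character vector of donor cell ids.
#' @export
radius_donors <- function(cells, focal_ids, scope = c("radius", "site", "range"),
                          radius_km = 50) {
  scope <- match.arg(scope)
  if (!all(focal_ids %in% cells$cell_id))
    abort_ctx("focal cells not present in cell table")
  if (scope == "site") return(intersect(cells$cell_id, focal_ids))
  if (scope == "range") return(cells$cell_id)
  focal <- cells[cells$cell_id %in% focal_ids, , drop = FALSE]
  dmin <- apply(geosphere::distm(
    as.matrix(cells[, c("lon", "lat")]),
    as.matrix(focal[, c("lon", "lat")]),
    fun = function(a, b) geosphere::distHaversine(a, b, r = 6371000)),
    1, min) / 1000
  cells$cell_id[dmin <= radius_km + 1e-9]
}
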