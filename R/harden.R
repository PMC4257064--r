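#' Hard (boolean) risk classification constrained by a target area
#'
#' Converts a soft risk map into the area-constrained hard prediction:
#' candidate thresholds are taken on the quantized ladder
#' `{1.00, 0.99, ..., 0.00}` (step `quantum`), cells selected at a threshold
#' are the currently forested, non-nodata cells with risk at or above it,
#' and the chosen threshold is the ladder value whose selected area is
#' nearest the target (ties resolved toward the higher threshold, i.e. the
#' smaller selection). Larger targets never raise the chosen threshold.
#'
#' @param risk soft risk `grid_raster` (logistic scale, values in [0, 1]).
#' @param forest_mask forest mask grid; only its TRUE, non-nodata cells are
#'   selectable.
#' @param target_area_ha the projected loss to accommodate (ha); must not
#'   exceed the forest area.
#' @param quantum threshold ladder step (default 0.01, i.e. whole percents).
#' @return object of class `hard_map`: `selected` mask grid, `threshold`
#'   (p*), `target_area_ha`, `achieved_area_ha`.
#' @export
harden <- function(risk, forest_mask, target_area_ha, quantum = 0.01) {
  stopifnot(inherits(risk, "grid_raster"), inherits(forest_mask, "grid_raster"),
            target_area_ha >= 0, quantum > 0, quantum <= 1)
  check_aligned(risk, forest_mask, "risk", "forest_mask")
  eligible <- forest_mask$values > 0 & !is.na(forest_mask$values) &
    !is.na(risk$values)
  cell_ha <- cell_area_ha(risk)
  forest_area <- sum(eligible) * cell_ha
  if (target_area_ha > forest_area)
    stop(sprintf("target area %.1f ha exceeds forest area %.1f ha",
                 target_area_ha, forest_area))
  p <- risk$values[eligible]
  n_steps <- round(1 / quantum)
  ladder <- (n_steps:0) / n_steps                 # 1.00 down to 0.00, exact
  areas <- vapply(ladder, function(th) sum(p >= th) * cell_ha, numeric(1))
  best <- which.min(abs(areas - target_area_ha))  # first hit = higher threshold
  thr <- ladder[best]
  sel <- matrix(FALSE, nrow(risk$values), ncol(risk$values))
  sel[eligible] <- p >= thr
  structure(list(selected = grid_raster(sel, risk$cell_size_m, risk$origin),
                 threshold = thr, target_area_ha = target_area_ha,
                 achieved_area_ha = areas[best]),
            class = "hard_map")
}

#' @export
print.hard_map <- function(x, ...) {
  cat(sprintf("<hard_map> p* = %.2f: %g ha selected (target %g ha)\n",
              x$threshold, x$achieved_area_ha, x$target_area_ha))
  invisible(x)
}

#' Carbon and CO2 at risk in a hard prediction
#'
#' Sums a per-cell carbon density grid over the selected cells when one is
#' available, otherwise multiplies the achieved area by the median density
#' in `params`; CO2 follows via the conversion factor.
#'
#' @param hard a [harden()] result.
#' @param params a [carbon_params()]; used when `carbon_grid` is `NULL`.
#' @param carbon_grid optional `grid_raster` of Mg C per ha.
#' @return list with `carbon_mg` and `co2_mg`.
#' @export
carbon_at_risk <- function(hard, params = carbon_params(), carbon_grid = NULL) {
  stopifnot(inherits(hard, "hard_map"))
  if (!is.null(carbon_grid)) {
    check_aligned(hard$selected, carbon_grid, "hard map", "carbon_grid")
    sel <- hard$selected$values > 0
    carbon_mg <- sum(carbon_grid$values[sel] * cell_area_ha(carbon_grid),
                     na.rm = TRUE)
    list(carbon_mg = carbon_mg, co2_mg = carbon_mg * params$co2_per_c)
  } else {
    emissions(hard$achieved_area_ha, params)
  }
}

#' Plain-text summary of a hard prediction
#' @param hard a [harden()] result.
#' @param params a [carbon_params()].
#' @param path output path.
#' @export
write_hard_summary <- function(hard, params = carbon_params(), path) {
  em <- carbon_at_risk(hard, params)
  writeLines(c(
    sprintf("threshold_p=%.2f", hard$threshold),
    sprintf("target_area_ha=%.10g", hard$target_area_ha),
    sprintf("achieved_area_ha=%.10g", hard$achieved_area_ha),
    sprintf("carbon_mg=%.10g", em$carbon_mg),
    sprintf("co2_mg=%.10g", em$co2_mg)), path)
  invisible(path)
}
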