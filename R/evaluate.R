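#' Validation point sets from later observed change
#'
#' Builds the two point groups used to validate a risk map against change
#' observed in a later period: the centroids of consensus-deforested patches
#' of at least `min_patch_ha` (8-connected), and random study-area points
#' kept only where forest was stable over the period (no-change points).
#' Patch centroids are snapped to the nearest cell for risk extraction.
#'
#' @param change a [consensus()] change layer for the validation period.
#' @param min_patch_ha minimum patch area in ha, inclusive (default 10).
#' @param n_nochange number of no-change points to draw (default 500); drawn
#'   uniformly over the study area then filtered to stable-forest cells, so
#'   fewer may be returned.
#' @param seed RNG seed.
#' @return list with data.frames `deforested` (patch centroids: `id`, `row`,
#'   `col`, `x`, `y`, `area_ha`) and `nochange` (`id`, `row`, `col`, `x`,
#'   `y`, `class`).
#' @export
validation_points <- function(change, min_patch_ha = 10, n_nochange = 500,
                              seed = 1) {
  stopifnot(inherits(change, "change_layer"))
  cp <- connected_patches(change$deforested)
  keep <- cp$patches[cp$patches$area_ha >= min_patch_ha, ]
  if (!nrow(keep))
    stop(sprintf("no deforested patches of at least %g ha", min_patch_ha))
  defo <- data.frame(id = seq_len(nrow(keep)),
                     row = round(keep$centroid_row),
                     col = round(keep$centroid_col),
                     x = keep$centroid_x, y = keep$centroid_y,
                     area_ha = keep$area_ha)
  # candidates over the whole study area, then keep stable-forest hits
  study <- grid_raster(!nodata_mask(change$undetermined),
                       change$deforested$cell_size_m, change$deforested$origin)
  cand <- sample_cells(study, min(n_nochange, sum(study$values > 0)), seed,
                       "no_change")
  stable <- change$stable_forest$values[cbind(cand$row, cand$col)] > 0
  nochange <- cand[stable, , drop = FALSE]
  nochange$id <- seq_len(nrow(nochange))
  list(deforested = defo, nochange = nochange)
}

#' Mann-Whitney U test (rank-sum) with exact small-sample p-value
#'
#' U counts, over all cross pairs, the times an `a` value exceeds a `b`
#' value (ties count one half); the reported statistic is the smaller of U
#' and `n_a * n_b - U`. The two-sided p-value uses the exact U distribution
#' when there are no ties and `n_a * n_b <= 400`, and otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric samples.
#' @return list with `U`, `p_value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na > 0, nb > 0)
  r <- rank(c(a, b))
  U_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2    # pairs where a beats b
  U <- min(U_a, na * nb - U_a)
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && na * nb <= 400) {
    # exact distribution of U under the null (equivalent to enumerating all
    # orderings), folded two-sided
    p <- 2 * stats::pwilcox(U, na, nb)
    p <- min(p, 1)
    method <- "exact"
  } else {
    n <- na + nb
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    if (sigma == 0) return(list(U = U, p_value = 1, method = "normal"))
    z <- (U - mu + 0.5) / sigma                     # continuity correction
    p <- min(2 * stats::pnorm(z), 1)
    method <- "normal"
  }
  list(U = U, p_value = p, method = method)
}

#' Validate a risk map against later observed change
#'
#' Extracts predicted risk at deforested-patch centroids and no-change
#' points, summarizes each group (mean and SD of risk), contrasts them with
#' the Mann-Whitney U test, and bins both groups into a risk histogram
#' (default 10 bins of width 0.1).
#'
#' @param risk soft risk `grid_raster` in [0, 1].
#' @param change a [consensus()] change layer for the later period.
#' @param min_patch_ha,n_nochange,seed passed to [validation_points()].
#' @param bins number of histogram bins over [0, 1] (default 10).
#' @return object of class `validation_report`.
#' @export
evaluate_risk <- function(risk, change, min_patch_ha = 10, n_nochange = 500,
                          seed = 1, bins = 10) {
  stopifnot(inherits(risk, "grid_raster"))
  pts <- validation_points(change, min_patch_ha, n_nochange, seed)
  risk_at <- function(df) risk$values[cbind(df$row, df$col)]
  rd <- risk_at(pts$deforested)
  rn <- risk_at(pts$nochange)
  rd <- rd[!is.na(rd)]; rn <- rn[!is.na(rn)]
  mw <- mann_whitney(rd, rn)
  brk <- seq(0, 1, length.out = bins + 1)
  hist_of <- function(x) {
    h <- graphics::hist(pmin(pmax(x, 0), 1), breaks = brk, plot = FALSE)
    h$counts
  }
  structure(list(
    n_deforested = length(rd), n_nochange = length(rn),
    mean_deforested = mean(rd), sd_deforested = stats::sd(rd),
    mean_nochange = mean(rn), sd_nochange = stats::sd(rn),
    U = mw$U, p_value = mw$p_value, method = mw$method,
    hist_breaks = brk, hist_deforested = hist_of(rd), hist_nochange = hist_of(rn),
    points = pts, seed = seed),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d deforested-patch centroids vs %d no-change points\n",
              x$n_deforested, x$n_nochange))
  cat(sprintf("  predicted risk: deforested %.0f%% (SD %.0f) vs no-change %.0f%% (SD %.0f)\n",
              100 * x$mean_deforested, 100 * x$sd_deforested,
              100 * x$mean_nochange, 100 * x$sd_nochange))
  cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.3g (%s)\n",
              x$U, x$p_value, x$method))
  invisible(x)
}

#' @rdname evaluate_risk
#' @param report a `validation_report`.
#' @param path output path; writes a tab-separated histogram table plus a
#'   `key=value` summary block.
#' @export
write_validation_report <- function(report, path) {
  ln <- c(sprintf("n_deforested=%d", report$n_deforested),
          sprintf("n_nochange=%d", report$n_nochange),
          sprintf("mean_deforested=%.6f", report$mean_deforested),
          sprintf("sd_deforested=%.6f", report$sd_deforested),
          sprintf("mean_nochange=%.6f", report$mean_nochange),
          sprintf("sd_nochange=%.6f", report$sd_nochange),
          sprintf("U=%g", report$U),
          sprintf("p_value=%.6g", report$p_value),
          sprintf("method=%s", report$method),
          "",
          paste("bin_lo", "bin_hi", "deforested", "nochange", sep = "\t"))
  for (i in seq_along(report$hist_deforested))
    ln <- c(ln, paste(report$hist_breaks[i], report$hist_breaks[i + 1],
                      report$hist_deforested[i], report$hist_nochange[i],
                      sep = "\t"))
  writeLines(ln, path)
  invisible(path)
}
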