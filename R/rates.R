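#' Annualized land-cover change rates
#'
#' `puyravaud_rate()` computes the annualized deforestation rate
#' \deqn{r = \frac{1}{t_2 - t_1}\,\ln\frac{A_2}{A_1}}
#' where `A1`, `A2` are forest areas (ha) at years `t1 < t2`. The rate is
#' returned signed on the decimal scale: negative for forest loss. Reports
#' conventionally quote `|r|` as percent per year (see [format_rate_pct()]).
#'
#' `fao_rate()` is the compound-interest form
#' \deqn{q = (A_2/A_1)^{1/(t_2-t_1)} - 1,}
#' kept for comparison; for the small rates typical of deforestation the two
#' agree to about `r^2/2` (order 1e-6 at r ~ 0.2%/yr).
#'
#' @param A1,A2 forest area (ha) at `t1` and `t2`; both must be positive.
#' @param t1,t2 assessment years, `t2 > t1`.
#' @return signed annual rate (decimal): `puyravaud_rate` on the log scale,
#'   `fao_rate` on the compound scale.
#' @examples
#' puyravaud_rate(4189955, 4109955, 2000, 2009)   # ~ -0.0021, i.e. 0.21 %/yr loss
#' @export
puyravaud_rate <- function(A1, A2, t1, t2) {
  check_rate_args(A1, A2, t1, t2)
  log(A2 / A1) / (t2 - t1)
}

#' @rdname puyravaud_rate
#' @export
fao_rate <- function(A1, A2, t1, t2) {
  check_rate_args(A1, A2, t1, t2)
  (A2 / A1)^(1 / (t2 - t1)) - 1
}

check_rate_args <- function(A1, A2, t1, t2) {
  if (any(t2 <= t1)) stop("t2 must be greater than t1")
  if (any(A1 <= 0) || any(A2 <= 0)) stop("forest areas must be positive")
  invisible(TRUE)
}

#' Format a signed annual rate as positive percent per year
#' @param r signed decimal rate.
#' @param digits decimals to keep (default 2, the conventional precision).
#' @return numeric `|r|` in percent, rounded.
#' @export
format_rate_pct <- function(r, digits = 2) round(abs(r) * 100, digits)

#' Project forest area under a constant annual rate
#'
#' Business-as-usual projection: `A_end = A0 * exp(r * years)` with `r` the
#' signed Puyravaud rate, plus the implied loss `A0 - A_end`. This is the
#' exact inverse of [puyravaud_rate()]: projecting `A1` at
#' `puyravaud_rate(A1, A2, t1, t2)` over `t2 - t1` years returns `A2`.
#'
#' @param A0 starting forest area (ha).
#' @param r signed annual rate (decimal, negative = loss).
#' @param years projection horizon in years (>= 0).
#' @return list with `A_end` (ha) and `loss_ha` (`A0 - A_end`; positive when
#'   forest shrinks).
#' @examples
#' r <- puyravaud_rate(4146955, 4109955, 2006, 2009)
#' project_forest(4109955, r, 11)   # horizon-2020 loss, ~132.9 kha
#' @export
project_forest <- function(A0, r, years) {
  stopifnot(A0 > 0, years >= 0)
  A_end <- A0 * exp(r * years)
  list(A_end = A_end, loss_ha = A0 - A_end)
}

#' Carbon accounting parameters
#'
#' Defaults: above-ground median forest carbon density of 113 Mg C/ha and the
#' stoichiometric CO2:C mass ratio 44/12 (~3.667). The commonly printed
#' rounded factor 3.67 can be selected explicitly. Other pools (below-ground,
#' soil, deadwood) are deliberately not modeled.
#'
#' @param carbon_density Mg C per ha of forest (> 0).
#' @param co2_per_c Mg CO2 emitted per Mg C (> 0).
#' @return list of class `carbon_params`.
#' @export
carbon_params <- function(carbon_density = 113, co2_per_c = 44 / 12) {
  stopifnot(carbon_density > 0, co2_per_c > 0)
  structure(list(carbon_density = carbon_density, co2_per_c = co2_per_c),
            class = "carbon_params")
}

#' Carbon and CO2 emissions from a cleared area
#'
#' @param area_ha area of forest lost (ha).
#' @param params a [carbon_params()] object.
#' @return list with `carbon_mg` (Mg C) and `co2_mg` (Mg CO2).
#' @examples
#' emissions(132865, carbon_params())  # ~15.0e6 Mg C, ~55.1e6 Mg CO2
#' @export
emissions <- function(area_ha, params = carbon_params()) {
  stopifnot(inherits(params, "carbon_params"), area_ha >= 0)
  carbon_mg <- area_ha * params$carbon_density
  list(carbon_mg = carbon_mg, co2_mg = carbon_mg * params$co2_per_c)
}

#' Tabulated rate report for a set of assessment periods
#'
#' @param periods data.frame with columns `t1`, `t2`, `A1`, `A2` (one row per
#'   assessment period).
#' @return data.frame adding `r_puyravaud`, `r_fao` (signed decimals) and
#'   `pct_per_yr` (positive percent, 2 decimals).
#' @export
rate_report <- function(periods) {
  stopifnot(all(c("t1", "t2", "A1", "A2") %in% names(periods)))
  r <- mapply(puyravaud_rate, periods$A1, periods$A2, periods$t1, periods$t2)
  q <- mapply(fao_rate, periods$A1, periods$A2, periods$t1, periods$t2)
  cbind(periods, r_puyravaud = r, r_fao = q, pct_per_yr = format_rate_pct(r))
}
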