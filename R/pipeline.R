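#' Run the full deforestation-risk pipeline on a synthetic landscape
#'
#' End-to-end orchestration of every stage on simulated data: generate a
#' landscape, simulate two epochs of deforestation (a fitting period and a
#' later validation period, with the distance-to-prior-deforestation surface
#' updated between them), emit noisy classifier views of each date, build
#' consensus change layers, sample presences and background, fit and
#' replicate the maximum-entropy risk model, predict the soft risk map,
#' validate it against the second epoch's observed change, estimate
#' annualized rates, project forest loss to a horizon, harden the risk map
#' to the projected loss, and account the carbon at risk.
#'
#' @param config a [sim_config()]; its seed drives every stochastic stage.
#' @param years1,years2 epoch lengths in years (defaults 6 and 3, a
#'   six-year fitting period and a three-year validation period).
#' @param horizon_years projection horizon beyond the second epoch
#'   (default 11).
#' @param n_presence presence points for model fitting (default 500).
#' @param n_background background points (default 10,000, capped at the
#'   study-area cell count).
#' @param k replicate model runs (default 25).
#' @param vars explanatory variables for the final model (default
#'   accessibility + land designation).
#' @param friction a [friction_table()].
#' @param params a [carbon_params()].
#' @return list with every intermediate product: `stack`, `epoch1`,
#'   `epoch2`, `classified` (per date), `change1`, `change2`, `presence`,
#'   `background`, `report` (replicate AUC/contribution), `model`, `risk`,
#'   `validation`, `rates` (realized-rate table), `projection`, `hard`,
#'   `carbon`.
#' @export
run_pipeline <- function(config = sim_config(), years1 = 6, years2 = 3,
                         horizon_years = 11, n_presence = 500,
                         n_background = 10000, k = 25,
                         vars = c("accessibility", "land_designation"),
                         friction = friction_table(),
                         params = carbon_params()) {
  stack <- generate_landscape(config, friction)

  ep1 <- simulate_deforestation(stack, config, years1,
                                forest = stack$forest_t0,
                                seed = config$seed + 1)
  prior2 <- grid_raster(stack$land_cover$values == 2 | ep1$cleared$values > 0,
                        stack[[1]]$cell_size_m, stack[[1]]$origin)
  stack2 <- stack_set(stack, "dist_deforestation", distance_transform(prior2))
  ep2 <- simulate_deforestation(stack2, config, years2,
                                forest = ep1$forest_end,
                                seed = config$seed + 2)

  cls <- list(t0 = emit_classifications(stack$forest_t0, config, seed = config$seed + 11),
              t1 = emit_classifications(ep1$forest_end, config, seed = config$seed + 12),
              t2 = emit_classifications(ep2$forest_end, config, seed = config$seed + 13))
  pair <- function(a, b) lapply(seq_along(a), function(i) list(start = a[[i]], end = b[[i]]))
  change1 <- consensus(pair(cls$t0, cls$t1))
  change2 <- consensus(pair(cls$t1, cls$t2))

  n_pres <- min(n_presence, sum(change1$deforested$values > 0))
  presence_pts <- sample_presence(change1, n_pres, seed = config$seed + 21)
  n_bg <- min(n_background, sum(!nodata_mask(stack[[1]])))
  background_pts <- sample_background(stack[[1]], n_bg, seed = config$seed + 22)
  presence <- extract_values(stack, presence_pts, vars)
  background <- extract_values(stack, background_pts, vars)

  report <- maxent_replicate(presence, background, k = k,
                             base_seed = config$seed + 31)
  model <- maxent_fit(presence, background, seed = config$seed + 31)
  risk <- predict(model, stack, scale = "logistic")

  validation <- evaluate_risk(risk, change2, seed = config$seed + 41)

  A0 <- area_ha(stack$forest_t0)
  A1 <- area_ha(ep1$forest_end)
  A2 <- area_ha(ep2$forest_end)
  rates <- rate_report(data.frame(
    t1 = c(0, 0, years1), t2 = c(years1 + years2, years1, years1 + years2),
    A1 = c(A0, A0, A1), A2 = c(A2, A1, A2)))
  r_bau <- rates$r_puyravaud[3]                 # latest-epoch rate, BAU
  projection <- project_forest(A2, r_bau, horizon_years)
  hard <- harden(risk, ep2$forest_end, projection$loss_ha)
  carbon <- carbon_at_risk(hard, params)

  list(config = config, stack = stack, epoch1 = ep1, epoch2 = ep2,
       classified = cls, change1 = change1, change2 = change2,
       presence_points = presence_pts, background_points = background_pts,
       presence = presence, background = background,
       report = report, model = model, risk = risk, validation = validation,
       rates = rates, r_bau = r_bau, projection = projection,
       hard = hard, carbon = carbon)
}
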