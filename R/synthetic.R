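#' Configuration of a synthetic landscape simulation
#'
#' Defines a seed-reproducible synthetic study area with the statistical
#' structure the risk analysis assumes: travel corridors (roads, rivers) and
#' towns that drive accessibility, categorical land-designation zones with
#' different clearing pressure, deforestation that concentrates in
#' accessible cells and near earlier clearings, several imperfect
#' classifiers observing the same truth, and cloud/nodata gaps per
#' classifier. The same config and seed always reproduce the same landscape
#' bit for bit.
#'
#' Defaults describe a 200 x 200 grid of 1-ha cells (40,000 ha) with an
#' annual clearing rate `r_target` of 0.003 (0.3 %/yr, a strong-pressure
#' frontier), accessibility as the dominant driver (`b_acc = 18` against
#' `b_dist = 12` on the logistic scale, with a strongly negative intercept so
#' clearing concentrates along travel corridors the way frontier
#' deforestation does), designation offsets that protect reserves and expose
#' mining/public land, classifier error rates of 2-5 % and cloud cover of
#' 5-10 % per source.
#'
#' @param nrow,ncol grid shape (cells).
#' @param cell_size_m cell edge (m); 100 gives 1-ha cells.
#' @param seed integer master seed.
#' @param n_roads,n_rivers,n_towns feature counts; at least one of the three
#'   must be positive (otherwise no access sources exist).
#' @param road_wiggle lateral drift (cells per column, SD) of corridors.
#' @param zone_names land-designation categories; Voronoi zones around
#'   random seed points partition the grid into these.
#' @param designation_offsets named logistic offsets, one per zone.
#' @param b0,b_acc,b_dist true risk coefficients on the logistic scale:
#'   intercept, weight on the accessibility index, and weight on (minus) the
#'   max-scaled distance to prior deforestation.
#' @param r_target target annual clearing rate (decimal in (0, 0.5)).
#' @param noise_rates per-source probability that a cell's forest/non-forest
#'   label is flipped.
#' @param cloud_fractions per-source fraction of the grid masked as
#'   cloud/nodata (blob-shaped).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(nrow = 200, ncol = 200, cell_size_m = 100, seed = 1,
                       n_roads = 2, n_rivers = 2, n_towns = 5,
                       road_wiggle = 0.4,
                       zone_names = c("protected", "indigenous_reserve",
                                      "concession", "mining", "public"),
                       designation_offsets = c(protected = -1.5,
                                               indigenous_reserve = -1,
                                               concession = 0,
                                               mining = 1.5, public = 0.5),
                       b0 = -14, b_acc = 18, b_dist = 12,
                       r_target = 0.003,
                       noise_rates = c(0.02, 0.03, 0.05),
                       cloud_fractions = c(0.05, 0.05, 0.1)) {
  stopifnot(nrow >= 20, ncol >= 20, cell_size_m > 0,
            n_roads >= 0, n_rivers >= 0, n_towns >= 0,
            length(zone_names) >= 1,
            all(noise_rates >= 0 & noise_rates <= 1),
            all(cloud_fractions >= 0 & cloud_fractions <= 1))
  if (!all(zone_names %in% names(designation_offsets)))
    stop("designation_offsets must name every zone in zone_names")
  if (r_target <= 0 || r_target >= 0.5)
    stop("r_target must lie in (0, 0.5)")
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @param config a `sim_config`.
#' @param path file for the plain `key=value` config (vectors comma-joined,
#'   named vectors as `name:value` pairs).
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  fmt <- function(x) {
    if (!is.null(names(x)) && any(nzchar(names(x))))
      paste(sprintf("%s:%.10g", names(x), as.numeric(x)), collapse = ",")
    else if (is.character(x)) paste(x, collapse = ",")
    else paste(formatC(x, format = "g", digits = 15), collapse = ",")
  }
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, fmt, character(1))), path)
  invisible(path)
}

#' @rdname sim_config
#' @export
read_sim_config <- function(path) {
  ln <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  keys <- sub("=.*", "", ln)
  vals <- sub("^[^=]*=", "", ln)
  parse1 <- function(s) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (all(grepl(":", parts, fixed = TRUE))) {
      nm <- sub(":.*", "", parts)
      stats::setNames(as.numeric(sub(".*:", "", parts)), nm)
    } else {
      num <- suppressWarnings(as.numeric(parts))
      if (anyNA(num)) parts else num
    }
  }
  args <- stats::setNames(lapply(vals, parse1), keys)
  do.call(sim_config, args[names(args) %in% names(formals(sim_config))])
}

## smooth Gaussian-ish random field: coarse white noise, bilinearly upsampled
smooth_field <- function(nr, nc, rng, scale = 15) {
  cr <- max(2L, ceiling(nr / scale) + 1L)
  cc <- max(2L, ceiling(nc / scale) + 1L)
  coarse <- matrix(with_rng(rng, stats::rnorm(cr * cc)), cr, cc)
  ri <- seq(1, cr, length.out = nr)
  ci <- seq(1, cc, length.out = nc)
  r0 <- pmin(floor(ri), cr - 1L); c0 <- pmin(floor(ci), cc - 1L)
  fr <- ri - r0; fc <- ci - c0
  m <- outer(seq_len(nr), seq_len(nc), function(i, j) {
    a <- coarse[cbind(r0[i], c0[j])] * (1 - fr[i]) * (1 - fc[j]) +
         coarse[cbind(r0[i] + 1L, c0[j])] * fr[i] * (1 - fc[j]) +
         coarse[cbind(r0[i], c0[j] + 1L)] * (1 - fr[i]) * fc[j] +
         coarse[cbind(r0[i] + 1L, c0[j] + 1L)] * fr[i] * fc[j]
    a
  })
  m
}

## rasterize a wiggly corridor crossing the full grid
corridor_cells <- function(nr, nc, rng, wiggle, horizontal = TRUE) {
  n_along <- if (horizontal) nc else nr
  n_across <- if (horizontal) nr else nc
  start <- with_rng(rng, sample.int(n_across, 1))
  drift <- cumsum(with_rng(rng, stats::rnorm(n_along, 0, wiggle)))
  pos <- pmin(pmax(round(start + drift), 1L), n_across)
  cells <- matrix(0L, nr, nc)
  for (k in seq_len(n_along)) {
    lo <- if (k == 1) pos[k] else min(pos[k - 1L], pos[k])
    hi <- if (k == 1) pos[k] else max(pos[k - 1L], pos[k])
    if (horizontal) cells[lo:hi, k] <- 1L else cells[k, lo:hi] <- 1L
  }
  cells
}

#' Generate a synthetic landscape
#'
#' Builds the full explanatory-variable stack for one synthetic study area:
#' rasterized roads/rivers/towns, a smooth slope field (0-25 degrees),
#' Voronoi land-designation zones that partition the grid, land cover,
#' initial (pre-period) clearings as small town footprints, the
#' distance-to-prior-deforestation surface, the friction-based accessibility
#' index, and a forest mask `forest_t0` covering everything except the town
#' footprints.
#'
#' @param config a [sim_config()].
#' @param friction a [friction_table()] used for the accessibility index.
#' @return a [landscape_stack()] with slots `forest_t0`, `land_cover`,
#'   `slope`, `land_designation`, `roads`, `rivers`, `towns`,
#'   `dist_deforestation`, `travel_time`, `accessibility`.
#' @export
generate_landscape <- function(config, friction = friction_table()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_roads == 0 && config$n_rivers == 0 && config$n_towns == 0)
    stop("config has no roads, rivers or towns: no access sources to build a landscape around")
  nr <- config$nrow; nc <- config$ncol
  rng <- make_rng(config$seed)
  g <- function(m, cats = NULL) grid_raster(m, config$cell_size_m, c(0, 0), cats)

  roads <- matrix(0L, nr, nc)
  for (i in seq_len(config$n_roads))
    roads <- pmax(roads, corridor_cells(nr, nc, rng, config$road_wiggle, horizontal = TRUE))
  rivers <- matrix(0L, nr, nc)
  for (i in seq_len(config$n_rivers))
    rivers <- pmax(rivers, corridor_cells(nr, nc, rng, config$road_wiggle * 2, horizontal = FALSE))

  towns <- matrix(0L, nr, nc)
  if (config$n_towns > 0) {
    on_net <- which(roads > 0 | rivers > 0)
    town_idx <- if (length(on_net))
      on_net[sample_int(rng, length(on_net), min(config$n_towns, length(on_net)))]
    else with_rng(rng, sample.int(nr * nc, config$n_towns))
    towns[town_idx] <- 1L
  }

  slope <- smooth_field(nr, nc, rng, scale = 12)
  slope <- (slope - min(slope)) / (max(slope) - min(slope)) * 25

  nz <- length(config$zone_names)
  zr <- with_rng(rng, sample.int(nr, nz, replace = TRUE))
  zc <- with_rng(rng, sample.int(nc, nz, replace = TRUE))
  zone <- outer(seq_len(nr), seq_len(nc), function(i, j) {
    d <- sapply(seq_len(nz), function(k) (i - zr[k])^2 + (j - zc[k])^2)
    max.col(-matrix(d, ncol = nz), ties.method = "first")
  })

  # pre-period clearings: 3x3 footprints around towns (or a corner patch if
  # the config has no towns) seed the distance-to-prior-deforestation field
  prior <- matrix(FALSE, nr, nc)
  ti <- which(towns > 0)
  if (length(ti)) {
    tr <- ((ti - 1L) %% nr) + 1L; tc <- ((ti - 1L) %/% nr) + 1L
    for (k in seq_along(ti)) {
      rr <- pmax(1L, tr[k] - 1L):pmin(nr, tr[k] + 1L)
      cc2 <- pmax(1L, tc[k] - 1L):pmin(nc, tc[k] + 1L)
      prior[rr, cc2] <- TRUE
    }
  } else prior[1:2, 1:2] <- TRUE

  land_cover <- matrix(1L, nr, nc)
  land_cover[prior] <- 2L

  stack <- landscape_stack(
    forest_t0 = g(!prior),
    land_cover = g(land_cover, cats = c("forest", "cleared")),
    slope = g(slope),
    land_designation = g(zone, cats = config$zone_names),
    roads = g(roads), rivers = g(rivers), towns = g(towns))
  stack <- stack_set(stack, "dist_deforestation", distance_transform(g(prior)))
  acc <- accessibility_surface(stack, friction)
  stack <- stack_set(stack, "travel_time", acc$travel_time)
  stack <- stack_set(stack, "accessibility", acc$index)
  stack
}

#' Simulate one epoch of deforestation
#'
#' Simulates the epoch one year at a time. Each year every remaining forest
#' cell is cleared by an independent Bernoulli draw whose probability
#' follows the configured risk surface on the logistic scale,
#' `logit(w) = b0 + b_acc * accessibility - b_dist * (dist / dist_scale_m) +
#' offset_designation`, rescaled so the *expected* cleared fraction of that
#' year matches the annual target `1 - exp(-r_target)` (cells pinned at the
#' 0.999 cap have the excess redistributed). Between years the
#' distance-to-prior-deforestation surface is recomputed from everything
#' cleared so far, so clearing spreads contiguously from existing clearings
#' and travel corridors — the patch-forming contagion real frontier
#' deforestation shows.
#'
#' @param stack a [generate_landscape()] stack.
#' @param config the [sim_config()] (supplies coefficients and `r_target`).
#' @param years epoch length in whole years.
#' @param forest forest mask grid at epoch start (default `stack$forest_t0`).
#' @param seed RNG seed for the Bernoulli draws (default `config$seed + 1`).
#' @param dist_scale_m characteristic distance (m) in which the
#'   distance-to-prior-deforestation term is expressed (default 300).
#' @return list: `forest_end` (forest mask grid), `cleared` (mask grid of
#'   cells lost this epoch), `prob` (per-cell clearing probability grid of
#'   the final simulated year).
#' @export
simulate_deforestation <- function(stack, config, years, forest = stack$forest_t0,
                                   seed = config$seed + 1, dist_scale_m = 300) {
  stopifnot(inherits(stack, "landscape_stack"), inherits(config, "sim_config"),
            years >= 1)
  if (config$r_target <= 0 || config$r_target >= 0.5)
    stop("r_target must lie in (0, 0.5)")
  if (is.null(stack$accessibility) || is.null(stack$dist_deforestation))
    stop("stack needs 'accessibility' and 'dist_deforestation' grids")
  acc <- stack$accessibility$values
  off <- config$designation_offsets[
    config$zone_names[stack$land_designation$values]]
  base_eta <- config$b0 + config$b_acc * acc + off
  cs <- forest$cell_size_m
  prior <- stack$dist_deforestation$values == 0        # pre-epoch clearings
  fnow <- forest$values > 0 & !is.na(acc)
  cleared_all <- matrix(FALSE, nrow(acc), ncol(acc))
  rng <- make_rng(seed)
  f_annual <- 1 - exp(-config$r_target)
  p <- matrix(0, nrow(acc), ncol(acc))
  for (yr in seq_len(years)) {
    dist_g <- distance_transform(grid_raster(prior | cleared_all, cs, forest$origin))
    eta <- base_eta - config$b_dist * dist_g$values / dist_scale_m
    w <- stats::plogis(eta)
    sel <- which(fnow)
    if (!length(sel)) break
    target <- f_annual * length(sel)
    # rescale so expected clearings hit the target, respecting the 0.999 cap
    pv <- scale_capped(w[sel], target, cap = 0.999)
    p[] <- 0
    p[sel] <- pv
    u <- with_rng(rng, stats::runif(length(sel)))
    hit <- sel[u < pv]
    cleared_all[hit] <- TRUE
    fnow[hit] <- FALSE
  }
  forest_end <- forest$values > 0 & !cleared_all
  gr <- function(m) grid_raster(m, cs, forest$origin)
  list(forest_end = gr(forest_end), cleared = gr(cleared_all), prob = gr(p))
}

## scale weights w to probabilities summing to `target`, capping at `cap`
## and redistributing the clipped excess over uncapped cells
scale_capped <- function(w, target, cap = 0.999) {
  if (sum(w) <= 0) return(rep(target / length(w), length(w)))
  p <- w * target / sum(w)
  for (i in 1:20) {
    over <- p > cap
    if (!any(over)) break
    deficit <- target - sum(pmin(p, cap))
    free <- which(!over)
    if (!length(free) || deficit <= 0) break
    p[free] <- p[free] * (1 + deficit / sum(p[free]))
    p[over] <- cap
  }
  pmin(p, cap)
}

#' Emit noisy classifier views of a true forest mask
#'
#' Simulates the independent imperfect classifiers of a multi-source change
#' analysis: each source flips cell labels independently at its noise rate
#' and blanks its own blob-shaped cloud/nodata patches (drawn as the top
#' quantile of a smooth random field, so the masked fraction is honored
#' almost exactly while staying spatially coherent).
#'
#' @param truth logical forest-mask `grid_raster`.
#' @param config a [sim_config()] (`noise_rates`, `cloud_fractions`; one
#'   source per entry).
#' @param seed RNG seed (default `config$seed + 2`); each source draws its
#'   own substream.
#' @return list of `grid_raster` forest masks, one per source, with `NA`
#'   where that source is clouded.
#' @export
emit_classifications <- function(truth, config, seed = config$seed + 2) {
  stopifnot(inherits(truth, "grid_raster"))
  nr <- nrow(truth$values); nc <- ncol(truth$values)
  n_src <- length(config$noise_rates)
  cloud <- rep_len(config$cloud_fractions, n_src)
  out <- vector("list", n_src)
  for (s in seq_len(n_src)) {
    rng <- make_rng(seed * 131L + s)
    v <- truth$values > 0
    flip <- matrix(with_rng(rng, stats::runif(nr * nc)) < config$noise_rates[s], nr, nc)
    v <- xor(v, flip)
    if (cloud[s] > 0) {
      fld <- smooth_field(nr, nc, rng, scale = 10)
      v[fld >= stats::quantile(fld, 1 - cloud[s])] <- NA
    }
    v[is.na(truth$values)] <- NA
    out[[s]] <- grid_raster(v, truth$cell_size_m, truth$origin)
  }
  names(out) <- paste0("source", seq_len(n_src))
  out
}
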