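#' Friction (travel speed) table
#'
#' Travel speeds used to turn a landscape into a per-cell traversal cost.
#' Each land-cover category gets a base speed (km/h); cells carrying a road
#' or river feature override the land-cover speed (precedence road > river).
#' Slope slows travel multiplicatively by `1 / (1 + slope_deg / slope_s0)`,
#' so a cell at `slope_s0` degrees is traversed at half speed.
#'
#' The shipped default speeds (forest 2, cleared/agriculture 4, river 10,
#' dirt road 30, paved road 60 km/h) are editable placeholders calibrated to
#' typical Amazonian field-travel estimates; any real application should
#' supply its own measured coefficients via [read_friction_table()].
#'
#' @param land_cover_kmh named numeric: speed per land-cover category name.
#' @param road_kmh,river_kmh speed overrides for road / river cells.
#' @param slope_s0 slope (degrees) at which speed is halved; `Inf` disables
#'   the slope penalty.
#' @param sources which feature grids act as travel origins: `"towns"`,
#'   `"roads"` or `"both"`.
#' @return object of class `friction_table`.
#' @export
friction_table <- function(land_cover_kmh = c(forest = 2, cleared = 4),
                           road_kmh = 30, river_kmh = 10, slope_s0 = 30,
                           sources = c("towns", "roads", "both")) {
  stopifnot(all(land_cover_kmh > 0), road_kmh > 0, river_kmh > 0, slope_s0 > 0,
            !is.null(names(land_cover_kmh)))
  structure(list(land_cover_kmh = land_cover_kmh, road_kmh = road_kmh,
                 river_kmh = river_kmh, slope_s0 = slope_s0,
                 sources = match.arg(sources)),
            class = "friction_table")
}

#' @rdname friction_table
#' @param path file path for the delimited (tab-separated) table with columns
#'   `category`, `speed_kmh`, `override_class` (`land_cover`, `road`,
#'   `river`, or `slope_s0` for the penalty parameter row).
#' @param table a `friction_table`.
#' @export
write_friction_table <- function(table, path) {
  stopifnot(inherits(table, "friction_table"))
  df <- rbind(
    data.frame(category = names(table$land_cover_kmh),
               speed_kmh = as.numeric(table$land_cover_kmh),
               override_class = "land_cover"),
    data.frame(category = c("road", "river", "slope_s0", "sources"),
               speed_kmh = c(table$road_kmh, table$river_kmh, table$slope_s0, NA),
               override_class = c("road", "river", "slope_s0", table$sources)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname friction_table
#' @export
read_friction_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lc <- df[df$override_class == "land_cover", ]
  pick <- function(cls, default) {
    row <- df[df$override_class == cls, ]
    if (nrow(row)) row$speed_kmh[1] else default
  }
  src_row <- df[df$category == "sources", ]
  friction_table(
    land_cover_kmh = stats::setNames(lc$speed_kmh, lc$category),
    road_kmh = pick("road", 30), river_kmh = pick("river", 10),
    slope_s0 = pick("slope_s0", 30),
    sources = if (nrow(src_row)) src_row$override_class[1] else "towns")
}

#' Per-cell traversal cost from a friction table
#'
#' Effective speed of a cell is its land-cover speed, overridden by the road
#' speed on road cells and the river speed on river cells (road wins where
#' both), then multiplied by the slope penalty `1/(1 + slope/s0)`. The
#' traversal cost is `60 / (1000 * speed_kmh)` minutes per meter.
#'
#' @param stack a [landscape_stack()] with `land_cover` (categorical) and
#'   optionally `slope`, `roads`, `rivers` grids.
#' @param table a [friction_table()]; every category present in `land_cover`
#'   must have a speed.
#' @return `grid_raster` of cost in minutes/meter (`NA` on nodata cells).
#' @export
build_friction <- function(stack, table) {
  stopifnot(inherits(stack, "landscape_stack"), inherits(table, "friction_table"))
  lc <- stack$land_cover
  if (is.null(lc)) stop("stack has no 'land_cover' grid")
  cats <- lc$categories
  if (is.null(cats)) stop("'land_cover' grid carries no category table")
  missing_cats <- setdiff(cats[sort(unique(lc$values[!is.na(lc$values)]))],
                          names(table$land_cover_kmh))
  if (length(missing_cats))
    stop("no speed for land-cover category: ", paste(missing_cats, collapse = ", "))
  speed <- matrix(table$land_cover_kmh[cats[lc$values]], nrow(lc$values))
  if (!is.null(stack$rivers)) speed[stack$rivers$values > 0] <- table$river_kmh
  if (!is.null(stack$roads)) speed[stack$roads$values > 0] <- table$road_kmh
  if (!is.null(stack$slope) && is.finite(table$slope_s0))
    speed <- speed / (1 + stack$slope$values / table$slope_s0)
  cost <- 60 / (1000 * speed)
  cost[is.na(lc$values)] <- NA_real_
  grid_raster(cost, lc$cell_size_m, lc$origin)
}

#' Least-cost cumulative travel time from source cells
#'
#' Minimal cumulative travel time (minutes) from any source cell over
#' 8-connected moves. A move between adjacent cells costs the step length
#' (cell size, times sqrt(2) diagonally) multiplied by the mean of the two
#' cells' friction costs — the standard cost-distance semantics. Computed
#' with Dijkstra's algorithm on the move graph.
#'
#' @param sources logical `grid_raster`/matrix of source cells, or a
#'   data.frame with `row`, `col`.
#' @param friction `grid_raster` of cost in minutes/meter (from
#'   [build_friction()]); `NA` cells are impassable.
#' @return `grid_raster` of travel time in minutes (`NA` where unreachable or
#'   nodata); source cells get 0.
#' @export
cost_distance <- function(sources, friction) {
  stopifnot(inherits(friction, "grid_raster"))
  cost <- friction$values
  nr <- nrow(cost); nc <- ncol(cost)
  if (is.data.frame(sources)) {
    src_idx <- (sources$col - 1L) * nr + sources$row
  } else {
    if (inherits(sources, "grid_raster")) {
      check_aligned(sources, friction, "sources", "friction")
      sources <- sources$values
    }
    src_idx <- which(sources > 0)
  }
  src_idx <- src_idx[!is.na(cost[src_idx])]
  if (!length(src_idx)) stop("cost_distance: no (passable) source cells")

  ok <- !is.na(cost)
  idx <- which(ok)
  vid <- match(seq_len(nr * nc), idx)      # linear cell index -> vertex id
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  cs <- friction$cell_size_m
  edges <- integer(0); w <- numeric(0)
  for (d in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))) {
    r2 <- rows + d[1]; c2 <- cols + d[2]
    inb <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[inb] - 1L) * nr + r2[inb]
    keep <- !is.na(vid[j])
    a <- which(inb)[keep]; b <- vid[j][keep]
    edges <- c(edges, rbind(a, b))
    w <- c(w, cs * d[3] * (cost[idx[a]] + cost[idx[b]]) / 2)
  }
  gr <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  dm <- igraph::distances(gr, v = match(src_idx, idx), weights = w,
                          algorithm = "dijkstra")
  tt <- if (is.matrix(dm)) apply(dm, 2L, min) else dm
  out <- matrix(NA_real_, nr, nc)
  out[idx] <- ifelse(is.finite(tt), tt, NA_real_)
  grid_raster(out, friction$cell_size_m, friction$origin)
}

#' Accessibility index from travel time
#'
#' Monotone-decreasing transform of travel time onto [0, 1]:
#' `index = exp(-time / tau)`. Source cells (time 0) get 1; the index decays
#' toward 0 for remote cells. `tau` sets the decay scale in minutes and
#' defaults to the median travel time of the study area, putting the middle
#' of the landscape at index ~0.37.
#'
#' @param travel_time `grid_raster` of minutes (from [cost_distance()]).
#' @param tau decay scale in minutes; default median non-nodata travel time.
#' @return `grid_raster` of accessibility in [0, 1].
#' @export
accessibility_index <- function(travel_time, tau = NULL) {
  stopifnot(inherits(travel_time, "grid_raster"))
  if (is.null(tau)) tau <- stats::median(travel_time$values, na.rm = TRUE)
  stopifnot(tau > 0)
  g <- grid_raster(exp(-travel_time$values / tau),
                   travel_time$cell_size_m, travel_time$origin)
  attr(g, "tau") <- tau
  g
}

#' One-call accessibility surface for a landscape
#'
#' Builds the friction surface, picks source cells per the table's `sources`
#' setting (towns and/or roads), runs the least-cost travel time, and maps it
#' to the accessibility index.
#'
#' @inheritParams build_friction
#' @param tau passed to [accessibility_index()].
#' @return list with `friction`, `travel_time`, `index` grids and `tau`.
#' @export
accessibility_surface <- function(stack, table = friction_table(), tau = NULL) {
  fr <- build_friction(stack, table)
  src <- matrix(FALSE, nrow(fr$values), ncol(fr$values))
  if (table$sources %in% c("towns", "both")) {
    if (is.null(stack$towns)) stop("friction table wants town sources but stack has no 'towns'")
    src <- src | stack$towns$values > 0
  }
  if (table$sources %in% c("roads", "both")) {
    if (is.null(stack$roads)) stop("friction table wants road sources but stack has no 'roads'")
    src <- src | stack$roads$values > 0
  }
  tt <- cost_distance(src, fr)
  ai <- accessibility_index(tt, tau)
  list(friction = fr, travel_time = tt, index = ai, tau = attr(ai, "tau"))
}
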