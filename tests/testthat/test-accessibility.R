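test_that("friction costs follow speed, overrides and slope penalty", {
  st <- toy_stack(6, 6)
  tab <- friction_table(land_cover_kmh = c(forest = 2, cleared = 4),
                        road_kmh = 60, river_kmh = 10)
  fr <- build_friction(st, tab)
  mid <- ceiling(6 / 2)
  expect_equal(fr$values[mid, 3], 60 / (1000 * 60))     # road at 60 km/h, flat -> 0.001 min/m
  expect_equal(fr$values[1, 1], 60 / (1000 * 2))        # forest at 2 km/h
  # slope penalty is 1 at 0 degrees and halves speed at s0
  st2 <- stack_set(st, "slope", grid_raster(matrix(30, 6, 6), 100))
  fr2 <- build_friction(st2, tab)
  expect_equal(fr2$values[1, 1], 2 * fr$values[1, 1])
})

test_that("river override applies where no road wins", {
  st <- toy_stack(6, 6)
  riv <- matrix(0L, 6, 6); riv[, 2] <- 1L
  st <- stack_set(st, "rivers", grid_raster(riv, 100))
  fr <- build_friction(st, friction_table(road_kmh = 30, river_kmh = 10))
  expect_equal(fr$values[1, 2], 60 / (1000 * 10))
  expect_equal(fr$values[3, 2], 60 / (1000 * 30))   # road cell beats river
})

test_that("unknown land-cover category is reported by name", {
  st <- toy_stack(4, 4)
  st$land_cover$values[2, 2] <- 2L   # 'cleared'
  expect_error(build_friction(st, friction_table(land_cover_kmh = c(forest = 2))),
               "cleared")
})

test_that("doubling all speeds halves every traversal cost", {
  st <- toy_stack(8, 8)
  st <- stack_set(st, "slope", grid_raster(matrix(runif(64, 0, 20), 8, 8), 100))
  t1 <- friction_table(land_cover_kmh = c(forest = 2, cleared = 4),
                       road_kmh = 30, river_kmh = 10)
  t2 <- friction_table(land_cover_kmh = c(forest = 4, cleared = 8),
                       road_kmh = 60, river_kmh = 20)
  f1 <- build_friction(st, t1); f2 <- build_friction(st, t2)
  expect_equal(f2$values, f1$values / 2)
})

test_that("uniform friction gives travel time proportional to octile distance", {
  fr <- grid_raster(matrix(0.01, 7, 7), 100)   # 0.01 min/m everywhere
  src <- matrix(FALSE, 7, 7); src[4, 4] <- TRUE
  tt <- cost_distance(src, fr)
  octile <- function(dr, dc) {
    a <- abs(dr); b <- abs(dc)
    (max(a, b) - min(a, b)) + sqrt(2) * min(a, b)
  }
  for (r in 1:7) for (c in 1:7)
    expect_equal(tt$values[r, c], octile(r - 4, c - 4) * 100 * 0.01,
                 tolerance = 1e-12)
})

test_that("cost distance equals the independent Dijkstra oracle on random friction", {
  set.seed(31)
  for (i in 1:5) {
    cost <- matrix(runif(225, 0.005, 0.05), 15, 15)
    cost[sample(225, 8)] <- NA   # impassable cells
    src <- which(!is.na(cost))[1:2]
    fr <- grid_raster(cost, 100)
    sm <- matrix(FALSE, 15, 15); sm[src] <- TRUE
    tt <- cost_distance(sm, fr)
    oracle <- bf_cost_distance(cost, 100, src)
    oracle[!is.finite(oracle) | is.na(cost)] <- NA
    expect_equal(tt$values, oracle, tolerance = 1e-9)
  }
})

test_that("adding a source never increases travel time anywhere", {
  set.seed(5)
  cost <- matrix(runif(100, 0.005, 0.05), 10, 10)
  fr <- grid_raster(cost, 100)
  s1 <- matrix(FALSE, 10, 10); s1[2, 2] <- TRUE
  s2 <- s1; s2[9, 9] <- TRUE
  t1 <- cost_distance(s1, fr); t2 <- cost_distance(s2, fr)
  expect_true(all(t2$values <= t1$values + 1e-12))
})

test_that("travel times obey the triangle property along the move graph", {
  set.seed(13)
  cost <- matrix(runif(144, 0.005, 0.05), 12, 12)
  fr <- grid_raster(cost, 100)
  sA <- matrix(FALSE, 12, 12); sA[1, 1] <- TRUE
  sB <- matrix(FALSE, 12, 12); sB[6, 7] <- TRUE
  tA <- cost_distance(sA, fr); tB <- cost_distance(sB, fr)
  # time from A to any c is bounded by time A->B plus B->c
  expect_true(all(tA$values <= tA$values[6, 7] + tB$values + 1e-9))
})

test_that("upgrading a corridor strictly reduces its travel times", {
  st <- toy_stack(12, 12)
  dirt <- accessibility_surface(st, friction_table(road_kmh = 30))
  paved <- accessibility_surface(st, friction_table(road_kmh = 60))
  mid <- ceiling(12 / 2)
  on_road <- st$roads$values > 0 & dirt$travel_time$values > 0
  expect_true(all(paved$travel_time$values[on_road] <
                    dirt$travel_time$values[on_road]))
  expect_true(all(paved$index$values[on_road] > dirt$index$values[on_road]))
})

test_that("accessibility index is a monotone [0,1] transform of travel time", {
  set.seed(3)
  tt <- grid_raster(matrix(rexp(100, 1 / 50), 10, 10), 100)
  tt$values[1, 1] <- 0
  ai <- accessibility_index(tt, tau = 60)
  expect_equal(ai$values[1, 1], 1)
  expect_equal(ai$values, exp(-tt$values / 60))
  expect_true(all(ai$values >= 0 & ai$values <= 1))
  expect_equal(order(ai$values), rev(order(tt$values)))
  # default tau is the median travel time
  ai2 <- accessibility_index(tt)
  expect_equal(attr(ai2, "tau"), median(tt$values))
})

test_that("cost distance requires at least one passable source", {
  fr <- grid_raster(matrix(0.01, 5, 5), 100)
  expect_error(cost_distance(matrix(FALSE, 5, 5), fr), "source")
})

test_that("friction tables round-trip through their delimited file", {
  tab <- friction_table(land_cover_kmh = c(forest = 2.5, cleared = 4),
                        road_kmh = 45, river_kmh = 12, slope_s0 = 25,
                        sources = "both")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_friction_table(tab, f)
  tab2 <- read_friction_table(f)
  expect_equal(tab2$land_cover_kmh, tab$land_cover_kmh)
  expect_equal(tab2$road_kmh, 45)
  expect_equal(tab2$river_kmh, 12)
  expect_equal(tab2$slope_s0, 25)
  expect_equal(tab2$sources, "both")
})
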