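make_toy_data <- function(n_pres = 40, n_bg = 200, seed = 1) {
  set.seed(seed)
  bg <- data.frame(acc = runif(n_bg), zone = sample(c("a", "b", "c"), n_bg, TRUE))
  pres <- data.frame(acc = rbeta(n_pres, 4, 1.5),
                     zone = sample(c("a", "b", "c"), n_pres, TRUE, prob = c(.5, .3, .2)))
  list(pres = pres, bg = bg)
}

test_that("feature expansion scales from background and stays in [0,1]", {
  d <- make_toy_data()
  fe <- maxent_features(d$bg)
  Fb <- expand_features(fe, d$bg)
  Fp <- expand_features(fe, d$pres)
  expect_true(all(Fb >= 0 & Fb <= 1))
  expect_true(all(Fp >= 0 & Fp <= 1))
  # one linear + one quadratic + 8 hinges for the continuous variable,
  # one indicator per category
  expect_equal(ncol(Fb), 10 + 3)
  # scaling constants come from the background, and out-of-range points clamp
  out <- expand_features(fe, data.frame(acc = c(-5, 99), zone = c("a", "b")))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(expand_features(fe, data.frame(acc = NaN, zone = "a")), "non-finite")
})

test_that("constant features yield the uniform model with a warning", {
  pres <- data.frame(x = rep(1, 5))
  bg <- data.frame(x = rep(1, 50))
  expect_warning(m <- maxent_fit(pres, bg), "uniform")
  expect_true(all(m$lambda == 0))
  raw <- predict(m, bg, scale = "raw")
  expect_equal(raw, rep(1, 50))                      # q = 1/N each, raw = q*N
  expect_equal(predict(m, bg, scale = "logistic"), rep(0.5, 50))
  expect_equal(m$entropy, log(50))
})

test_that("one-binary-feature fit matches a brute-force grid search of the objective", {
  # a single 0/1 variable with no hinge features expands to two identical
  # columns (linear and quadratic), so the total weight s = sum(lambda) is
  # the 1-D parameter; presences sit only where the feature is 1
  # with equal per-column beta and a symmetric optimizer the two columns get
  # equal weight, so the penalty equals beta * |s| and the problem is 1-D
  bg <- data.frame(x = rep(c(0, 1), c(60, 40)))
  pres <- data.frame(x = rep(1, 12))
  beta1 <- 1
  m <- maxent_fit(pres, bg, h_hinge = 0, beta = c(beta1, beta1),
                  tol = 1e-12, max_iter = 5000)
  obj <- function(s) {
    z <- bg$x * s
    mean(pres$x * s) - log(sum(exp(z))) - beta1 * abs(s)
  }
  grid <- seq(-20, 20, by = 1e-4)
  s_star <- grid[which.max(vapply(grid, obj, numeric(1)))]
  expect_equal(unname(m$lambda[1]), unname(m$lambda[2]))
  expect_lt(abs(sum(m$lambda) - s_star), 1e-3)
  expect_gte(obj(sum(m$lambda)), obj(s_star) - 1e-9)
})

test_that("two-feature fit agrees with a dense grid search", {
  set.seed(8)
  bg <- data.frame(x = runif(80))
  pres <- data.frame(x = rbeta(15, 5, 1))
  beta <- c(0.02, 0.02)
  m <- maxent_fit(pres, bg, h_hinge = 0, beta = beta, tol = 1e-12, max_iter = 5000)
  fe <- maxent_features(bg, h_hinge = 0)
  Fb <- expand_features(fe, bg); Fp <- expand_features(fe, pres)
  obj <- function(l1, l2) {
    lam <- c(l1, l2)
    z <- drop(Fb %*% lam)
    mean(drop(Fp %*% lam)) - log(sum(exp(z))) - sum(beta * abs(lam))
  }
  # coarse-to-fine search
  g1 <- expand.grid(l1 = seq(-10, 10, 0.2), l2 = seq(-10, 10, 0.2))
  v1 <- mapply(obj, g1$l1, g1$l2)
  c1 <- g1[which.max(v1), ]
  g2 <- expand.grid(l1 = seq(c1$l1 - 0.3, c1$l1 + 0.3, 5e-4),
                    l2 = seq(c1$l2 - 0.3, c1$l2 + 0.3, 5e-4))
  v2 <- mapply(obj, g2$l1, g2$l2)
  c2 <- g2[which.max(v2), ]
  expect_lt(abs(unname(m$lambda[1]) - c2$l1), 1e-3)
  expect_lt(abs(unname(m$lambda[2]) - c2$l2), 1e-3)
  expect_gte(obj(m$lambda[1], m$lambda[2]), obj(c2$l1, c2$l2) - 1e-8)
})

test_that("every fit satisfies the KKT slack condition and a monotone objective", {
  for (seed in 1:5) {
    d <- make_toy_data(seed = seed)
    m <- maxent_fit(d$pres, d$bg)
    expect_true(all(m$kkt_slack <= 2.5e-4),
                label = sprintf("KKT slack (seed %d)", seed))
    expect_false(is.unsorted(m$objective_trace),
                 label = sprintf("objective trace monotone (seed %d)", seed))
    # raw predictions over the background form a probability distribution
    raw <- predict(m, d$bg, scale = "raw")
    expect_equal(sum(raw / m$n_background), 1, tolerance = 1e-12)
  }
})

test_that("logistic and raw outputs are monotone in the linear predictor", {
  d <- make_toy_data(seed = 3)
  m <- maxent_fit(d$pres, d$bg)
  sc_raw <- predict(m, d$bg, scale = "raw")
  sc_log <- predict(m, d$bg, scale = "logistic")
  expect_equal(order(sc_raw), order(sc_log))
  expect_true(all(sc_log >= 0 & sc_log <= 1))
})

test_that("AUC matches the all-pairs oracle and its anchor cases", {
  expect_equal(auc_presence_background(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(auc_presence_background(c(0.3, 0.7), c(0.3, 0.7)), 0.5)
  set.seed(17)
  for (i in 1:5) {
    p <- sample(round(runif(30), 2))   # rounding forces ties
    b <- sample(round(runif(30), 2))
    expect_equal(auc_presence_background(p, b), bf_auc(p, b))
  }
})

test_that("replicate runs are deterministic in the base seed and report SD", {
  d <- make_toy_data(n_pres = 30, seed = 5)
  r1 <- maxent_replicate(d$pres, d$bg, k = 4, base_seed = 11)
  r2 <- maxent_replicate(d$pres, d$bg, k = 4, base_seed = 11)
  expect_identical(r1$auc_runs, r2$auc_runs)
  expect_identical(r1$contribution, r2$contribution)
  expect_gt(r1$auc_mean, 0.5)
  expect_warning(r3 <- maxent_replicate(d$pres, d$bg, k = 1, base_seed = 2),
                 "undefined")
  expect_equal(r3$auc_sd, 0)
})

test_that("percent contribution: single variable takes 100, duplicates share, noise is small", {
  d <- make_toy_data(seed = 9)
  m1 <- maxent_fit(d$pres["acc"], d$bg["acc"])
  pc1 <- percent_contribution(m1, d$pres["acc"], d$bg["acc"], seed = 2)
  expect_equal(unname(pc1["acc"]), 100)

  dup_p <- data.frame(a1 = d$pres$acc, a2 = d$pres$acc)
  dup_b <- data.frame(a1 = d$bg$acc, a2 = d$bg$acc)
  m2 <- maxent_fit(dup_p, dup_b)
  pc2 <- percent_contribution(m2, dup_p, dup_b, seed = 3)
  expect_lt(abs(pc2["a1"] - pc2["a2"]), 10)

  # strong signal: presences pile up at high values of the real variable
  set.seed(4)
  strong_p <- data.frame(acc = rbeta(80, 12, 1), junk = runif(80))
  strong_b <- data.frame(acc = runif(400), junk = runif(400))
  m3 <- maxent_fit(strong_p, strong_b)
  pc3 <- percent_contribution(m3, strong_p, strong_b, seed = 5)
  expect_lt(unname(pc3["junk"]), 5)
})

test_that("a model file reproduces predictions bit for bit", {
  d <- make_toy_data(seed = 12)
  m <- maxent_fit(d$pres, d$bg, seed = 42)
  f <- withr::local_tempfile(fileext = ".txt")
  write_maxent_model(m, f)
  m2 <- read_maxent_model(f)
  expect_equal(predict(m2, d$bg), predict(m, d$bg), tolerance = 1e-15)
  expect_equal(predict(m2, d$pres, scale = "raw"), predict(m, d$pres, scale = "raw"),
               tolerance = 1e-15)
  expect_equal(m2$seed, 42L)
})
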