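#' Feature expansion for maximum-entropy modeling
#'
#' Builds the feature space of the presence-only model. Continuous variables
#' are min-max scaled to [0, 1] using the *background* sample only (the
#' scaling constants are stored and reused for any later prediction, with
#' clamping to [0, 1]); each contributes a linear and a quadratic feature
#' plus `h_hinge` forward hinge features at equally spaced knots
#' `k = 0, 1/h, ..., (h-1)/h`, `hinge_k(x) = max(0, (x - k) / (1 - k))`.
#' Categorical variables contribute one 0/1 indicator per category seen in
#' the background. Every feature therefore maps any point into [0, 1].
#'
#' @param background data.frame of variable values at background points.
#' @param types named character vector, `"continuous"` or `"categorical"`
#'   per variable; by default factors/characters are categorical.
#' @param h_hinge hinge features per continuous variable (default 8).
#' @return object of class `maxent_features` with a `$expand(data)` mapping.
#' @export
maxent_features <- function(background, types = NULL, h_hinge = 8) {
  stopifnot(is.data.frame(background), nrow(background) > 1)
  vars <- names(background)
  if (is.null(types))
    types <- vapply(background, function(v)
      if (is.numeric(v)) "continuous" else "categorical", character(1))
  types <- types[vars]
  stopifnot(all(types %in% c("continuous", "categorical")))
  defs <- list()
  for (v in vars) {
    x <- background[[v]]
    if (anyNA(x)) stop("missing values in variable '", v, "'")
    if (types[[v]] == "continuous") {
      lo <- min(x); hi <- max(x)
      if (!all(is.finite(c(lo, hi)))) stop("non-finite values in variable '", v, "'")
      defs[[v]] <- list(type = "continuous", min = lo, max = hi,
                        knots = if (h_hinge > 0) (seq_len(h_hinge) - 1) / h_hinge
                                else numeric(0))
    } else {
      defs[[v]] <- list(type = "categorical",
                        levels = sort(unique(as.character(x))))
    }
  }
  fe <- structure(list(defs = defs, h_hinge = h_hinge), class = "maxent_features")
  meta <- feature_meta(fe)
  fe$names <- meta$name
  fe$classes <- meta$class
  fe$variable <- meta$variable
  fe
}

feature_meta <- function(fe) {
  out <- list(name = character(0), class = character(0), variable = character(0))
  for (v in names(fe$defs)) {
    d <- fe$defs[[v]]
    if (d$type == "continuous") {
      out$name <- c(out$name, paste0(v, ":lin"), paste0(v, ":quad"),
                    if (length(d$knots)) sprintf("%s:hinge%.4g", v, d$knots))
      out$class <- c(out$class, "linear", "quadratic",
                     rep("hinge", length(d$knots)))
      out$variable <- c(out$variable, rep(v, 2 + length(d$knots)))
    } else {
      out$name <- c(out$name, paste0(v, "=", d$levels))
      out$class <- c(out$class, rep("categorical", length(d$levels)))
      out$variable <- c(out$variable, rep(v, length(d$levels)))
    }
  }
  out
}

#' @rdname maxent_features
#' @param fe a `maxent_features` object.
#' @param data data.frame holding every variable of the expansion.
#' @return `expand_features` returns the numeric feature matrix (points x
#'   features), all entries in [0, 1].
#' @export
expand_features <- function(fe, data) {
  stopifnot(inherits(fe, "maxent_features"))
  cols <- list()
  for (v in names(fe$defs)) {
    d <- fe$defs[[v]]
    if (is.null(data[[v]])) stop("data lacks variable '", v, "'")
    if (d$type == "continuous") {
      x <- as.numeric(data[[v]])
      if (any(!is.finite(x))) stop("non-finite values in variable '", v, "'")
      z <- if (d$max > d$min) (x - d$min) / (d$max - d$min) else rep(0, length(x))
      z <- pmin(pmax(z, 0), 1)
      cols[[length(cols) + 1L]] <- z
      cols[[length(cols) + 1L]] <- z^2
      for (k in d$knots)
        cols[[length(cols) + 1L]] <- pmax(0, (z - k) / (1 - k))
    } else {
      x <- as.character(data[[v]])
      for (lev in d$levels)
        cols[[length(cols) + 1L]] <- as.numeric(x == lev)
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- fe$names
  m
}

#' Default L1 regularization per feature class
#'
#' Base widths 0.05 (linear, quadratic), 0.5 (hinge), 0.25 (categorical),
#' scaled by `1/sqrt(n_presence)`: more presences allow tighter matching of
#' feature means.
#'
#' @param classes character vector of feature classes.
#' @param n_presence number of presence points.
#' @return numeric vector of beta_j.
#' @export
default_beta <- function(classes, n_presence) {
  base <- c(linear = 0.05, quadratic = 0.05, hinge = 0.5, categorical = 0.25)
  unname(base[classes]) / sqrt(n_presence)
}

#' Fit a presence-only maximum-entropy (Maxent-style) model
#'
#' Fits the Gibbs distribution `q(x) = exp(lambda . f(x)) / Z` over the
#' background by maximizing the L1-penalized mean presence log-likelihood
#' \deqn{J(\lambda) = \overline{\lambda\cdot f}_{presence} - \log Z(\lambda)
#'   - \sum_j \beta_j |\lambda_j|,}
#' with `Z` summed over the background sample. Optimization is proximal
#' gradient ascent (soft-thresholding step) with backtracking line search,
#' which keeps the penalized objective non-decreasing; iteration stops when
#' the objective improves by less than `tol` (default 1e-7) or after
#' `max_iter` (default 500) steps. At the optimum the fitted feature
#' expectations match the presence means within the regularization slack:
#' `|E_q[f_j] - mean_presence[f_j]| <= beta_j` for every feature.
#'
#' @param presence data.frame of variable values at presence points (>= 2).
#' @param background data.frame of variable values at background points.
#' @param types,h_hinge passed to [maxent_features()].
#' @param beta per-feature L1 widths; default [default_beta()].
#' @param max_iter,tol optimizer contract (see above).
#' @param seed stored in the model for provenance (fitting is deterministic).
#' @return object of class `maxent_model`: `lambda`, `beta`, `Z`, `entropy`
#'   (H of the fitted distribution over the background), the feature
#'   expansion, KKT slack diagnostics, and the objective trace.
#' @export
maxent_fit <- function(presence, background, types = NULL, h_hinge = 8,
                       beta = NULL, max_iter = 500, tol = 1e-7, seed = NA) {
  stopifnot(is.data.frame(presence), nrow(presence) >= 2)
  fe <- maxent_features(background, types = types, h_hinge = h_hinge)
  Fp <- expand_features(fe, presence)
  Fb <- expand_features(fe, background)
  if (is.null(beta)) beta <- default_beta(fe$classes, nrow(Fp))
  stopifnot(length(beta) == ncol(Fb), all(beta >= 0))

  fbar <- colMeans(Fp)
  p <- ncol(Fb)
  lambda <- numeric(p)
  if (all(apply(Fb, 2L, function(x) diff(range(x)) == 0))) {
    warning("all features are constant over the background; returning the uniform model")
    max_iter <- 0
  }

  logZ_q <- function(lam) {
    s <- drop(Fb %*% lam)
    mx <- max(s)
    lz <- mx + log(sum(exp(s - mx)))
    list(logZ = lz, q = exp(s - lz))
  }
  smooth_val <- function(lam, lz) sum(fbar * lam) - lz
  obj_trace <- numeric(0)
  st <- logZ_q(lambda)
  J <- smooth_val(lambda, st$logZ) - sum(beta * abs(lambda))
  step <- 1
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    grad <- fbar - drop(crossprod(Fb, st$q))
    repeat {
      cand <- lambda + step * grad
      cand <- sign(cand) * pmax(abs(cand) - step * beta, 0)
      st2 <- logZ_q(cand)
      g_new <- smooth_val(cand, st2$logZ)
      dlam <- cand - lambda
      # majorization bound on the (concave) smooth part
      ok <- g_new >= smooth_val(lambda, st$logZ) + sum(grad * dlam) -
        sum(dlam^2) / (2 * step) - 1e-12
      if (ok || step < 1e-12) break
      step <- step / 2
    }
    J_new <- g_new - sum(beta * abs(cand))
    if (J_new < J) break  # numerically stuck; keep the monotone iterate
    lambda <- cand; st <- st2
    improve <- J_new - J
    J <- J_new
    obj_trace <- c(obj_trace, J)
    if (improve < tol) break
    step <- step * 1.3
  }
  q <- st$q
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  Eqf <- drop(crossprod(Fb, q))
  structure(list(
    features = fe, lambda = stats::setNames(lambda, fe$names),
    beta = stats::setNames(beta, fe$names),
    logZ = st$logZ, Z = exp(st$logZ), entropy = H,
    presence_means = fbar, fitted_means = Eqf,
    kkt_slack = abs(Eqf - fbar) - beta,
    objective = J, objective_trace = obj_trace, iterations = iter,
    n_presence = nrow(Fp), n_background = nrow(Fb), seed = seed),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features over %d variables; %d presences, %d background\n",
              length(x$lambda), length(unique(x$features$variable)),
              x$n_presence, x$n_background))
  if (!is.null(x$objective))
    cat(sprintf("  penalized objective %.6f after %d iterations; entropy H = %.4f\n",
                x$objective, x$iterations, x$entropy))
  cat(sprintf("  nonzero weights: %d\n", sum(x$lambda != 0)))
  if (!is.null(x$kkt_slack))
    cat(sprintf("  max KKT slack violation: %.3g\n", max(x$kkt_slack)))
  invisible(x)
}

#' Predict deforestation risk from a fitted model
#'
#' `scale = "raw"` returns the relative occurrence rate
#' `q(x) * N_background` (the raw Gibbs density times the background size, so
#' it averages 1 over the background). `scale = "logistic"` — the default
#' risk scale — returns `q(x) e^H / (1 + q(x) e^H)` with `H` the entropy of
#' the fitted distribution; a completely uninformative model scores 0.5
#' everywhere. Both are monotone in `lambda . f(x)`.
#'
#' @param object a `maxent_model`.
#' @param newdata a data.frame of variables, or a [landscape_stack()] whose
#'   slots named like the model variables supply per-cell values.
#' @param scale `"logistic"` or `"raw"`.
#' @param ... unused.
#' @return numeric vector for data.frame input; a `grid_raster` risk map for
#'   stack input (`NA` on nodata cells).
#' @export
predict.maxent_model <- function(object, newdata, scale = c("logistic", "raw"), ...) {
  scale <- match.arg(scale)
  if (inherits(newdata, "landscape_stack")) {
    ref <- newdata[[1]]
    vars <- names(object$features$defs)
    miss <- setdiff(vars, names(newdata))
    if (length(miss)) stop("stack lacks model variables: ", paste(miss, collapse = ", "))
    valid <- !Reduce(`|`, lapply(newdata[vars], nodata_mask))
    df <- as.data.frame(lapply(newdata[vars], function(g) {
      v <- g$values[valid]
      if (!is.null(g$categories)) v <- g$categories[v]
      v
    }), optional = TRUE)
    names(df) <- vars
    out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
    out[valid] <- predict(object, df, scale = scale)
    return(grid_raster(out, ref$cell_size_m, ref$origin))
  }
  Fm <- expand_features(object$features, newdata)
  q <- exp(drop(Fm %*% object$lambda) - object$logZ)
  switch(scale,
         raw = q * object$n_background,
         logistic = {
           qe <- q * exp(object$entropy)
           qe / (1 + qe)
         })
}

#' Area under the ROC curve for presence vs background scores
#'
#' Rank-based AUC: the probability that a random presence point outscores a
#' random background point, ties counting one half. Background points act as
#' pseudo-absences, the standard presence-only evaluation.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in [0, 1].
#' @export
auc_presence_background <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  stopifnot(m > 0, n > 0)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Permutation-based percent contribution of each variable
#'
#' Importance of a variable is the mean drop in training gain (mean presence
#' log-likelihood relative to the uniform model) when that variable's values
#' are permuted across the pooled presence + background points, breaking its
#' association with presence while preserving its marginal distribution.
#' Drops are averaged over `m` seeded permutations, floored at zero, and
#' normalized to sum to 100.
#'
#' @param model a `maxent_model`.
#' @param presence,background the data the model was trained on.
#' @param m permutations per variable (default 10).
#' @param seed RNG seed for the permutations.
#' @return named numeric vector of percents summing to 100 (all zero, by
#'   convention uniform, if no variable has any effect).
#' @export
percent_contribution <- function(model, presence, background, m = 10, seed = 1) {
  vars <- names(model$features$defs)
  np <- nrow(presence)
  gain <- function(pres, bg) {
    Fp <- expand_features(model$features, pres)
    Fb <- expand_features(model$features, bg)
    s <- drop(Fb %*% model$lambda)
    mx <- max(s)
    lz <- mx + log(sum(exp(s - mx)))
    mean(drop(Fp %*% model$lambda)) - lz + log(nrow(bg))
  }
  g0 <- gain(presence, background)
  drops <- stats::setNames(numeric(length(vars)), vars)
  rng <- make_rng(seed)
  for (v in vars) {
    pooled <- c(as.character_or_num(presence[[v]]), as.character_or_num(background[[v]]))
    dv <- 0
    for (i in seq_len(m)) {
      perm <- pooled[sample_int(rng, length(pooled))]
      p2 <- presence; b2 <- background
      p2[[v]] <- perm[seq_len(np)]
      b2[[v]] <- perm[-seq_len(np)]
      dv <- dv + (g0 - gain(p2, b2))
    }
    drops[v] <- max(dv / m, 0)
  }
  if (sum(drops) == 0) return(drops)
  100 * drops / sum(drops)
}

as.character_or_num <- function(x) if (is.numeric(x)) x else as.character(x)

## local RNG helpers so package functions never disturb the caller's RNG state
make_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  }
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  eval(expr, envir = parent.frame())
}

sample_int <- function(rng, n, size = n, replace = FALSE)
  with_rng(rng, sample.int(n, size, replace = replace))

#' Replicate model runs with presence subsampling
#'
#' Runs `k` fits, each on a random `1 - holdout` fraction of the presences
#' (background shared), scores the held-out presences against the background
#' for a test AUC, and averages permutation percent contributions across
#' runs. Reseeded deterministically from `base_seed`, so the same base seed
#' reproduces the report exactly.
#'
#' @param presence,background training data (data.frames of variables).
#' @param k number of runs (default 100).
#' @param base_seed integer seed driving all subsampling and permutations.
#' @param holdout fraction of presences held out per run (default 0.3).
#' @param ... passed to [maxent_fit()].
#' @return object of class `maxent_report`: `auc_mean`, `auc_sd`,
#'   `contribution` (named percents summing to 100), `auc_runs`, `k`.
#' @export
maxent_replicate <- function(presence, background, k = 100, base_seed = 1,
                             holdout = 0.3, ...) {
  stopifnot(k >= 1, holdout > 0, holdout < 1)
  np <- nrow(presence)
  n_test <- max(1L, round(holdout * np))
  if (np - n_test < 2) stop("too few presences for the requested holdout")
  rng <- make_rng(base_seed)
  aucs <- numeric(k)
  contribs <- NULL
  for (i in seq_len(k)) {
    test_idx <- sample_int(rng, np, n_test)
    fit <- maxent_fit(presence[-test_idx, , drop = FALSE], background,
                      seed = base_seed + i, ...)
    sc_p <- predict(fit, presence[test_idx, , drop = FALSE], scale = "logistic")
    sc_b <- predict(fit, background, scale = "logistic")
    aucs[i] <- auc_presence_background(sc_p, sc_b)
    pc <- percent_contribution(fit, presence[-test_idx, , drop = FALSE],
                               background, seed = base_seed + 7919L * i)
    contribs <- if (is.null(contribs)) pc else contribs + pc
  }
  if (k == 1) warning("single run: AUC standard deviation is undefined, reported as 0")
  contribs <- contribs / k
  if (sum(contribs) > 0) contribs <- 100 * contribs / sum(contribs)
  structure(list(auc_mean = mean(aucs),
                 auc_sd = if (k > 1) stats::sd(aucs) else 0,
                 contribution = contribs, auc_runs = aucs, k = k),
            class = "maxent_report")
}

#' @export
print.maxent_report <- function(x, ...) {
  cat(sprintf("<maxent_report> %d runs: mean test AUC %.3f (SD %.3f)\n",
              x$k, x$auc_mean, x$auc_sd))
  cat("  percent contribution:\n")
  for (v in names(sort(x$contribution, decreasing = TRUE)))
    cat(sprintf("    %-28s %5.1f\n", v, x$contribution[v]))
  invisible(x)
}

#' @rdname maxent_replicate
#' @param report a `maxent_report`.
#' @param path output path for the delimited (tab-separated) report table.
#' @export
write_maxent_report <- function(report, path) {
  df <- data.frame(variable = names(report$contribution),
                   percent_contribution = round(as.numeric(report$contribution), 1),
                   auc_mean = round(report$auc_mean, 3),
                   auc_sd = round(report$auc_sd, 3))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
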