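#' Serialize a fitted maxent model as plain text
#'
#' Writes everything needed for bit-reproducible prediction: variable
#' definitions with their background scaling constants, hinge knots or
#' category levels, per-feature weights and regularization, the background
#' normalizer and entropy, and training metadata. The format is a plain
#' UTF-8 document with `key=value` lines and two tab-separated blocks.
#'
#' @param model a `maxent_model`.
#' @param path output file.
#' @return `path`, invisibly; `read_maxent_model` returns a `maxent_model`
#'   usable with [predict.maxent_model()].
#' @export
write_maxent_model <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  num <- function(x) formatC(x, format = "g", digits = 17)
  ln <- c("deforisk_maxent_model 1",
          paste0("n_presence=", model$n_presence),
          paste0("n_background=", model$n_background),
          paste0("logZ=", num(model$logZ)),
          paste0("entropy=", num(model$entropy)),
          paste0("seed=", model$seed),
          paste0("h_hinge=", model$features$h_hinge),
          "[variables]")
  for (v in names(model$features$defs)) {
    d <- model$features$defs[[v]]
    ln <- c(ln, if (d$type == "continuous")
      paste(v, "continuous", num(d$min), num(d$max),
            paste(num(d$knots), collapse = ","), sep = "\t")
      else paste(v, "categorical", "", "",
                 paste(d$levels, collapse = ","), sep = "\t"))
  }
  ln <- c(ln, "[features]")
  for (j in seq_along(model$lambda))
    ln <- c(ln, paste(names(model$lambda)[j], model$features$classes[j],
                      model$features$variable[j], num(model$lambda[j]),
                      num(model$beta[j]), sep = "\t"))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  ln <- readLines(path)
  if (!startsWith(ln[1], "deforisk_maxent_model"))
    stop("not a deforisk maxent model file: ", path)
  kv <- function(key) {
    hit <- grep(paste0("^", key, "="), ln, value = TRUE)[1]
    sub("^[^=]*=", "", hit)
  }
  iv <- which(ln == "[variables]"); ifx <- which(ln == "[features]")
  defs <- list()
  for (row in ln[seq(iv + 1L, ifx - 1L)]) {
    p <- strsplit(row, "\t", fixed = TRUE)[[1]]
    defs[[p[1]]] <- if (p[2] == "continuous")
      list(type = "continuous", min = as.numeric(p[3]), max = as.numeric(p[4]),
           knots = if (nzchar(p[5])) as.numeric(strsplit(p[5], ",")[[1]]) else numeric(0))
    else list(type = "categorical", levels = strsplit(p[5], ",")[[1]])
  }
  fe <- structure(list(defs = defs, h_hinge = as.numeric(kv("h_hinge"))),
                  class = "maxent_features")
  meta <- feature_meta(fe)
  fe$names <- meta$name; fe$classes <- meta$class; fe$variable <- meta$variable
  frows <- do.call(rbind, strsplit(ln[seq(ifx + 1L, length(ln))], "\t", fixed = TRUE))
  lambda <- stats::setNames(as.numeric(frows[, 4]), frows[, 1])
  beta <- stats::setNames(as.numeric(frows[, 5]), frows[, 1])
  stopifnot(identical(names(lambda), fe$names))
  logZ <- as.numeric(kv("logZ"))
  structure(list(features = fe, lambda = lambda, beta = beta,
                 logZ = logZ, Z = exp(logZ),
                 entropy = as.numeric(kv("entropy")),
                 n_presence = as.integer(kv("n_presence")),
                 n_background = as.integer(kv("n_background")),
                 seed = suppressWarnings(as.integer(kv("seed")))),
            class = "maxent_model")
}
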