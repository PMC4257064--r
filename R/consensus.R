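#' Consensus change layer from multiple classifications
#'
#' Combines forest/non-forest grids from one or more classifiers into a
#' conservative change layer. A cell is *deforested* only when every source
#' labels it forest at the start date and non-forest at the end date;
#' *stable forest* only when every source labels it forest at both dates;
#' everything else — including any cell that is cloud/nodata in any source —
#' is *undetermined* and never used as presence or absence. The three masks
#' partition the grid, and adding a source can only shrink the deforested
#' mask.
#'
#' @param sources list with one element per classifier, each a list with
#'   aligned forest-mask grids `start` and `end` (TRUE/1 = forest, `NA` =
#'   cloud/nodata).
#' @return object of class `change_layer` with grids `deforested`,
#'   `stable_forest`, `undetermined`.
#' @export
consensus <- function(sources) {
  if (!length(sources)) stop("consensus needs at least one source")
  ref <- sources[[1]]$start
  for (i in seq_along(sources)) {
    s <- sources[[i]]
    if (is.null(s$start) || is.null(s$end))
      stop("each source needs 'start' and 'end' forest grids")
    check_aligned(ref, s$start, "source 1 start", paste("source", i, "start"))
    check_aligned(ref, s$end, "source 1 start", paste("source", i, "end"))
  }
  defo <- stable <- matrix(TRUE, nrow(ref$values), ncol(ref$values))
  any_na <- matrix(FALSE, nrow(ref$values), ncol(ref$values))
  for (s in sources) {
    f1 <- s$start$values > 0; f2 <- s$end$values > 0
    any_na <- any_na | is.na(f1) | is.na(f2)
    defo <- defo & !is.na(f1) & f1 & !is.na(f2) & !f2
    stable <- stable & !is.na(f1) & f1 & !is.na(f2) & f2
  }
  defo[any_na] <- FALSE
  stable[any_na] <- FALSE
  g <- function(m) grid_raster(m, ref$cell_size_m, ref$origin)
  structure(list(deforested = g(defo), stable_forest = g(stable),
                 undetermined = g(!(defo | stable))),
            class = "change_layer")
}

#' @export
print.change_layer <- function(x, ...) {
  cat(sprintf("<change_layer> deforested %g ha, stable forest %g ha, undetermined %g ha\n",
              area_ha(x$deforested), area_ha(x$stable_forest), area_ha(x$undetermined)))
  invisible(x)
}

sample_cells <- function(mask, n, seed, class_label) {
  idx <- which(mask$values > 0)
  if (n > length(idx))
    stop(sprintf("requested %d points but only %d cells are available", n, length(idx)))
  rng <- make_rng(seed)
  take <- idx[sample_int(rng, length(idx), n)]
  nr <- nrow(mask$values)
  pts <- cell_centers(mask, ((take - 1L) %% nr) + 1L, ((take - 1L) %/% nr) + 1L)
  data.frame(id = seq_len(n), pts, class = class_label)
}

#' Sample presence points from the deforested mask
#'
#' Uniform sample without replacement of deforested cells, one point per
#' cell at the cell center. The conventional presence count is 500 but `n`
#' is free.
#'
#' @param change a [consensus()] change layer.
#' @param n number of points (default 500); must not exceed the number of
#'   deforested cells.
#' @param seed RNG seed; same seed, same sample.
#' @return data.frame: `id`, `row`, `col`, `x`, `y`, `class`.
#' @export
sample_presence <- function(change, n = 500, seed = 1) {
  stopifnot(inherits(change, "change_layer"))
  sample_cells(change$deforested, n, seed, "deforestation")
}

#' Sample background points over the study area
#'
#' Uniform sample without replacement over non-nodata study cells; used both
#' as the maximum-entropy background and as no-change candidate points.
#'
#' @param x a [landscape_stack()] (study area = cells valid in every grid)
#'   or a single `grid_raster` (study area = its non-nodata cells).
#' @inheritParams sample_presence
#' @export
sample_background <- function(x, n = 500, seed = 1) {
  if (inherits(x, "landscape_stack")) {
    valid <- !Reduce(`|`, lapply(x, nodata_mask))
    ref <- x[[1]]
  } else {
    stopifnot(inherits(x, "grid_raster"))
    valid <- !nodata_mask(x)
    ref <- x
  }
  sample_cells(grid_raster(valid, ref$cell_size_m, ref$origin),
               n, seed, "background")
}

#' Write sampled points as a delimited table
#' @param points data.frame from [sample_presence()]/[sample_background()].
#' @param path output path (tab-separated).
#' @export
write_points <- function(points, path) {
  utils::write.table(points, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract variable values at sampled points
#'
#' Looks up each point's cell in the named grids of a stack, translating
#' categorical grids to their category labels.
#'
#' @param stack a [landscape_stack()].
#' @param points data.frame with `row`, `col`.
#' @param vars stack slot names to extract.
#' @return data.frame of variable values, one row per point.
#' @export
extract_values <- function(stack, points, vars) {
  miss <- setdiff(vars, names(stack))
  if (length(miss)) stop("stack lacks: ", paste(miss, collapse = ", "))
  out <- lapply(vars, function(v) {
    g <- stack[[v]]
    val <- g$values[cbind(points$row, points$col)]
    if (!is.null(g$categories)) g$categories[val] else val
  })
  stats::setNames(as.data.frame(out, optional = TRUE), vars)
}
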