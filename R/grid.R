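#' Planar raster grid
#'
#' Lightweight raster data model used throughout the package: a 2-D matrix of
#' values on a square-cell planar grid, with `NA` marking nodata cells. Row 1
#' is the top of the map; indexing is `[row, col]`. The default cell size of
#' 100 m gives 1-ha cells, the working resolution of the analysis.
#'
#' Coordinates are planar (projected) units: `origin` is the (x, y) of the
#' grid's lower-left corner, and the center of cell `[r, c]` on an
#' `nr x nc` grid is `x = x0 + (c - 0.5) * cell_size_m`,
#' `y = y0 + (nr - r + 0.5) * cell_size_m`. No CRS handling is done.
#'
#' @param values numeric (or integer-coded categorical) matrix; `NA` = nodata.
#' @param cell_size_m cell edge length in meters (default 100, i.e. 1 ha).
#' @param origin numeric length-2, planar (x, y) of the lower-left corner.
#' @param categories optional character vector naming the categories of an
#'   integer-coded categorical grid (code k means `categories[k]`).
#' @return An object of class `grid_raster`.
#' @examples
#' g <- grid_raster(matrix(runif(25), 5, 5))
#' cell_area_ha(g)
#' @export
grid_raster <- function(values, cell_size_m = 100, origin = c(0, 0),
                        categories = NULL) {
  if (is.logical(values)) storage.mode(values) <- "integer"
  stopifnot(is.matrix(values), is.numeric(values),
            length(cell_size_m) == 1L, cell_size_m > 0,
            length(origin) == 2L, is.numeric(origin))
  if (!is.null(categories)) {
    stopifnot(is.character(categories))
    codes <- values[!is.na(values)]
    if (length(codes) && (any(codes < 1) || any(codes > length(categories))))
      stop("categorical grid holds codes outside the category table")
  }
  structure(list(values = values,
                 cell_size_m = as.numeric(cell_size_m),
                 origin = as.numeric(origin),
                 categories = categories),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_raster> %d x %d cells, %.6g m cells (%.4g ha), origin (%g, %g)\n",
              d[1], d[2], x$cell_size_m, cell_area_ha(x), x$origin[1], x$origin[2]))
  cat(sprintf("  nodata cells: %d; range: [%g, %g]\n",
              sum(is.na(x$values)),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  if (!is.null(x$categories))
    cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @rdname grid_raster
#' @param g a `grid_raster`.
#' @export
cell_area_ha <- function(g) g$cell_size_m^2 / 1e4

#' @rdname grid_raster
#' @export
nodata_mask <- function(g) is.na(g$values)

#' Check that grids share geometry
#'
#' All grids in one analysis must share shape, cell size and origin; any
#' spatial operation on misaligned grids is an error naming both grids.
#'
#' @param a,b `grid_raster` objects.
#' @param name_a,name_b labels used in the error message.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_aligned <- function(a, b, name_a = deparse(substitute(a)),
                          name_b = deparse(substitute(b))) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$cell_size_m, b$cell_size_m)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop(sprintf("grids '%s' and '%s' are not aligned (shape/cell size/origin differ)",
                 name_a, name_b))
  invisible(TRUE)
}

#' Planar coordinates of cell centers
#'
#' @param g a `grid_raster`.
#' @param rows,cols integer vectors of 1-based row/column indices (row 1 = top).
#' @return data.frame with columns `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(g, rows, cols) {
  nr <- nrow(g$values)
  cs <- g$cell_size_m
  data.frame(row = rows, col = cols,
             x = g$origin[1] + (cols - 0.5) * cs,
             y = g$origin[2] + (nr - rows + 0.5) * cs)
}

#' Area of a boolean mask in hectares
#'
#' Counts `TRUE`, non-nodata cells and multiplies by the cell area. `NA`
#' (nodata) cells never contribute.
#'
#' @param mask a logical matrix or a `grid_raster` of 0/1 values.
#' @param cell_size_m cell size, only used when `mask` is a bare matrix.
#' @return area in ha.
#' @export
area_ha <- function(mask, cell_size_m = 100) {
  if (inherits(mask, "grid_raster")) {
    cell_size_m <- mask$cell_size_m
    mask <- mask$values
  }
  sum(mask > 0, na.rm = TRUE) * cell_size_m^2 / 1e4
}

#' Euclidean distance to the nearest TRUE cell
#'
#' For every cell, the center-to-center Euclidean distance in meters to the
#' nearest `TRUE` cell of `mask` (0 on `TRUE` cells themselves). Used to build
#' the distance-to-previous-deforestation explanatory variable. Nodata cells
#' are neither reference features nor receive a distance (`NA` out).
#'
#' @param mask logical `grid_raster` (or 0/1 values); at least one `TRUE` cell.
#' @return `grid_raster` of distances in meters.
#' @export
distance_transform <- function(mask) {
  stopifnot(inherits(mask, "grid_raster"))
  m <- mask$values > 0
  m[is.na(m)] <- FALSE
  if (!any(m)) stop("distance_transform: mask has no TRUE cells (no reference features)")
  # EBImage::distmap gives each nonzero pixel its distance to the nearest zero
  # pixel, so feed it the complement of the feature mask.
  d <- EBImage::distmap(matrix(as.numeric(!m), nrow(m), ncol(m)), metric = "euclidean")
  d <- matrix(as.numeric(d), nrow(m), ncol(m)) * mask$cell_size_m
  d[is.na(mask$values)] <- NA_real_
  grid_raster(d, mask$cell_size_m, mask$origin)
}

#' Connected patches of a boolean mask
#'
#' Labels 8-connected components of `TRUE` cells (diagonal contact joins a
#' patch) and summarizes each patch: cell count, area in ha, and centroid as
#' the mean of member cell centers. Nodata cells are treated as `FALSE`.
#'
#' @param mask logical `grid_raster` (or 0/1 values).
#' @return list with `labels` (integer matrix, 0 = background) and `patches`
#'   (data.frame: `id`, `n_cells`, `area_ha`, `centroid_row`, `centroid_col`,
#'   `centroid_x`, `centroid_y`), patches ordered by id.
#' @export
connected_patches <- function(mask) {
  stopifnot(inherits(mask, "grid_raster"))
  m <- mask$values > 0
  m[is.na(m)] <- FALSE
  nr <- nrow(m); nc <- ncol(m)
  labels <- matrix(0L, nr, nc)
  empty <- list(labels = labels,
                patches = data.frame(id = integer(), n_cells = integer(),
                                     area_ha = numeric(), centroid_row = numeric(),
                                     centroid_col = numeric(), centroid_x = numeric(),
                                     centroid_y = numeric()))
  idx <- which(m)
  if (!length(idx)) return(empty)
  pos <- match(seq_len(nr * nc), idx)  # linear index -> vertex id
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  # 8-neighbor edges (4 forward directions to avoid duplicates)
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + d[1]; c2 <- cols + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- !is.na(pos[j])
    if (any(keep))
      edges <- c(edges, rbind(which(ok)[keep], pos[j][keep]))
  }
  gr <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(gr)$membership
  labels[idx] <- as.integer(comp)
  cen <- cell_centers(mask, rows, cols)
  n_cells <- as.integer(tabulate(comp))
  patches <- data.frame(
    id = seq_along(n_cells),
    n_cells = n_cells,
    area_ha = n_cells * cell_area_ha(mask),
    centroid_row = as.numeric(tapply(rows, comp, mean)),
    centroid_col = as.numeric(tapply(cols, comp, mean)),
    centroid_x = as.numeric(tapply(cen$x, comp, mean)),
    centroid_y = as.numeric(tapply(cen$y, comp, mean)))
  list(labels = labels, patches = patches)
}

#' Stack of co-registered landscape grids
#'
#' Bundles the explanatory-variable and forest-mask grids of one analysis and
#' enforces mutual alignment. Conventional slots (any may be absent until
#' computed): `forest_<date>` forest/non-forest masks, `land_cover`
#' (categorical), `slope` (degrees), `land_designation` (categorical),
#' `roads`, `rivers`, `towns` (boolean features), `dist_deforestation` (m),
#' `accessibility`, `carbon_density` (Mg C/ha).
#'
#' @param ... named `grid_raster` objects, or a single named list of them.
#' @return object of class `landscape_stack` (a named list of grids).
#' @export
landscape_stack <- function(...) {
  grids <- list(...)
  if (length(grids) == 1L && is.list(grids[[1]]) && !inherits(grids[[1]], "grid_raster"))
    grids <- grids[[1]]
  if (!length(grids) || is.null(names(grids)) || any(names(grids) == ""))
    stop("landscape_stack needs named grids")
  for (nm in names(grids)) {
    if (!inherits(grids[[nm]], "grid_raster"))
      stop(sprintf("stack member '%s' is not a grid_raster", nm))
    check_aligned(grids[[1]], grids[[nm]], names(grids)[1], nm)
  }
  structure(grids, class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  d <- dim(x[[1]]$values)
  cat(sprintf("<landscape_stack> %d grids, %d x %d cells @ %.6g m\n",
              length(x), d[1], d[2], x[[1]]$cell_size_m))
  cat(" ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Add or replace a grid in a stack
#' @param stack a `landscape_stack`.
#' @param name slot name.
#' @param g aligned `grid_raster`.
#' @export
stack_set <- function(stack, name, g) {
  check_aligned(stack[[1]], g, names(stack)[1], name)
  stack[[name]] <- g
  class(stack) <- "landscape_stack"
  stack
}
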