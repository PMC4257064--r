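#' Read and write planar raster grids
#'
#' Two on-disk formats are supported:
#' \itemize{
#' \item ESRI ASCII grid (`.asc`): plain text, exact round-trip (values are
#'   printed with 17 significant digits). Nodata cells are written as the
#'   header's `NODATA_value` (-9999 by default).
#' \item GeoTIFF (`.tif`/`.tiff`): single-band, uncompressed, little-endian
#'   IEEE float32 with ModelPixelScale/ModelTiepoint tags carrying cell size
#'   and origin; nodata is stored as NaN. Round-trips are exact for any
#'   float32-representable values.
#' }
#' Categorical grids write a plain-text sidecar `<path>.categories.txt`
#' (`code=name` lines) that `read_grid()` picks up automatically.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"auto"`, `"ascii"` or `"gtiff"`.
#' @param grid a `grid_raster`.
#' @param nodata_value numeric written for nodata cells in ASCII grids.
#' @return `read_grid` returns a `grid_raster`; `write_grid` returns `path`
#'   invisibly.
#' @export
read_grid <- function(path, format = c("auto", "ascii", "gtiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  g <- if (format == "ascii") read_ascii_grid(path) else read_geotiff(path)
  side <- paste0(path, ".categories.txt")
  if (file.exists(side)) g$categories <- read_category_table(side)
  g
}

#' @rdname read_grid
#' @export
write_grid <- function(grid, path, format = c("auto", "ascii", "gtiff"),
                       nodata_value = -9999) {
  stopifnot(inherits(grid, "grid_raster"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "ascii") write_ascii_grid(grid, path, nodata_value)
  else write_geotiff(grid, path)
  if (!is.null(grid$categories))
    write_category_table(grid$categories, paste0(path, ".categories.txt"))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) "gtiff"
  else if (ext %in% c("asc", "agr", "txt")) "ascii"
  else stop(sprintf("cannot infer grid format from extension '.%s'", ext))
}

write_category_table <- function(categories, path) {
  writeLines(sprintf("%d=%s", seq_along(categories), categories), path)
}

read_category_table <- function(path) {
  ln <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  code <- as.integer(sub("=.*", "", ln))
  categories <- sub("^[^=]*=", "", ln)
  categories[order(code)]
}

## ---- ESRI ASCII grid -------------------------------------------------------

read_ascii_grid <- function(path) {
  ln <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing ", paste(setdiff(need, names(hdr)), collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(ln[i:length(ln)], collapse = "\n"),
               quiet = TRUE, what = numeric())
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d", length(vals), nr * nc))
  m <- matrix(vals, nr, nc, byrow = TRUE)  # rows run top to bottom
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
        else if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2 else 0
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
        else if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2 else 0
  grid_raster(m, cell_size_m = hdr$cellsize, origin = c(x0, y0))
}

write_ascii_grid <- function(grid, path, nodata_value = -9999) {
  m <- grid$values
  if (any(!is.na(m) & m == nodata_value))
    stop("grid contains the nodata sentinel value ", nodata_value,
         "; choose another nodata_value")
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size_m),
           sprintf("NODATA_value %.10g", nodata_value))
  body <- apply(m, 1L, function(r) {
    r[is.na(r)] <- nodata_value
    paste(formatC(r, format = "g", digits = 17), collapse = " ")
  })
  writeLines(c(hdr, body), path)
}

## ---- minimal single-band float32 GeoTIFF ----------------------------------
## Baseline TIFF, uncompressed, one strip per image, IEEE float32 samples.
## Geo-referencing uses ModelPixelScaleTag (33550) and ModelTiepointTag
## (33922); nodata cells are stored as NaN.

write_geotiff <- function(grid, path) {
  m <- grid$values
  nr <- nrow(m); nc <- ncol(m)
  vals <- as.numeric(t(m))            # row-major, top row first
  vals[is.na(vals)] <- NaN
  cs <- grid$cell_size_m
  scale <- c(cs, cs, 0)
  # tiepoint: raster (0,0,0) -> model (x_topleft, y_topleft, 0)
  tie <- c(0, 0, 0, grid$origin[1], grid$origin[2] + nr * cs, 0)
  n_tags <- 12L
  ifd_off <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  off_scale <- ifd_off + ifd_size
  off_tie <- off_scale + 24L
  off_strip <- off_tie + 48L
  strip_bytes <- nr * nc * 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")

  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {          # SHORT inline
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {                                   # LONG inline or offset
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(n_tags, con, size = 2, endian = "little")
  tag(256, 3, 1, nc)                 # ImageWidth
  tag(257, 3, 1, nr)                 # ImageLength
  tag(258, 3, 1, 32)                 # BitsPerSample
  tag(259, 3, 1, 1)                  # Compression = none
  tag(262, 3, 1, 1)                  # Photometric = BlackIsZero
  tag(273, 4, 1, off_strip)          # StripOffsets
  tag(277, 3, 1, 1)                  # SamplesPerPixel
  tag(278, 3, 1, nr)                 # RowsPerStrip
  tag(279, 4, 1, strip_bytes)        # StripByteCounts
  tag(339, 3, 1, 3)                  # SampleFormat = IEEE float
  tag(33550, 12, 3, off_scale)       # ModelPixelScale (DOUBLE x3)
  tag(33922, 12, 6, off_tie)         # ModelTiepoint (DOUBLE x6)
  writeBin(0L, con, size = 4, endian = "little")  # next IFD = none
  writeBin(scale, con, size = 8, endian = "little")
  writeBin(tie, con, size = 8, endian = "little")
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

read_geotiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  bom <- rawToChar(raw[1:2])
  endian <- if (bom == "II") "little" else if (bom == "MM") "big"
            else stop("not a TIFF file: ", path)
  rint <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4L)
  rdouble <- function(off, n)
    readBin(raw[(off + 1):(off + 8 * n)], "double", n = n, size = 8, endian = endian)
  if (rint(2, 2) != 42L) stop("not a TIFF file: ", path)
  ifd <- rint(4, 4)
  n_tags <- rint(ifd, 2)
  tags <- list()
  for (k in seq_len(n_tags)) {
    e <- ifd + 2L + (k - 1L) * 12L
    id <- rint(e, 2); type <- rint(e + 2, 2); count <- rint(e + 4, 4)
    tsize <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[type]
    total <- tsize * count
    voff <- if (total <= 4L) e + 8L else rint(e + 8, 4)
    val <- switch(as.character(type),
      "3" = rint(voff, 2, count),
      "4" = rint(voff, 4, count),
      "12" = rdouble(voff, count),
      "2" = rawToChar(raw[(voff + 1):(voff + count)][raw[(voff + 1):(voff + count)] != as.raw(0)]),
      rint(voff, 1, count))
    tags[[as.character(id)]] <- val
  }
  need <- function(id) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) stop("TIFF missing required tag ", id)
    v
  }
  nc <- need(256); nr <- need(257)
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
    stop("only uncompressed TIFF is supported (compression tag ",
         tags[["259"]], ")")
  bps <- if (is.null(tags[["258"]])) 32L else tags[["258"]][1]
  fmt <- if (is.null(tags[["339"]])) 3L else tags[["339"]][1]
  if (bps != 32L || fmt != 3L)
    stop("only 32-bit IEEE float samples are supported")
  offs <- need(273)
  counts <- if (is.null(tags[["279"]])) nr * nc * 4L else tags[["279"]]
  vals <- numeric(0)
  for (s in seq_along(offs)) {
    nsamp <- counts[min(s, length(counts))] %/% 4L
    vals <- c(vals, readBin(raw[(offs[s] + 1):(offs[s] + nsamp * 4L)],
                            "double", n = nsamp, size = 4, endian = endian))
  }
  if (length(vals) != nr * nc)
    stop(sprintf("TIFF strip data has %d samples, expected %d", length(vals), nr * nc))
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[is.nan(m)] <- NA_real_
  cs <- if (!is.null(tags[["33550"]])) tags[["33550"]][1] else 100
  tie <- tags[["33922"]]
  origin <- if (!is.null(tie)) c(tie[4], tie[5] - nr * cs) else c(0, 0)
  grid_raster(m, cell_size_m = cs, origin = origin)
}
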