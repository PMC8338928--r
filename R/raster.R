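# A minimal planar raster: regular grid in local projected metres.
# values[ix, iy] with ix indexing x (west -> east) and iy indexing y
# (south -> north); cell centres at (x0 + (ix - 0.5) * cell, ...).

#' Construct a planar grid
#'
#' @param x0,y0 Lower-left corner (metres, local projection).
#' @param cell Cell size in metres.
#' @param nx,ny Number of columns (x) and rows (y).
#' @param values Numeric matrix `nx` by `ny`, or a single value to fill.
#' @return An object of class `planar_grid`.
#' @export
planar_grid <- function(x0, y0, cell, nx, ny, values = NA_real_) {
  stopifnot(cell > 0, nx >= 1, ny >= 1)
  if (!is.matrix(values)) values <- matrix(values, nrow = nx, ncol = ny)
  stopifnot(nrow(values) == nx, ncol(values) == ny)
  structure(
    list(x0 = x0, y0 = y0, cell = cell, nx = nx, ny = ny, values = values),
    class = "planar_grid"
  )
}

#' @export
print.planar_grid <- function(x, ...) {
  cat(sprintf(
    "<planar_grid: %d x %d cells of %g m, origin (%.0f, %.0f)>\n",
    x$nx, x$ny, x$cell, x$x0, x$y0
  ))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#' @param grid A `planar_grid`.
#' @return List with numeric vectors `x` (length nx) and `y` (length ny).
#' @export
grid_centres <- function(grid) {
  list(
    x = grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell,
    y = grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell
  )
}

#' Nearest-cell lookup
#'
#' @param grid A `planar_grid`.
#' @param x,y Planar coordinates (metres).
#' @return Numeric vector of cell values; `NA` outside the extent, with
#'   attribute `outside` (logical vector).
#' @export
grid_lookup <- function(grid, x, y) {
  ix <- floor((x - grid$x0) / grid$cell) + 1
  iy <- floor((y - grid$y0) / grid$cell) + 1
  outside <- ix < 1 | ix > grid$nx | iy < 1 | iy > grid$ny | !is.finite(ix) | !is.finite(iy)
  out <- rep(NA_real_, length(x))
  if (any(!outside)) {
    out[!outside] <- grid$values[cbind(ix[!outside], iy[!outside])]
  }
  attr(out, "outside") <- outside
  out
}

#' Write a grid as an ESRI ASCII raster (.asc)
#'
#' Plain-text, georeferenced in the local planar metres of the analysis.
#'
#' @param grid A `planar_grid`.
#' @param path Output path.
#' @param nodata NODATA sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$nx),
    paste("nrows", grid$ny),
    paste("xllcorner", format(grid$x0, scientific = FALSE)),
    paste("yllcorner", format(grid$y0, scientific = FALSE)),
    paste("cellsize", format(grid$cell, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  v <- grid$values
  v[!is.finite(v)] <- nodata
  for (iy in rev(seq_len(grid$ny))) { # rows north -> south
    writeLines(paste(format(v[, iy], digits = 17, trim = TRUE), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster written by [write_ascii_grid()]
#' @param path Input path.
#' @return A `planar_grid`; NODATA cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  nx <- as.integer(hdr$ncols)
  ny <- as.integer(hdr$nrows)
  vals <- matrix(NA_real_, nrow = nx, ncol = ny)
  for (r in seq_len(ny)) {
    row <- as.numeric(strsplit(trimws(lines[i + r - 1]), "\\s+")[[1]])
    vals[, ny - r + 1] <- row
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  planar_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nx, ny, vals)
}
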