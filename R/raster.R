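#' Construct a DEM raster
#'
#' Minimal georeferenced elevation grid: a numeric matrix whose first row is
#' the northernmost range of pixels, an affine transform given by the
#' lower-left corner and square pixel size, and a nodata sentinel.
#'
#' @param values Numeric matrix of elevations in meters (row 1 = top/north).
#' @param xll,yll Coordinates of the lower-left corner of the grid (meters).
#' @param pixel_size Square pixel edge in meters (> 0).
#' @param nodata Sentinel value for missing cells (default -9999).
#' @return Object of class `dem_raster`.
#' @export
dem_raster <- function(values, xll = 0, yll = 0, pixel_size = 1,
                       nodata = -9999) {
  stopifnot(is.matrix(values), pixel_size > 0)
  bad <- !is.finite(values) & values != nodata
  if (any(bad, na.rm = TRUE)) stop("non-finite values other than nodata")
  structure(list(values = values, xll = xll, yll = yll,
                 pixel_size = pixel_size, nodata = nodata),
            class = "dem_raster")
}

#' @export
print.dem_raster <- function(x, ...) {
  v <- x$values[x$values != x$nodata]
  cat(sprintf(
    "<dem_raster> %d x %d px @ %.3g m, origin (%.2f, %.2f), range [%.3f, %.3f] m\n",
    nrow(x$values), ncol(x$values), x$pixel_size, x$xll, x$yll,
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Pixel-center coordinates of a DEM raster
#'
#' @param r A `dem_raster`.
#' @return List with `x` (per column) and `y` (per row, decreasing) center
#'   coordinates in meters.
#' @export
pixel_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$pixel_size,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$pixel_size)
}

#' Write a DEM as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster (ncols/nrows/xllcorner/yllcorner/cellsize/nodata
#' header followed by rows north to south), readable by GDAL and most GIS
#' tools.
#'
#' @param r A `dem_raster`.
#' @param path Output path.
#' @export
write_dem_asc <- function(r, path) {
  stopifnot(inherits(r, "dem_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$pixel_size),
    sprintf("NODATA_value %.10g", r$nodata)
  ), con)
  utils::write.table(format(r$values, trim = TRUE, digits = 8,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a DEM from an ESRI ASCII grid
#'
#' @param path `.asc` path written by [write_dem_asc()] or any GIS tool.
#' @return A `dem_raster`.
#' @export
read_dem_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (!k %in% key) stop("missing ESRI ASCII header field: ", k)
  }
  nodata <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = val[["nrows"]], ncol = val[["ncols"]],
              byrow = TRUE)
  dem_raster(m, xll = val[["xllcorner"]], yll = val[["yllcorner"]],
             pixel_size = val[["cellsize"]], nodata = nodata)
}

#' Differential DEM: pre-lodging minus post-lodging
#'
#' Positive values indicate elevation loss (canopy drop).  Nodata in either
#' layer propagates to the differential.
#'
#' @param pre,post `dem_raster` layers on the same grid (identical shape,
#'   origin, pixel size, and nodata convention).
#' @return A `dem_raster` of per-pixel `pre - post`.
#' @export
differential_dem <- function(pre, post) {
  stopifnot(inherits(pre, "dem_raster"), inherits(post, "dem_raster"))
  if (!identical(dim(pre$values), dim(post$values))) {
    stop("alignment error: raster shapes differ (",
         paste(dim(pre$values), collapse = "x"), " vs ",
         paste(dim(post$values), collapse = "x"), ")")
  }
  if (pre$xll != post$xll || pre$yll != post$yll ||
      pre$pixel_size != post$pixel_size) {
    stop("alignment error: transforms differ")
  }
  if (pre$nodata != post$nodata) stop("alignment error: nodata conventions differ")
  na_mask <- pre$values == pre$nodata | post$values == post$nodata
  if (all(na_mask)) stop("empty raster: all pixels are nodata")
  d <- pre$values - post$values
  d[na_mask] <- pre$nodata
  dem_raster(d, xll = pre$xll, yll = pre$yll,
             pixel_size = pre$pixel_size, nodata = pre$nodata)
}

# Even-odd rule point-in-polygon, vectorized over points; boundary points
# are treated as outside (strict interior, consistent with the
# pixel-center-in-polygon membership rule).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Extract differential pixels for one plot polygon
#'
#' Returns the values of all pixels whose center lies strictly inside the
#' polygon, with nodata cells removed.  An empty selection (polygon outside
#' the raster, or fully nodata) is flagged through the `"empty"` attribute
#' rather than silently returning zeros.
#'
#' @param r A `dem_raster` (typically the differential DEM).
#' @param polygon Either a k x 2 matrix of vertices (meters, same frame as
#'   the raster) or a named vector/list with `x_min`, `x_max`, `y_min`,
#'   `y_max` for an axis-aligned rectangle.
#' @return Numeric vector of pixel values; attributes `n_inside` (pixel
#'   centers inside, before nodata removal) and `empty` (TRUE if no pixels
#'   were selected).
#' @export
extract_plot_pixels <- function(r, polygon) {
  stopifnot(inherits(r, "dem_raster"))
  ctr <- pixel_centers(r)
  if (!is.matrix(polygon)) {
    polygon <- as.list(polygon)
    polygon <- matrix(c(polygon$x_min, polygon$y_min,
                        polygon$x_max, polygon$y_min,
                        polygon$x_max, polygon$y_max,
                        polygon$x_min, polygon$y_max),
                      ncol = 2, byrow = TRUE)
  }
  bx <- range(polygon[, 1]); by <- range(polygon[, 2])
  cols <- which(ctr$x > bx[1] & ctr$x < bx[2])
  rows <- which(ctr$y > by[1] & ctr$y < by[2])
  if (length(cols) == 0 || length(rows) == 0) {
    return(structure(numeric(0), n_inside = 0L, empty = TRUE))
  }
  px <- rep(ctr$x[cols], each = length(rows))
  py <- rep(ctr$y[rows], times = length(cols))
  keep <- points_in_polygon(px, py, polygon)
  idx <- cbind(rep(rows, times = length(cols))[keep],
               rep(cols, each = length(rows))[keep])
  vals <- r$values[idx]
  n_inside <- length(vals)
  vals <- vals[vals != r$nodata]
  structure(vals, n_inside = n_inside, empty = length(vals) == 0)
}
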