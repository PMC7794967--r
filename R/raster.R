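#' In-memory raster with a geotransform
#'
#' Minimal single-band raster container used throughout the package. Values
#' are stored as a matrix with row 1 the northernmost row; the geotransform
#' is the north-west corner plus a square pixel size in projected meters.
#'
#' @param values numeric or integer matrix; row 1 = north.
#' @param xmin x coordinate of the west edge (m).
#' @param ymax y coordinate of the north edge (m).
#' @param cell_size pixel side length (m).
#' @param crs character tag naming the projected reference system; rasters
#'   entering the same analysis must carry identical tags.
#' @param type `"categorical"` (integer class codes) or `"continuous"`.
#' @param legend named integer vector mapping class names to codes
#'   (categorical rasters only).
#' @param nodata value marking missing pixels (default 0 for categorical,
#'   -9999 for continuous).
#' @return An object of class `kh_raster`.
#' @export
kh_raster <- function(values, xmin = 0, ymax = nrow(values) * cell_size,
                      cell_size = 1000, crs = "local-m",
                      type = c("continuous", "categorical"),
                      legend = NULL, nodata = NULL) {
  type <- match.arg(type)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (cell_size <= 0) stop("`cell_size` must be positive")
  if (is.null(nodata)) nodata <- if (type == "categorical") 0L else -9999
  if (type == "categorical") {
    storage.mode(values) <- "integer"
    if (is.null(legend)) legend <- landuse_legend()
    codes <- unique(values[values != nodata & !is.na(values)])
    unknown <- setdiff(codes, legend)
    if (length(unknown) > 0)
      stop("codes not in legend: ", paste(unknown, collapse = ", "))
  }
  structure(
    list(values = values, xmin = xmin, ymax = ymax, cell_size = cell_size,
         crs = crs, type = type, legend = legend, nodata = nodata),
    class = "kh_raster"
  )
}

#' @export
print.kh_raster <- function(x, ...) {
  cat(sprintf("<kh_raster> %d x %d pixels @ %g m, %s, crs=%s\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$type, x$crs))
  invisible(x)
}

#' @export
dim.kh_raster <- function(x) dim(x$values)

#' Land-use legend used by the package
#'
#' Eight ecological classes (the levels carrying an ecological value
#' coefficient) plus built-up land. Codes are arbitrary but fixed.
#'
#' @return Named integer vector, class name -> raster code.
#' @export
landuse_legend <- function() {
  c(farmland = 1L, forestland = 2L, shrubland = 3L,
    grassland_high = 4L, grassland_mid = 5L, grassland_low = 6L,
    water = 7L, builtup = 8L, unused = 9L)
}

#' Pixel-center coordinates of a raster
#'
#' @param r a [kh_raster].
#' @return data.frame with columns `row`, `col`, `x`, `y`, `value`.
#' @export
raster_pixels <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  data.frame(
    row = row, col = col,
    x = r$xmin + (col - 0.5) * r$cell_size,
    y = r$ymax - (row - 0.5) * r$cell_size,
    value = as.vector(r$values)
  )
}

#' Mask of valid (non-NoData) pixels
#' @param r a [kh_raster].
#' @return logical matrix.
#' @export
raster_valid <- function(r) {
  v <- r$values != r$nodata
  v[is.na(v)] <- FALSE
  v & !is.na(r$values)
}

same_registration <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$xmin, a$ymax, a$cell_size), c(b$xmin, b$ymax, b$cell_size))) &&
    identical(a$crs, b$crs)
}

stop_if_misregistered <- function(a, b, what = "rasters") {
  if (!same_registration(a, b))
    stop(what, " do not share grid registration (extent, resolution, CRS)")
  invisible(TRUE)
}

#' Slope in degrees from a DEM (Horn's method)
#'
#' 3x3 finite-difference slope estimator with edge replication at the raster
#' border, the common GIS default. A single-pixel DEM yields zero slope.
#'
#' @param dem a continuous [kh_raster] of elevations in meters with square
#'   pixels.
#' @return A continuous [kh_raster] of slope in degrees.
#' @export
slope_deg <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr == 1 && nc == 1) {
    return(kh_raster(matrix(0, 1, 1), dem$xmin, dem$ymax, dem$cell_size,
                     dem$crs, "continuous"))
  }
  # edge-replicated padded matrix
  ri <- c(1, seq_len(nr), nr)
  ci <- c(1, seq_len(nc), nc)
  p <- z[ri, ci, drop = FALSE]
  i <- seq_len(nr) + 1L; j <- seq_len(nc) + 1L
  a <- p[i - 1L, j - 1L]; b <- p[i - 1L, j]; cc <- p[i - 1L, j + 1L]
  d <- p[i,      j - 1L];                    f <- p[i,      j + 1L]
  g <- p[i + 1L, j - 1L]; h <- p[i + 1L, j]; k <- p[i + 1L, j + 1L]
  s <- dem$cell_size
  dzdx <- ((cc + 2 * f + k) - (a + 2 * d + g)) / (8 * s)
  dzdy <- ((g + 2 * h + k) - (a + 2 * b + cc)) / (8 * s)
  deg <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  kh_raster(deg, dem$xmin, dem$ymax, dem$cell_size, dem$crs, "continuous")
}
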