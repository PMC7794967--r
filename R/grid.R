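#' Build the analysis fishnet
#'
#' Tiles a rectangular extent with square cells, enumerated row-major from
#' the north-west corner with ids contiguous from 0. Cells are half-open,
#' `[x, x + s) x (y - s, y]`, so every point of the plane belongs to exactly
#' one cell. Edge cells that extend past the extent (when the extent is not
#' an exact multiple of the cell size) are kept but flagged `boundary`.
#'
#' @param extent numeric vector `c(xmin, xmax, ymin, ymax)` in projected
#'   meters.
#' @param cell_size_m cell side length, default 2000 (a 2 x 2 km grid).
#' @param crs reference-system tag.
#' @return An object of class `kh_grid`: a data.frame with columns
#'   `cell_id` (0-based), `row`, `col` (1-based from NW), cell bounds
#'   `xmin`/`xmax`/`ymin`/`ymax`, center `x`/`y`, and `boundary`.
#' @export
build_fishnet <- function(extent, cell_size_m = 2000, crs = "local-m") {
  if (length(extent) != 4) stop("extent must be c(xmin, xmax, ymin, ymax)")
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent is degenerate")
  if (cell_size_m <= 0) stop("cell_size_m must be positive")
  s <- cell_size_m
  ncol <- ceiling((extent[2] - extent[1]) / s)
  nrow <- ceiling((extent[4] - extent[3]) / s)
  col <- rep(seq_len(ncol), times = nrow)
  row <- rep(seq_len(nrow), each = ncol)
  xmin <- extent[1] + (col - 1) * s
  ymax <- extent[4] - (row - 1) * s
  g <- data.frame(
    cell_id = seq_len(ncol * nrow) - 1L,
    row = row, col = col,
    xmin = xmin, xmax = xmin + s,
    ymin = ymax - s, ymax = ymax,
    x = xmin + s / 2, y = ymax - s / 2,
    boundary = (xmin + s > extent[2] + 1e-9) | (ymax - s < extent[3] - 1e-9)
  )
  structure(g, class = c("kh_grid", "data.frame"),
            cell_size = s, crs = crs, n_row = nrow, n_col = ncol,
            extent = extent)
}

#' Cell id containing each point
#'
#' Applies the grid's half-open cell convention; points outside the gridded
#' area get `NA`.
#'
#' @param grid a [build_fishnet()] grid.
#' @param x,y point coordinates (m).
#' @return integer vector of 0-based cell ids (NA outside the grid).
#' @export
cell_id_at <- function(grid, x, y) {
  s <- attr(grid, "cell_size")
  ext <- attr(grid, "extent")
  n_col <- attr(grid, "n_col"); n_row <- attr(grid, "n_row")
  col <- floor((x - ext[1]) / s)            # [x, x+s): left edge inclusive
  row <- floor((ext[4] - y) / s)            # (y-s, y]: top edge inclusive
  id <- row * n_col + col
  bad <- col < 0 | col >= n_col | row < 0 | row >= n_row
  id[bad] <- NA_integer_
  as.integer(id)
}

# 1-based cell index (into grid rows) per raster pixel, NA when the pixel
# center falls outside the grid or the pixel is NoData.
pixel_cell_index <- function(raster, grid) {
  if (!identical(raster$crs, attr(grid, "crs")))
    stop("raster and grid CRS differ: ", raster$crs, " vs ", attr(grid, "crs"))
  px <- raster_pixels(raster)
  idx <- cell_id_at(grid, px$x, px$y) + 1L
  valid <- as.vector(raster_valid(raster))
  idx[!valid] <- NA_integer_
  list(idx = idx, value = px$value, valid = valid)
}

#' Per-cell fraction of pixels in a set of classes
#'
#' For each grid cell, the count of valid pixels whose center falls inside
#' the cell and whose code is in `class_codes`, divided by the count of all
#' valid pixels in the cell. Cells with no valid pixel are missing.
#'
#' @param raster a categorical [kh_raster].
#' @param grid a [build_fishnet()] grid sharing the raster's CRS.
#' @param class_codes integer codes (or class names resolved through the
#'   raster legend) counted in the numerator.
#' @param name,epoch labels attached to the returned layer.
#' @return An indicator layer: data.frame `cell_id`, `value` with attributes
#'   `name` and `epoch`.
#' @export
zonal_fraction <- function(raster, grid, class_codes, name = "fraction",
                           epoch = NA) {
  if (raster$type != "categorical") stop("zonal_fraction needs a categorical raster")
  if (is.character(class_codes)) {
    miss <- setdiff(class_codes, names(raster$legend))
    if (length(miss) > 0) stop("unknown class name(s): ", paste(miss, collapse = ", "))
    class_codes <- unname(raster$legend[class_codes])
  }
  pc <- pixel_cell_index(raster, grid)
  n <- nrow(grid)
  tot <- tabulate(pc$idx, nbins = n)
  hit <- tabulate(pc$idx[pc$value %in% class_codes], nbins = n)
  value <- ifelse(tot > 0, hit / tot, NA_real_)
  indicator_layer(grid, value, name, epoch)
}

#' Per-cell mean of a continuous raster
#'
#' Mean over valid pixels whose center falls in each cell; missing when a
#' cell covers no valid pixel.
#'
#' @inheritParams zonal_fraction
#' @param raster a continuous [kh_raster].
#' @return An indicator layer (see [zonal_fraction()]).
#' @export
zonal_mean <- function(raster, grid, name = "mean", epoch = NA) {
  pc <- pixel_cell_index(raster, grid)
  n <- nrow(grid)
  keep <- !is.na(pc$idx)
  tot <- tabulate(pc$idx[keep], nbins = n)
  sums <- rep(0, n)
  agg <- tapply(pc$value[keep], pc$idx[keep], sum)
  sums[as.integer(names(agg))] <- agg
  value <- ifelse(tot > 0, sums / tot, NA_real_)
  indicator_layer(grid, value, name, epoch)
}

#' Construct an indicator layer
#'
#' One real value (or NA) per grid cell, labeled with an indicator name and
#' epoch. The workhorse value container between the zonal engine and the
#' composite index.
#'
#' @param grid a [build_fishnet()] grid.
#' @param values numeric vector, one per cell (recycled scalars allowed).
#' @param name indicator label.
#' @param epoch year label.
#' @return data.frame `cell_id`, `value` with attributes `name`, `epoch`.
#' @export
indicator_layer <- function(grid, values, name = "indicator", epoch = NA) {
  if (length(values) == 1) values <- rep(values, nrow(grid))
  if (length(values) != nrow(grid))
    stop("values length (", length(values), ") != number of cells (", nrow(grid), ")")
  structure(data.frame(cell_id = grid$cell_id, value = as.numeric(values)),
            name = name, epoch = epoch, class = c("kh_layer", "data.frame"))
}

#' Pixel values grouped by grid cell
#'
#' Used by the per-cell landscape metrics, which need the raw pixel codes of
#' each cell rather than a summary.
#'
#' @param raster a categorical [kh_raster].
#' @param grid a [build_fishnet()] grid.
#' @return list (one element per cell, in cell-id order) of matrices of
#'   pixel codes with their local row/col layout preserved; `NULL` for empty
#'   cells.
#' @export
cell_pixel_blocks <- function(raster, grid) {
  if (!identical(raster$crs, attr(grid, "crs")))
    stop("raster and grid CRS differ")
  px <- raster_pixels(raster)
  idx <- cell_id_at(grid, px$x, px$y) + 1L
  valid <- as.vector(raster_valid(raster))
  out <- vector("list", nrow(grid))
  keep <- which(!is.na(idx) & valid)
  sp <- split(keep, idx[keep])
  for (nm in names(sp)) {
    sel <- sp[[nm]]
    rows <- px$row[sel]; cols <- px$col[sel]
    m <- matrix(NA_integer_, max(rows) - min(rows) + 1L,
                max(cols) - min(cols) + 1L)
    m[cbind(rows - min(rows) + 1L, cols - min(cols) + 1L)] <- px$value[sel]
    out[[as.integer(nm)]] <- m
  }
  out
}
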