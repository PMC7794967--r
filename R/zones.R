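#' Dissolved buffer around mine points
#'
#' The union of disks of one radius around every mine. The union is kept
#' analytically (centers + radius): membership tests reduce to a distance
#' minimum and the area is evaluated by scanline integration of the union
#' of chord intervals, so no polygon engine is needed.
#'
#' @param mines data.frame with columns `x`, `y` (>= 1 row).
#' @param radius_m buffer distance in meters (> 0).
#' @return object of class `kh_buffer`: list with `mines`, `radius_m`,
#'   `n_mines`, `area_m2`.
#' @export
buffer_union <- function(mines, radius_m) {
  if (is.null(mines) || nrow(mines) == 0) stop("empty mine list")
  if (radius_m <= 0) stop("radius must be positive")
  structure(list(mines = mines[, c("x", "y")], radius_m = radius_m,
                 n_mines = nrow(mines),
                 area_m2 = disk_union_area(mines$x, mines$y, radius_m)),
            class = "kh_buffer")
}

# area of a union of equal-radius disks by scanline integration: at each x
# the union of y-chords is merged exactly; the x-integral uses midpoint
# evaluation on a fine step (relative error well below 1e-3).
disk_union_area <- function(cx, cy, r, n_steps_per_r = 2000) {
  dx <- r / n_steps_per_r
  xs <- seq(min(cx) - r + dx / 2, max(cx) + r, by = dx)
  total <- 0
  for (x in xs) {
    act <- which(abs(x - cx) < r)
    if (length(act) == 0) next
    half <- sqrt(r^2 - (x - cx[act])^2)
    lo <- cy[act] - half; hi <- cy[act] + half
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    # merge overlapping intervals
    cur_lo <- lo[1]; cur_hi <- hi[1]; len <- 0
    if (length(lo) > 1) {
      for (k in 2:length(lo)) {
        if (lo[k] > cur_hi) {
          len <- len + (cur_hi - cur_lo)
          cur_lo <- lo[k]; cur_hi <- hi[k]
        } else cur_hi <- max(cur_hi, hi[k])
      }
    }
    len <- len + (cur_hi - cur_lo)
    total <- total + len * dx
  }
  total
}

#' Is each point inside the buffer?
#'
#' @param zone a [buffer_union()] object.
#' @param x,y point coordinates.
#' @return logical vector.
#' @export
in_buffer <- function(zone, x, y) {
  vapply(seq_along(x), function(i)
    any((x[i] - zone$mines$x)^2 + (y[i] - zone$mines$y)^2 <=
          zone$radius_m^2), logical(1))
}

#' @export
print.kh_buffer <- function(x, ...) {
  cat(sprintf("<kh_buffer> %d mines, r = %g m, area = %.1f km2\n",
              x$n_mines, x$radius_m, x$area_m2 / 1e6))
  invisible(x)
}

#' Zonal P/S/R/ESH statistics of a buffer
#'
#' Unweighted means of the pressure, state, response subscores and of ESH
#' over grid cells whose centers fall inside the buffer, per epoch; missing
#' cells are excluded. The mean ESH equals the sum of the three mean
#' subscores (linearity of the mean).
#'
#' @param zone a [buffer_union()] object.
#' @param esh_tab a [compute_esh()] result (all epochs).
#' @param grid the [build_fishnet()] grid the ESH table lives on.
#' @return data.frame `epoch`, `P`, `S`, `R`, `ESH`, `n_cells` (one row per
#'   epoch; NAs with a warning when no cell center falls in the zone).
#' @export
zone_stats <- function(zone, esh_tab, grid) {
  inside_ids <- grid$cell_id[in_buffer(zone, grid$x, grid$y)]
  if (length(inside_ids) == 0)
    warning("buffer contains no cell centers; zone statistics are missing")
  out <- NULL
  for (ep in unique(esh_tab$epoch)) {
    sub <- esh_tab[esh_tab$epoch == ep & esh_tab$cell_id %in% inside_ids, ]
    sub <- sub[!is.na(sub$ESH), ]
    out <- rbind(out, data.frame(
      epoch = ep,
      P = if (nrow(sub)) mean(sub$P) else NA_real_,
      S = if (nrow(sub)) mean(sub$S) else NA_real_,
      R = if (nrow(sub)) mean(sub$R) else NA_real_,
      ESH = if (nrow(sub)) mean(sub$ESH) else NA_real_,
      n_cells = nrow(sub)))
  }
  out
}

#' Health-class tallies at the mine points
#'
#' Each mine takes the health class of the grid cell containing it; counts
#' per class per epoch always sum to the number of mines (mines on cells
#' with missing classification are tallied as "missing").
#'
#' @param mines data.frame with `x`, `y`.
#' @param esh_tab a [compute_esh()] result carrying a `class` column.
#' @param grid the [build_fishnet()] grid.
#' @return data.frame `epoch`, `class`, `n`.
#' @export
mine_health_counts <- function(mines, esh_tab, grid) {
  if (!"class" %in% names(esh_tab))
    stop("esh_tab has no 'class' column; classify ESH first")
  cell <- cell_id_at(grid, mines$x, mines$y)
  lv <- c(levels(esh_tab$class), "missing")
  out <- NULL
  for (ep in unique(esh_tab$epoch)) {
    sub <- esh_tab[esh_tab$epoch == ep, ]
    cls <- as.character(sub$class[match(cell, sub$cell_id)])
    cls[is.na(cls)] <- "missing"
    tab <- table(factor(cls, levels = lv))
    out <- rbind(out, data.frame(epoch = ep, class = names(tab),
                                 n = as.integer(tab)))
  }
  out
}

#' Write buffer geometry as GeoJSON
#'
#' The disk union is discretized per mine as a polygonized circle (the
#' consuming GIS dissolves overlaps on display); mainly an interchange
#' convenience.
#'
#' @param zone a [buffer_union()] object.
#' @param path output path.
#' @param n_vertices vertices per circle.
#' @export
write_buffer_geojson <- function(zone, path, n_vertices = 64) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)
  feats <- lapply(seq_len(zone$n_mines), function(i) {
    ring <- lapply(ang, function(a)
      c(zone$mines$x[i] + zone$radius_m * cos(a),
        zone$mines$y[i] + zone$radius_m * sin(a)))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(mine = i, radius_m = zone$radius_m))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
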