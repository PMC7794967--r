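#' Ecological levels of the land-use classes
#'
#' Per-class ecological value coefficients \eqn{D} used by the change
#' direction score: higher means ecologically more valuable cover. Built-up
#' land carries no published level and defaults to 0 (below unused land),
#' reflecting that conversion to construction is the most ecologically
#' negative transition; it is configurable.
#'
#' @param builtup level assigned to built-up land (default 0).
#' @return named numeric vector, class name -> level.
#' @export
eco_levels <- function(builtup = 0) {
  c(farmland = 0.11, forestland = 0.245, shrubland = 0.147,
    grassland_high = 0.125, grassland_mid = 0.063, grassland_low = 0.018,
    water = 0.282, builtup = builtup, unused = 0.01)
}

#' Land-use transition matrix between two epochs
#'
#' Entry (i, j) is the area (km^2) coded class i at the first epoch and
#' class j at the second, from a pixel-by-pixel cross-tabulation. Pixels
#' that are NoData in either epoch are excluded.
#'
#' @param lu_t1,lu_t2 co-registered categorical [kh_raster] objects sharing
#'   a legend.
#' @param interval optional `c(year1, year2)` label.
#' @return object of class `kh_transition`: list with `classes`, `area`
#'   (named square matrix, km^2), `interval`, `pixel_area_km2`.
#' @export
transition_matrix <- function(lu_t1, lu_t2, interval = c(NA, NA)) {
  stop_if_misregistered(lu_t1, lu_t2, "land-use rasters")
  if (!identical(lu_t1$legend, lu_t2$legend))
    stop("land-use rasters have different legends")
  valid <- raster_valid(lu_t1) & raster_valid(lu_t2)
  legend <- lu_t1$legend
  f1 <- factor(lu_t1$values[valid], levels = legend, labels = names(legend))
  f2 <- factor(lu_t2$values[valid], levels = legend, labels = names(legend))
  px_km2 <- (lu_t1$cell_size / 1000)^2
  area <- unclass(table(f1, f2)) * px_km2
  dimnames(area) <- list(names(legend), names(legend))
  structure(list(classes = names(legend), area = area, interval = interval,
                 pixel_area_km2 = px_km2),
            class = "kh_transition")
}

#' @export
print.kh_transition <- function(x, ...) {
  cat(sprintf("<kh_transition> %s -> %s, %.0f km2 total, %.0f km2 changed\n",
              x$interval[1], x$interval[2], sum(x$area),
              sum(x$area) - sum(diag(x$area))))
  print(round(x$area, 2))
  invisible(x)
}

#' Write a transition matrix as labeled CSV
#' @param tm a [transition_matrix()] result.
#' @param path output path.
#' @export
write_transition_csv <- function(tm, path) {
  utils::write.csv(as.data.frame(tm$area), path, row.names = TRUE)
  invisible(path)
}

#' Land-use change direction score (LCDM)
#'
#' Transition-area-weighted mean change in ecological level,
#' \deqn{LCDM = \sum_{i \ne j} A_{ij} (D_j - D_i) / A \times 100\%,}
#' where \eqn{A_{ij}} is the area moving from class i to class j, \eqn{D}
#' the per-class ecological level and \eqn{A} the total changed
#' (off-diagonal) area. Positive when land converts toward ecologically
#' higher-valued classes; 0 when nothing changed.
#'
#' @param tm a [transition_matrix()] result.
#' @param levels named level vector, default [eco_levels()].
#' @return percentage (scalar).
#' @export
lcdm <- function(tm, levels = eco_levels()) {
  miss <- setdiff(tm$classes, names(levels))
  if (length(miss) > 0)
    stop("no ecological level for class(es): ", paste(miss, collapse = ", "))
  if (any(levels < 0)) stop("ecological levels must be >= 0")
  D <- levels[tm$classes]
  a <- tm$area
  diag(a) <- 0
  A <- sum(a)
  if (A == 0) return(0)
  sum(a * outer(D, D, function(di, dj) dj - di)) / A * 100
}

#' Single land-use dynamic degree
#'
#' Annual relative rate of change of one class,
#' \eqn{K = (U_b - U_a) / (U_a T) \times 100\%} per year, with the class
#' areas at the two epochs read off the transition matrix margins.
#'
#' @param tm a [transition_matrix()] result.
#' @param class_name class whose rate is computed.
#' @param years interval length in years (> 0).
#' @return percent per year; `NA` (with a warning) when the class is absent
#'   at the first epoch.
#' @export
single_dynamic_degree <- function(tm, class_name, years) {
  if (!class_name %in% tm$classes) stop("unknown class: ", class_name)
  if (years <= 0) stop("years must be positive")
  a1 <- sum(tm$area[class_name, ])
  a2 <- sum(tm$area[, class_name])
  if (a1 == 0) {
    warning("class '", class_name, "' has zero area at the first epoch; ",
            "dynamic degree undefined")
    return(NA_real_)
  }
  (a2 - a1) / a1 / years * 100
}
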