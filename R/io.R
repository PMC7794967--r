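#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by every desktop GIS. Land-use
#' rasters are written as integer codes (NoData 0 by default), continuous
#' surfaces as floats (NoData -9999).
#'
#' @param r a [kh_raster].
#' @param path output file path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- r$values
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", r$xmin),
    sprintf("yllcorner %.6f", r$ymax - nrow(v) * r$cell_size),
    sprintf("cellsize %.6f", r$cell_size),
    sprintf("NODATA_value %s", format(r$nodata, scientific = FALSE))
  ), con)
  fmt <- if (r$type == "categorical") "%d" else "%.6g"
  for (i in seq_len(nrow(v)))
    writeLines(paste(sprintf(fmt, v[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param type `"continuous"` or `"categorical"`.
#' @param crs reference-system tag to attach.
#' @param legend legend for categorical rasters (default [landuse_legend()]).
#' @return a [kh_raster].
#' @export
read_ascii_grid <- function(path, type = c("continuous", "categorical"),
                            crs = "local-m", legend = NULL) {
  type <- match.arg(type)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- scan(text = lines[i:length(lines)], quiet = TRUE)
  v <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else
    if (type == "categorical") 0 else -9999
  if (type == "categorical") {
    storage.mode(v) <- "integer"
    nodata <- as.integer(nodata)
  }
  kh_raster(v, xmin = hdr$xllcorner,
            ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
            cell_size = hdr$cellsize, crs = crs, type = type,
            legend = legend, nodata = nodata)
}

#' Write point features as GeoJSON
#'
#' @param points data.frame with columns `x`, `y` (projected meters) and any
#'   extra property columns.
#' @param path output path.
#' @param crs_name name recorded in the (legacy) GeoJSON `crs` member.
#' @export
write_points_geojson <- function(points, path, crs_name = "local-m") {
  props <- setdiff(names(points), c("x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(points$x[i], points$y[i])),
      properties = as.list(points[i, props, drop = FALSE])
    )
  })
  obj <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = crs_name)),
    features = feats
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON point features
#'
#' @param path GeoJSON file with Point features.
#' @return data.frame with columns `x`, `y` plus feature properties.
#' @export
read_points_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- obj$features
  xy <- t(vapply(feats, function(f) unlist(f$geometry$coordinates),
                 numeric(2)))
  out <- data.frame(x = xy[, 1], y = xy[, 2])
  if (length(feats) > 0 && length(feats[[1]]$properties) > 0) {
    props <- do.call(rbind, lapply(feats, function(f)
      as.data.frame(f$properties, stringsAsFactors = FALSE)))
    out <- cbind(out, props)
  }
  out
}

#' Export indicator layers as long-format CSV
#'
#' One row per (cell, epoch, indicator): the package's tabular interchange
#' format for grid-level values.
#'
#' @param ind long data.frame with columns `cell_id`, `epoch`, `indicator`,
#'   `value`.
#' @param path output CSV path.
#' @export
write_indicator_csv <- function(ind, path) {
  utils::write.csv(ind[, c("cell_id", "epoch", "indicator", "value")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a scene / analysis configuration file
#'
#' YAML or JSON, keyed by extension. Configuration carries the coefficient
#' tables, the rocky-desertification rule and the weight scheme; missing
#' entries fall back to package defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml or .json file: ", path)
  }
}
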