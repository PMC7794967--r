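#' Compute all twelve indicators for every epoch of a scene
#'
#' Runs the zonal engine over the scene's rasters and assembles the long
#' indicator table the composite index consumes: four pressure indicators
#' (population density, man-made interference, reclamation rate,
#' steep-farmland ratio), six state indicators (vegetation coverage, SHEI,
#' SHDI, contagion, resilience, ecosystem-service value) and two response
#' indicators (forest proportion, rocky-desertification sensitivity).
#'
#' @param scene a [generate_scene()] result (or an equivalently shaped list
#'   of rasters built from real data).
#' @param grid a [build_fishnet()] grid on the scene extent.
#' @param interference,resilience,esv per-class coefficient tables, default
#'   [coefficient_table()] defaults.
#' @param rds the [rds_rule()] used for rocky-desertification sensitivity.
#' @param steep_threshold_deg slope threshold of the steep-farmland
#'   indicator, default 25 degrees.
#' @return long data.frame `cell_id`, `epoch`, `indicator`, `value`.
#' @export
compute_indicators <- function(scene, grid,
                               interference = coefficient_table("interference"),
                               resilience = coefficient_table("resilience"),
                               esv = coefficient_table("esv"),
                               rds = rds_rule(),
                               steep_threshold_deg = 25) {
  slope <- slope_deg(scene$dem)
  epochs <- as.numeric(names(scene$landuse_series))
  out <- vector("list", length(epochs))
  for (e in seq_along(epochs)) {
    ep <- epochs[e]
    lu <- scene$landuse_series[[e]]
    lm <- landscape_metrics(lu, grid, ep)
    veg <- vegetation_coverage(lu, grid, ep)
    layers <- list(
      pop_density(scene$pop_series[[e]], grid, ep),
      area_weighted_index(lu, grid, interference, "interference", ep),
      reclamation_rate(lu, grid, ep),
      steep_farmland_ratio(lu, slope, grid, steep_threshold_deg, ep),
      veg,
      lm$shei, lm$shdi, lm$contag,
      area_weighted_index(lu, grid, resilience, "resilience", ep),
      area_weighted_index(lu, grid, esv, "esv", ep),
      forest_proportion(lu, grid, ep),
      rds_sensitivity(slope, veg, scene$carbonate_mask, grid, rds, ep)
    )
    out[[e]] <- do.call(rbind, lapply(layers, function(l)
      data.frame(cell_id = l$cell_id, epoch = ep,
                 indicator = attr(l, "name"), value = l$value)))
  }
  do.call(rbind, out)
}

#' Run the full ecosystem-health assessment on a scene
#'
#' End-to-end convenience wrapper: indicators, pooled normalization and the
#' P/S/R/ESH composite, pooled Jenks five-level health classification, the
#' urbanization index, per-epoch global bivariate Moran's I between
#' urbanization and ESH with permutation inference, local LISA clusters for
#' the final epoch, and mine-buffer zonal statistics.
#'
#' @param scene a [generate_scene()] result.
#' @param grid_cell_m analysis cell size, default 2000 m.
#' @param weights a [weight_scheme()].
#' @param n_perm permutations for Moran/LISA inference.
#' @param alpha LISA significance level.
#' @param buffer_radii_m mine-buffer radii, default `c(2000, 3000, 6000)`.
#' @param seed seed for the permutation tests.
#' @return list of class `kh_assessment` with elements `grid`, `indicators`,
#'   `esh` (with health classes), `breaks`, `urbanization`, `moran`
#'   (per-epoch data.frame), `lisa` (final epoch), `zone_stats` (per
#'   radius), `mine_counts`, `scene`.
#' @export
run_assessment <- function(scene, grid_cell_m = 2000,
                           weights = weight_scheme(), n_perm = 999,
                           alpha = 0.05,
                           buffer_radii_m = c(2000, 3000, 6000),
                           seed = 1L) {
  grid <- build_fishnet(scene$params$extent, grid_cell_m,
                        crs = scene$params$crs)
  ind <- compute_indicators(scene, grid)
  esh_tab <- compute_esh(ind, weights)
  breaks <- jenks_breaks(esh_tab$ESH, k = 5)
  esh_tab$class <- classify_esh(esh_tab$ESH, breaks)

  epochs <- as.numeric(names(scene$landuse_series))
  pop_layers <- lapply(seq_along(epochs), function(e)
    pop_density(scene$pop_series[[e]], grid, epochs[e]))
  gdp_layers <- lapply(seq_along(epochs), function(e)
    zonal_mean(scene$gdp_series[[e]], grid, "gdp", epochs[e]))
  clp_layers <- lapply(seq_along(epochs), function(e)
    clp(scene$landuse_series[[e]], grid, epochs[e]))
  urb <- urbanization_index(pop_layers, gdp_layers, clp_layers)

  moran <- NULL
  lisa <- NULL
  for (e in seq_along(epochs)) {
    ep <- epochs[e]
    u <- urb$U[urb$epoch == ep]
    h <- esh_tab$ESH[esh_tab$epoch == ep]
    ok <- !is.na(u) & !is.na(h)
    W <- build_weights(grid, "queen", include = grid$cell_id[ok])
    mt <- moran_permutation_test(u[ok], h[ok], W, n_perm,
                                 seed = seed + e)
    moran <- rbind(moran, data.frame(
      epoch = ep, I = mt$I_obs, z_value = mt$z_value,
      pseudo_p = mt$pseudo_p, permutations = mt$permutations, n = sum(ok)))
    if (e == length(epochs))
      lisa <- bivariate_lisa(u[ok], h[ok], W, n_perm, alpha,
                             seed = seed + 100L)
  }

  zs <- NULL
  mine_counts <- NULL
  if (nrow(scene$mines) > 0) {
    for (r in buffer_radii_m) {
      zone <- buffer_union(scene$mines, r)
      st <- zone_stats(zone, esh_tab, grid)
      st$radius_m <- r
      zs <- rbind(zs, st)
    }
    mine_counts <- mine_health_counts(scene$mines, esh_tab, grid)
  }

  structure(list(grid = grid, indicators = ind, esh = esh_tab,
                 breaks = breaks, urbanization = urb, moran = moran,
                 lisa = lisa, zone_stats = zs, mine_counts = mine_counts,
                 scene = scene),
            class = "kh_assessment")
}

#' @export
print.kh_assessment <- function(x, ...) {
  eps <- unique(x$esh$epoch)
  cat(sprintf("<kh_assessment> %d cells x %d epochs (%s-%s)\n",
              nrow(x$grid), length(eps), min(eps), max(eps)))
  cat("scene-mean ESH by epoch:\n")
  print(round(tapply(x$esh$ESH, x$esh$epoch, mean, na.rm = TRUE), 3))
  cat("bivariate Moran's I (urbanization vs ESH):\n")
  print(transform(x$moran, I = round(I, 3), z_value = round(z_value, 2)))
  invisible(x)
}
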