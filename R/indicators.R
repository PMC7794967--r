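#' Default per-class coefficient tables
#'
#' Area-weighted coefficient tables behind three composite indicators:
#' `interference` (man-made interference H, hemeroby-style: high for
#' built-up and farmland, low for near-natural cover), `resilience`
#' (ecological resilience ERI: high for forest and water, low for built-up),
#' and `esv` (relative ecosystem-service value per unit area, following the
#' common Chinese equivalent-value pattern: water highest, forest high,
#' built-up zero). All are configurable; these defaults are package
#' conventions, not published constants.
#'
#' @param purpose one of `"interference"`, `"resilience"`, `"esv"`.
#' @return named numeric vector over the full land-use legend.
#' @export
coefficient_table <- function(purpose = c("interference", "resilience", "esv")) {
  purpose <- match.arg(purpose)
  switch(purpose,
    interference = c(farmland = 0.6, forestland = 0.1, shrubland = 0.2,
                     grassland_high = 0.2, grassland_mid = 0.25,
                     grassland_low = 0.3, water = 0.05, builtup = 1.0,
                     unused = 0.4),
    resilience = c(farmland = 0.4, forestland = 0.9, shrubland = 0.75,
                   grassland_high = 0.7, grassland_mid = 0.6,
                   grassland_low = 0.45, water = 0.8, builtup = 0.1,
                   unused = 0.2),
    esv = c(farmland = 0.25, forestland = 0.65, shrubland = 0.45,
            grassland_high = 0.40, grassland_mid = 0.30,
            grassland_low = 0.20, water = 1.0, builtup = 0.0,
            unused = 0.05)
  )
}

#' Rocky-desertification sensitivity rule
#'
#' Banded scoring rule for karst rocky-desertification susceptibility:
#' steeper slopes and sparser vegetation score higher, and the score only
#' applies where carbonate rock is present. `slope_breaks` /`cover_breaks`
#' are the interior band edges; scores are per band (low to high band).
#'
#' @param slope_breaks slope band edges in degrees.
#' @param slope_scores score per slope band (length `length(slope_breaks)+1`).
#' @param cover_breaks vegetation-coverage band edges in \[0,1\].
#' @param cover_scores score per coverage band (note: decreasing, sparse
#'   cover is more sensitive).
#' @return list of class `kh_rds_rule`.
#' @export
rds_rule <- function(slope_breaks = c(8, 15, 25),
                     slope_scores = c(1, 2, 3, 4),
                     cover_breaks = c(0.2, 0.5, 0.8),
                     cover_scores = c(4, 3, 2, 1)) {
  if (length(slope_scores) != length(slope_breaks) + 1 ||
      length(cover_scores) != length(cover_breaks) + 1)
    stop("need one score per band (length(breaks) + 1)")
  if (any(slope_scores < 0) || any(cover_scores < 0))
    stop("band scores must be >= 0")
  if (is.unsorted(slope_breaks, strictly = TRUE) ||
      is.unsorted(cover_breaks, strictly = TRUE))
    stop("band edges must be strictly increasing")
  structure(list(slope_breaks = slope_breaks, slope_scores = slope_scores,
                 cover_breaks = cover_breaks, cover_scores = cover_scores,
                 max_score = max(slope_scores) + max(cover_scores)),
            class = "kh_rds_rule")
}

band_score <- function(x, breaks, scores) {
  scores[findInterval(x, breaks, left.open = FALSE) + 1L]
}

#' Per-cell population density
#'
#' Zonal mean of the population-density raster (persons/km^2).
#'
#' @param pop continuous [kh_raster] of population density.
#' @param grid a [build_fishnet()] grid.
#' @param epoch year label.
#' @return indicator layer `pop_density`.
#' @export
pop_density <- function(pop, grid, epoch = NA) {
  zonal_mean(pop, grid, name = "pop_density", epoch = epoch)
}

#' Area-weighted composite of a per-class coefficient table
#'
#' Per cell, \eqn{\sum_c coeff(c) \cdot fraction(c)}: the shared
#' construction behind man-made interference (H), ecological resilience
#' (ERI) and ecosystem-service value (ESV).
#'
#' @param lu categorical [kh_raster].
#' @param grid a [build_fishnet()] grid.
#' @param coeff named coefficient vector covering the legend (see
#'   [coefficient_table()]).
#' @param name,epoch layer labels.
#' @return indicator layer.
#' @export
area_weighted_index <- function(lu, grid, coeff, name = "index", epoch = NA) {
  miss <- setdiff(names(lu$legend), names(coeff))
  if (length(miss) > 0)
    stop("no coefficient for class(es): ", paste(miss, collapse = ", "))
  pc <- pixel_cell_index(lu, grid)
  n <- nrow(grid)
  keep <- !is.na(pc$idx)
  tot <- tabulate(pc$idx[keep], nbins = n)
  code_coeff <- coeff[names(lu$legend)][match(pc$value[keep], lu$legend)]
  sums <- rep(0, n)
  agg <- tapply(code_coeff, pc$idx[keep], sum)
  sums[as.integer(names(agg))] <- agg
  value <- ifelse(tot > 0, sums / tot, NA_real_)
  indicator_layer(grid, value, name, epoch)
}

#' Land reclamation rate
#'
#' Fraction of each cell under farmland.
#'
#' @inheritParams area_weighted_index
#' @export
reclamation_rate <- function(lu, grid, epoch = NA) {
  zonal_fraction(lu, grid, "farmland", name = "reclamation_rate", epoch = epoch)
}

#' Proportion of steep-slope farmland
#'
#' Per cell, the fraction of pixels that are farmland on slopes steeper
#' than the threshold (downhill farming pressure, a karst-specific
#' stressor). The denominator is all valid pixels of the cell, so cells
#' without farmland score 0 rather than missing.
#'
#' @param lu categorical [kh_raster].
#' @param slope continuous slope raster in degrees, co-registered with `lu`.
#' @param grid a [build_fishnet()] grid.
#' @param threshold_deg slope threshold, default 25.
#' @param epoch year label.
#' @export
steep_farmland_ratio <- function(lu, slope, grid, threshold_deg = 25,
                                 epoch = NA) {
  stop_if_misregistered(lu, slope, "land-use and slope rasters")
  pc <- pixel_cell_index(lu, grid)
  n <- nrow(grid)
  keep <- !is.na(pc$idx)
  tot <- tabulate(pc$idx[keep], nbins = n)
  steep_farm <- keep & pc$value == lu$legend[["farmland"]] &
    as.vector(slope$values) > threshold_deg
  hit <- tabulate(pc$idx[steep_farm], nbins = n)
  value <- ifelse(tot > 0, hit / tot, NA_real_)
  indicator_layer(grid, value, "steep_farmland", epoch)
}

#' Vegetation coverage index
#'
#' Fraction of each cell under vegetated cover (forest, shrub, any
#' grassland). A land-cover proxy: no reflectance-based NDVI enters the
#' pipeline.
#'
#' @inheritParams area_weighted_index
#' @export
vegetation_coverage <- function(lu, grid, epoch = NA) {
  zonal_fraction(lu, grid,
                 c("forestland", "shrubland", "grassland_high",
                   "grassland_mid", "grassland_low"),
                 name = "vegetation_coverage", epoch = epoch)
}

#' Proportion of forest land
#'
#' Fraction of each cell under forest or shrub.
#'
#' @inheritParams area_weighted_index
#' @export
forest_proportion <- function(lu, grid, epoch = NA) {
  zonal_fraction(lu, grid, c("forestland", "shrubland"),
                 name = "forest_proportion", epoch = epoch)
}

#' Shannon diversity of class proportions
#'
#' \eqn{SHDI = -\sum_k p_k \ln p_k} over classes with \eqn{p_k > 0}.
#'
#' @param p class proportions (non-negative, summing to 1 over classes
#'   present).
#' @return scalar in \[0, ln m\].
#' @export
shdi <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(NA_real_)
  -sum(p * log(p))
}

#' Shannon evenness of class proportions
#'
#' \eqn{SHEI = SHDI / \ln m} with \eqn{m} the number of classes present;
#' defined 0 for a single class.
#'
#' @inheritParams shdi
#' @return scalar in \[0, 1\].
#' @export
shei <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(NA_real_)
  if (length(p) == 1) return(0)
  shdi(p) / log(length(p))
}

#' Contagion of a pixel block
#'
#' FRAGSTATS-style contagion (0, 100]: 100 for a single-class block,
#' decreasing as classes interleave. Adjacencies are 4-neighbour and
#' double-counted; \eqn{m} is the number of classes present in the block.
#' \deqn{CONTAG = 100 \left[1 + \frac{\sum_i \sum_k q_{ik} \ln q_{ik}}{2 \ln m}\right],
#'   \quad q_{ik} = P_i \frac{g_{ik}}{\sum_k g_{ik}}}
#'
#' @param block integer matrix of class codes (NA = no pixel).
#' @return scalar percent; 100 when only one class (or one pixel) is
#'   present, NA for an empty block.
#' @export
contag <- function(block) {
  codes <- block[!is.na(block)]
  if (length(codes) == 0) return(NA_real_)
  cls <- sort(unique(codes))
  m <- length(cls)
  if (m == 1) return(100)
  p_i <- as.vector(table(factor(codes, levels = cls))) / length(codes)
  g <- adjacency_counts(block, cls)
  rs <- rowSums(g)
  q <- (p_i * g / rs)
  terms <- q * log(q)
  terms[!is.finite(terms)] <- 0
  100 * (1 + sum(terms) / (2 * log(m)))
}

# 4-neighbour double-count adjacency tally g_ik within one block.
adjacency_counts <- function(block, cls) {
  m <- length(cls)
  g <- matrix(0, m, m, dimnames = list(cls, cls))
  idx <- function(v) match(v, cls)
  nr <- nrow(block); nc <- ncol(block)
  add_pairs <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return()
    t1 <- table(factor(idx(a[ok]), levels = seq_len(m)),
                factor(idx(b[ok]), levels = seq_len(m)))
    g <<- g + unclass(t1) + t(unclass(t1))   # double count: both directions
  }
  if (nc > 1) add_pairs(block[, -nc, drop = FALSE], block[, -1, drop = FALSE])
  if (nr > 1) add_pairs(block[-nr, , drop = FALSE], block[-1, , drop = FALSE])
  g
}

#' Per-cell landscape metrics
#'
#' SHDI, SHEI and contagion computed treating each grid cell's pixel block
#' as its own landscape.
#'
#' @param lu categorical [kh_raster].
#' @param grid a [build_fishnet()] grid.
#' @param epoch year label.
#' @return named list of three indicator layers: `shdi`, `shei`, `contag`.
#' @export
landscape_metrics <- function(lu, grid, epoch = NA) {
  blocks <- cell_pixel_blocks(lu, grid)
  vals <- vapply(blocks, function(b) {
    if (is.null(b)) return(c(NA_real_, NA_real_, NA_real_))
    codes <- b[!is.na(b)]
    p <- as.vector(table(codes)) / length(codes)
    c(shdi(p), shei(p), contag(b))
  }, numeric(3))
  list(shdi = indicator_layer(grid, vals[1, ], "shdi", epoch),
       shei = indicator_layer(grid, vals[2, ], "shei", epoch),
       contag = indicator_layer(grid, vals[3, ], "contag", epoch))
}

#' Rocky-desertification sensitivity
#'
#' Per cell: carbonate fraction times the banded slope + coverage score,
#' rescaled to \[0,1\] by the rule's maximum attainable score. Cells with no
#' carbonate score 0.
#'
#' @param slope continuous slope raster (degrees).
#' @param veg_layer vegetation-coverage indicator layer for the epoch.
#' @param carbonate_mask categorical 0/1 [kh_raster] of karst lithology.
#' @param grid a [build_fishnet()] grid.
#' @param rule an [rds_rule()].
#' @param epoch year label.
#' @export
rds_sensitivity <- function(slope, veg_layer, carbonate_mask, grid,
                            rule = rds_rule(), epoch = NA) {
  mean_slope <- zonal_mean(slope, grid)$value
  carb_frac <- zonal_mean(
    kh_raster(matrix(as.numeric(carbonate_mask$values),
                     nrow(carbonate_mask$values)),
              carbonate_mask$xmin, carbonate_mask$ymax,
              carbonate_mask$cell_size, carbonate_mask$crs, "continuous"),
    grid)$value
  s_score <- band_score(mean_slope, rule$slope_breaks, rule$slope_scores)
  c_score <- band_score(veg_layer$value, rule$cover_breaks, rule$cover_scores)
  value <- carb_frac * (s_score + c_score) / rule$max_score
  value[carb_frac == 0] <- 0
  indicator_layer(grid, value, "rds_sensitivity", epoch)
}
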