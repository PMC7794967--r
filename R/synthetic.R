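#' Parameters of a synthetic study scene
#'
#' Defines the stated world the generator draws from: a desk-scale karst
#' mining prefecture observed at 1 km resolution over six five-year epochs.
#' Defaults emulate the structure the downstream analysis assumes — a patchy
#' multi-class landscape, Markov land-use dynamics with urban expansion
#' around seeded centers and post-2000 farmland-to-forest/grassland
#' conversion, smooth terrain with a 500 m relief, population/GDP surfaces
#' decaying from urban centers and growing over time, mines clustered in
#' mining belts near the urban/industrial cores (the "coupled" layout that
#' ties high urbanization to low ecosystem health).
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in meters (default 48 x 48 km).
#' @param cell_size_m raster resolution, default 1000 m.
#' @param epochs ordered year labels, default `c(1990, 1995, 2000, 2005,
#'   2010, 2015)`.
#' @param n_urban_centers number of seeded urban cores (>= 1).
#' @param n_mines number of mine points (>= 0), default 66.
#' @param transition_regimes list of 9 x 9 row-stochastic matrices, one per
#'   epoch interval (rows/cols in [landuse_legend()] order); default
#'   [default_regimes()].
#' @param relief_amplitude_m DEM vertical range (m), default 500.
#' @param base_elevation_m elevation of the lowest terrain, default 1400 m.
#' @param carbonate_fraction fraction of the extent underlain by carbonate
#'   rock, default 0.6318.
#' @param urban_boost,urban_sigma_m multiplier (at the kernel center) on the
#'   regime's own conversion-to-built-up probability around urban centers,
#'   and the Gaussian length scale of that kernel. A regime with zero
#'   built-up gain is unaffected.
#' @param pop_growth,gdp_growth multiplicative per-epoch growth factors of
#'   the population and per-capita-GDP surfaces.
#' @param mining_belts list of `c(xmin, xmax, ymin, ymax)` rectangles mines
#'   are drawn from; `NULL` = two belts centered on the first two urban
#'   centers.
#' @param crs reference-system tag shared by all scene layers.
#' @param seed integer RNG seed; per-stage child seeds are derived from it.
#' @return list of class `kh_scene_params`.
#' @export
scene_params <- function(extent = c(0, 48000, 0, 48000),
                         cell_size_m = 1000,
                         epochs = c(1990, 1995, 2000, 2005, 2010, 2015),
                         n_urban_centers = 3,
                         n_mines = 66,
                         transition_regimes = NULL,
                         relief_amplitude_m = 500,
                         base_elevation_m = 1400,
                         carbonate_fraction = 0.6318,
                         urban_boost = 4,
                         urban_sigma_m = 5000,
                         pop_growth = 1.15,
                         gdp_growth = 1.25,
                         mining_belts = NULL,
                         crs = "local-m",
                         seed = 1L) {
  if (any(diff(epochs) <= 0)) stop("epochs must be strictly increasing")
  if (n_urban_centers < 1) stop("need at least one urban center")
  if (n_mines < 0) stop("n_mines must be >= 0")
  if (is.null(transition_regimes)) transition_regimes <- default_regimes(epochs)
  if (length(transition_regimes) != length(epochs) - 1)
    stop("need one transition regime per epoch interval")
  for (k in seq_along(transition_regimes))
    check_stochastic(transition_regimes[[k]], sprintf("interval %d", k))
  p <- list(extent = extent, cell_size_m = cell_size_m, epochs = epochs,
            n_urban_centers = n_urban_centers, n_mines = n_mines,
            transition_regimes = transition_regimes,
            relief_amplitude_m = relief_amplitude_m,
            base_elevation_m = base_elevation_m,
            carbonate_fraction = carbonate_fraction,
            urban_boost = urban_boost, urban_sigma_m = urban_sigma_m,
            pop_growth = pop_growth, gdp_growth = gdp_growth,
            mining_belts = mining_belts, crs = crs, seed = as.integer(seed))
  class(p) <- "kh_scene_params"
  p
}

#' Build scene parameters from a configuration file
#'
#' Reads a YAML or JSON file (see [read_config()]) whose top-level keys are
#' [scene_params()] arguments. Transition regimes, if present, are expected
#' as a list of row-major numeric matrices and are converted; omitted keys
#' take the package defaults.
#'
#' @param path configuration file path.
#' @return a [scene_params()] object.
#' @export
scene_params_from_config <- function(path) {
  cfg <- read_config(path)
  known <- names(formals(scene_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown scene parameter(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$transition_regimes)) {
    legend <- landuse_legend()
    cfg$transition_regimes <- lapply(cfg$transition_regimes, function(m) {
      m <- matrix(unlist(m), length(legend), length(legend), byrow = TRUE)
      dimnames(m) <- list(names(legend), names(legend))
      m
    })
  }
  if (!is.null(cfg$mining_belts) && !is.list(cfg$mining_belts))
    cfg$mining_belts <- apply(cfg$mining_belts, 1, identity, simplify = FALSE)
  do.call(scene_params, cfg)
}

check_stochastic <- function(m, label) {
  legend <- landuse_legend()
  if (!is.matrix(m) || nrow(m) != length(legend) || ncol(m) != length(legend))
    stop("transition matrix (", label, ") must be ",
         length(legend), " x ", length(legend))
  if (any(m < 0)) stop("transition matrix (", label, ") has negative entries")
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad) > 0)
    stop("transition matrix (", label, ") row ", bad[1], " (",
         names(legend)[bad[1]], ") sums to ", format(rs[bad[1]]),
         ", not 1")
  invisible(TRUE)
}

#' Default per-interval transition regimes
#'
#' Identity-dominated Markov matrices expressing the qualitative dynamics of
#' a rapidly urbanizing karst prefecture: steady conversion of farmland (and
#' some grassland) to built-up land throughout, an accelerated built-up gain
#' in the final interval, and — in post-2000 intervals — conversion of
#' farmland to forest and high-density grassland (the "grain-for-green"
#' regime). Water and built-up land are absorbing.
#'
#' @param epochs ordered year labels.
#' @return list of row-stochastic 9 x 9 matrices, one per interval, with
#'   dimnames from [landuse_legend()].
#' @export
default_regimes <- function(epochs) {
  legend <- landuse_legend()
  m <- length(legend)
  regimes <- vector("list", length(epochs) - 1)
  for (k in seq_len(length(epochs) - 1)) {
    tr <- matrix(0, m, m, dimnames = list(names(legend), names(legend)))
    diag(tr) <- 1
    post2000 <- epochs[k + 1] > 2000
    last <- k == length(epochs) - 1
    flow <- function(from, to, p) {
      tr[from, to] <<- tr[from, to] + p
      tr[from, from] <<- tr[from, from] - p
    }
    flow("farmland", "builtup", if (last) 0.020 else 0.010)
    flow("grassland_low", "farmland", 0.015)
    flow("grassland_mid", "farmland", 0.008)
    if (post2000) {
      flow("farmland", "forestland", 0.030)
      flow("farmland", "grassland_high", 0.015)
      flow("grassland_low", "grassland_mid", 0.010)
      flow("unused", "grassland_low", 0.010)
    } else {
      flow("forestland", "farmland", 0.006)
      flow("grassland_high", "farmland", 0.006)
    }
    regimes[[k]] <- tr
  }
  regimes
}

# Deterministic per-stage child seeds (kept well below 2^31).
child_seed <- function(params, stage) {
  (params$seed %% 1000000L) * 1000L + stage
}

# Urban-center coordinates, deterministic in the scene seed: drawn from the
# central 60% of the extent so kernels stay inside the scene.
scene_centers <- function(params) {
  ext <- params$extent
  with_seed(child_seed(params, 0L), {
    pad_x <- 0.2 * (ext[2] - ext[1]); pad_y <- 0.2 * (ext[4] - ext[3])
    data.frame(
      x = stats::runif(params$n_urban_centers, ext[1] + pad_x, ext[2] - pad_x),
      y = stats::runif(params$n_urban_centers, ext[3] + pad_y, ext[4] - pad_y)
    )
  })
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Bilinearly interpolated coarse Gaussian noise: the building block of the
# DEM and of the carbonate field.
smooth_noise <- function(nr, nc, n_coarse) {
  cz <- matrix(stats::rnorm((n_coarse + 1)^2), n_coarse + 1, n_coarse + 1)
  ri <- (seq_len(nr) - 0.5) / nr * n_coarse
  ci <- (seq_len(nc) - 0.5) / nc * n_coarse
  r0 <- pmin(floor(ri), n_coarse - 1); c0 <- pmin(floor(ci), n_coarse - 1)
  fr <- ri - r0; fc <- ci - c0
  a <- cz[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  b <- cz[cbind(rep(r0 + 1, nc), rep(c0 + 2, each = nr))]
  d <- cz[cbind(rep(r0 + 2, nc), rep(c0 + 1, each = nr))]
  e <- cz[cbind(rep(r0 + 2, nc), rep(c0 + 2, each = nr))]
  fr_m <- rep(fr, nc); fc_m <- rep(fc, each = nr)
  matrix((1 - fr_m) * (1 - fc_m) * a + (1 - fr_m) * fc_m * b +
           fr_m * (1 - fc_m) * d + fr_m * fc_m * e, nr, nc)
}

# 3x3 modal (majority) filter on a categorical matrix; ties keep the
# incumbent class. Gives the initial landscape its patchy structure.
majority_filter <- function(v, n_class, passes = 2) {
  nr <- nrow(v); nc <- ncol(v)
  for (p in seq_len(passes)) {
    counts <- array(0L, c(nr, nc, n_class))
    for (dr in -1:1) for (dc in -1:1) {
      rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
      cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      sh <- v[rs, cs, drop = FALSE]
      for (k in seq_len(n_class))
        counts[, , k] <- counts[, , k] + (sh == k)
    }
    best <- v; best_n <- counts[cbind(rep(seq_len(nr), nc),
                                      rep(seq_len(nc), each = nr), as.vector(v))]
    best_n <- matrix(best_n, nr, nc)
    for (k in seq_len(n_class)) {
      better <- counts[, , k] > best_n
      best[better] <- k
      best_n[better] <- counts[, , k][better]
    }
    v <- best
  }
  v
}

#' Generate the land-use raster series
#'
#' Epoch 0 is a spatially clustered mosaic built by assigning each pixel the
#' class of its nearest seeded nucleus and smoothing with a majority filter;
#' built-up nuclei sit on the urban centers. Each later epoch applies the
#' interval's Markov regime pixel-wise, with the conversion-to-built-up
#' probability boosted by a Gaussian distance kernel around urban centers.
#'
#' @param params a [scene_params()] object.
#' @return list of categorical [kh_raster], one per epoch, named by year.
#' @export
generate_landuse_series <- function(params) {
  legend <- landuse_legend()
  ext <- params$extent; s <- params$cell_size_m
  nc <- round((ext[2] - ext[1]) / s); nr <- round((ext[4] - ext[3]) / s)
  centers <- scene_centers(params)

  base <- with_seed(child_seed(params, 1L), {
    # class mix of the initial mosaic (fractions of nuclei)
    mix <- c(farmland = 0.30, forestland = 0.22, shrubland = 0.08,
             grassland_high = 0.10, grassland_mid = 0.10,
             grassland_low = 0.06, water = 0.03, builtup = 0.02,
             unused = 0.09)
    n_nuc <- max(80L, (nr * nc) %/% 30L)
    nx <- stats::runif(n_nuc, ext[1], ext[2])
    ny <- stats::runif(n_nuc, ext[3], ext[4])
    ncl <- sample(seq_along(legend), n_nuc, replace = TRUE, prob = mix)
    # the coupled layout: terrain around the urban/mining cores is the
    # disturbed agricultural basin (farmland, sparse grass, unused), so the
    # urbanization kernels overlap low-ecological-state land
    basin <- c(farmland = 0.55, forestland = 0, shrubland = 0.05,
               grassland_high = 0, grassland_mid = 0.10,
               grassland_low = 0.15, water = 0, builtup = 0.05,
               unused = 0.10)
    d2ctr <- vapply(seq_len(n_nuc), function(i)
      min((nx[i] - centers$x)^2 + (ny[i] - centers$y)^2), numeric(1))
    near <- d2ctr < (1.6 * params$urban_sigma_m)^2
    if (any(near))
      ncl[near] <- sample(seq_along(legend), sum(near), replace = TRUE,
                          prob = basin)
    # pin one built-up nucleus on each urban center
    nx <- c(nx, centers$x); ny <- c(ny, centers$y)
    ncl <- c(ncl, rep(legend[["builtup"]], nrow(centers)))
    px <- ext[1] + (rep(seq_len(nc), each = nr) - 0.5) * s
    py <- ext[4] - (rep(seq_len(nr), times = nc) - 0.5) * s
    nearest <- vapply(seq_along(px), function(i)
      which.min((nx - px[i])^2 + (ny - py[i])^2), integer(1))
    v <- matrix(ncl[nearest], nr, nc)
    majority_filter(v, length(legend), passes = 2)
  })

  # per-pixel kernel of proximity to urban centers
  px <- ext[1] + (rep(seq_len(nc), each = nr) - 0.5) * s
  py <- ext[4] - (rep(seq_len(nr), times = nc) - 0.5) * s
  kern <- rep(0, nr * nc)
  for (i in seq_len(nrow(centers)))
    kern <- pmax(kern, exp(-((px - centers$x[i])^2 + (py - centers$y[i])^2) /
                             (2 * params$urban_sigma_m^2)))

  series <- vector("list", length(params$epochs))
  names(series) <- params$epochs
  series[[1]] <- kh_raster(base, ext[1], ext[4], s, params$crs,
                           "categorical", legend)
  built <- legend[["builtup"]]
  cur <- base
  for (k in seq_len(length(params$epochs) - 1)) {
    tr <- params$transition_regimes[[k]]
    cur <- with_seed(child_seed(params, 10L + k), {
      p_mat <- tr[as.vector(cur), , drop = FALSE]      # n_pixel x 9
      # boost conversion to built-up near urban centers, keep rows stochastic
      bo <- params$urban_boost * kern
      not_built <- as.vector(cur) != built
      # multiplicative boost of the regime's own built-up gain: a regime
      # with zero built-up gain (e.g. identity) is left untouched
      extra <- pmin(p_mat[, built] * bo, 1 - p_mat[, built]) * not_built
      denom <- 1 - p_mat[, built]
      scale <- ifelse(denom > 0, (denom - extra) / denom, 1)
      keep_built <- p_mat[, built] + extra
      p_mat <- p_mat * scale
      p_mat[, built] <- keep_built
      cum <- p_mat %*% upper.tri(diag(ncol(p_mat)), diag = TRUE)
      cum[, ncol(cum)] <- 1
      u <- stats::runif(nrow(p_mat))
      nxt <- max.col(cum >= u, ties.method = "first")
      matrix(as.integer(nxt), nrow(cur), ncol(cur))
    })
    series[[k + 1]] <- kh_raster(cur, ext[1], ext[4], s, params$crs,
                                 "categorical", legend)
  }
  series
}

#' Generate terrain, socio-economic surfaces and the carbonate mask
#'
#' The DEM is multi-scale smooth noise rescaled to the configured relief;
#' population and per-capita-GDP surfaces are sums of Gaussian kernels on
#' the urban centers over a low background, multiplied by a per-epoch growth
#' factor; the carbonate mask thresholds an independent smooth field so that
#' the configured fraction of the extent is karst.
#'
#' @param landuse_series output of [generate_landuse_series()] (fixes the
#'   raster geometry).
#' @param params a [scene_params()] object.
#' @return list with elements `dem`, `pop_series`, `gdp_series`,
#'   `carbonate_mask`.
#' @export
generate_surfaces <- function(landuse_series, params) {
  ref <- landuse_series[[1]]
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  ext <- params$extent; s <- params$cell_size_m
  centers <- scene_centers(params)

  dem_v <- with_seed(child_seed(params, 2L), {
    f <- smooth_noise(nr, nc, 5) + 0.5 * smooth_noise(nr, nc, 11) +
      0.25 * smooth_noise(nr, nc, 23)
    rng <- range(f)
    if (rng[2] > rng[1]) f <- (f - rng[1]) / (rng[2] - rng[1]) else f[] <- 0
    params$base_elevation_m + params$relief_amplitude_m * f
  })
  dem <- kh_raster(dem_v, ext[1], ext[4], s, params$crs, "continuous")

  px <- ext[1] + (rep(seq_len(nc), each = nr) - 0.5) * s
  py <- ext[4] - (rep(seq_len(nr), times = nc) - 0.5) * s
  kernsum <- rep(0, nr * nc)
  for (i in seq_len(nrow(centers)))
    kernsum <- kernsum + exp(-((px - centers$x[i])^2 + (py - centers$y[i])^2) /
                               (2 * params$urban_sigma_m^2))
  kernsum <- matrix(kernsum, nr, nc)

  n_ep <- length(params$epochs)
  pop_series <- gdp_series <- vector("list", n_ep)
  names(pop_series) <- names(gdp_series) <- params$epochs
  for (e in seq_len(n_ep)) {
    popv <- (50 + 2000 * kernsum) * params$pop_growth^(e - 1)
    gdpv <- (2000 + 15000 * kernsum) * params$gdp_growth^(e - 1)
    pop_series[[e]] <- kh_raster(popv, ext[1], ext[4], s, params$crs, "continuous")
    gdp_series[[e]] <- kh_raster(gdpv, ext[1], ext[4], s, params$crs, "continuous")
  }

  carb_v <- with_seed(child_seed(params, 3L), {
    f <- smooth_noise(nr, nc, 7) + 0.5 * smooth_noise(nr, nc, 15)
    thr <- stats::quantile(f, 1 - params$carbonate_fraction)
    matrix(as.integer(f >= thr), nr, nc)
  })
  carbonate <- kh_raster(carb_v, ext[1], ext[4], s, params$crs,
                         "categorical", legend = c(non_karst = 0L, karst = 1L),
                         nodata = -1L)

  list(dem = dem, pop_series = pop_series, gdp_series = gdp_series,
       carbonate_mask = carbonate)
}

#' Generate mine points inside mining belts
#'
#' Mines are sampled uniformly within the configured belt rectangles
#' (probability proportional to belt area). The default belts sit on the
#' first urban centers, which couples mining pressure to the urbanized,
#' ecologically stressed part of the scene.
#'
#' @param landuse_series output of [generate_landuse_series()].
#' @param params a [scene_params()] object.
#' @return data.frame with columns `mine_id`, `x`, `y`.
#' @export
generate_mines <- function(landuse_series, params) {
  ext <- params$extent
  belts <- params$mining_belts
  if (is.null(belts)) {
    centers <- scene_centers(params)
    half <- 6000
    belts <- lapply(seq_len(min(2, nrow(centers))), function(i) {
      c(max(ext[1], centers$x[i] - half), min(ext[2], centers$x[i] + half),
        max(ext[3], centers$y[i] - half), min(ext[4], centers$y[i] + half))
    })
  }
  for (b in belts) {
    if (b[1] < ext[1] - 1e-9 || b[2] > ext[2] + 1e-9 ||
        b[3] < ext[3] - 1e-9 || b[4] > ext[4] + 1e-9)
      stop("mining belt extends outside the scene extent")
    if (b[2] <= b[1] || b[4] <= b[3]) stop("degenerate mining belt")
  }
  if (params$n_mines == 0)
    return(data.frame(mine_id = integer(0), x = numeric(0), y = numeric(0)))
  with_seed(child_seed(params, 4L), {
    areas <- vapply(belts, function(b) (b[2] - b[1]) * (b[4] - b[3]), numeric(1))
    which_belt <- sample(seq_along(belts), params$n_mines, replace = TRUE,
                         prob = areas)
    x <- y <- numeric(params$n_mines)
    for (i in seq_len(params$n_mines)) {
      b <- belts[[which_belt[i]]]
      x[i] <- stats::runif(1, b[1], b[2])
      y[i] <- stats::runif(1, b[3], b[4])
    }
    data.frame(mine_id = seq_len(params$n_mines), x = x, y = y)
  })
}

#' Generate a complete synthetic scene
#'
#' Runs the land-use, surface and mine generators with deterministically
#' derived child seeds and bundles the result.
#'
#' @param params a [scene_params()] object.
#' @return list of class `kh_scene`: `landuse_series`, `dem`, `pop_series`,
#'   `gdp_series`, `carbonate_mask`, `mines`, `urban_centers`, `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  lu <- generate_landuse_series(params)
  sf <- generate_surfaces(lu, params)
  mines <- generate_mines(lu, params)
  structure(
    list(landuse_series = lu, dem = sf$dem, pop_series = sf$pop_series,
         gdp_series = sf$gdp_series, carbonate_mask = sf$carbonate_mask,
         mines = mines, urban_centers = scene_centers(params),
         params = params),
    class = "kh_scene"
  )
}

#' Write a scene to disk as plain-text GIS files
#'
#' Land-use, DEM, POP/GDP and carbonate rasters as ESRI ASCII grids; mines
#' and urban centers as GeoJSON points.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if absent).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ep in names(scene$landuse_series))
    write_ascii_grid(scene$landuse_series[[ep]],
                     file.path(dir, paste0("landuse_", ep, ".asc")))
  write_ascii_grid(scene$dem, file.path(dir, "dem.asc"))
  for (ep in names(scene$pop_series)) {
    write_ascii_grid(scene$pop_series[[ep]],
                     file.path(dir, paste0("pop_", ep, ".asc")))
    write_ascii_grid(scene$gdp_series[[ep]],
                     file.path(dir, paste0("gdp_", ep, ".asc")))
  }
  write_ascii_grid(scene$carbonate_mask, file.path(dir, "carbonate.asc"))
  write_points_geojson(scene$mines, file.path(dir, "mines.geojson"),
                       crs_name = scene$params$crs)
  invisible(dir)
}
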