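# Shared fixtures and independent oracles. Oracles deliberately use the
# dumbest correct method (exhaustive enumeration, dense algebra) and never
# call the code paths they check.

make_lu <- function(m, cell = 1000, crs = "local-m") {
  kh_raster(m, xmin = 0, ymax = nrow(m) * cell, cell_size = cell, crs = crs,
            type = "categorical")
}

make_cont <- function(m, cell = 1000, crs = "local-m") {
  kh_raster(m, xmin = 0, ymax = nrow(m) * cell, cell_size = cell, crs = crs,
            type = "continuous")
}

# a small scene shared by the slower tests (16 x 16 km at 1 km)
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_scene(scene_params(
        extent = c(0, 16000, 0, 16000), n_urban_centers = 1, n_mines = 8,
        seed = 42))
    cache
  }
})

# brute-force per-cell pixel statistics by looping over every pixel
bf_zonal <- function(raster, grid, stat, class_codes = NULL) {
  px <- raster_pixels(raster)
  valid <- as.vector(raster_valid(raster))
  n <- nrow(grid)
  out <- rep(NA_real_, n)
  for (ci in seq_len(n)) {
    g <- grid[ci, ]
    inside <- px$x >= g$xmin & px$x < g$xmax & px$y > g$ymin & px$y <= g$ymax
    sel <- inside & valid
    if (!any(sel)) next
    out[ci] <- if (stat == "mean") mean(px$value[sel])
    else sum(px$value[sel] %in% class_codes) / sum(sel)
  }
  out
}

# dense-matrix oracle for bivariate Moran's I
bf_bivariate_moran <- function(x, y, W) {
  n <- length(x)
  zs <- function(v) (v - mean(v)) / (stats::sd(v) * sqrt((n - 1) / n))
  wm <- weights_matrix(W)
  as.numeric(t(zs(x)) %*% wm %*% zs(y)) / n
}

# exhaustive Fisher-Jenks oracle: best contiguous partition of sorted
# values into k groups by enumerating every break placement
bf_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; best_breaks <- NULL
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- 0
    for (g in seq_len(k)) tot <- tot + ssd(x[(b[g] + 1):b[g + 1]])
    if (tot < best - 1e-12) {
      best <- tot
      best_breaks <- x[cuts[, j]]
    }
  }
  list(ssd = best, breaks = best_breaks)
}

bf_jenks_ssd_of_breaks <- function(values, breaks) {
  cls <- findInterval(values, breaks, left.open = TRUE) + 1
  sum(tapply(values, cls, function(v) sum((v - mean(v))^2)))
}

# contagion oracle: tallies directed 4-neighbour adjacencies pair by pair,
# then evaluates the published formula term by term
bf_contag <- function(block) {
  codes <- block[!is.na(block)]
  cls <- sort(unique(codes))
  m <- length(cls)
  if (m == 1) return(100)
  nr <- nrow(block); nc <- ncol(block)
  g <- matrix(0, m, m)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(block[r, c])) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || is.na(block[rr, cc])) next
      g[match(block[r, c], cls), match(block[rr, cc], cls)] <-
        g[match(block[r, c], cls), match(block[rr, cc], cls)] + 1
    }
  }
  p <- as.vector(table(factor(codes, levels = cls))) / length(codes)
  acc <- 0
  for (i in seq_len(m)) for (k in seq_len(m)) {
    if (g[i, k] == 0) next
    q <- p[i] * g[i, k] / sum(g[i, ])
    acc <- acc + q * log(q)
  }
  100 * (1 + acc / (2 * log(m)))
}
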