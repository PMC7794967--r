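tiny_params <- function(...) {
  args <- utils::modifyList(
    list(extent = c(0, 12000, 0, 12000), n_urban_centers = 1,
         n_mines = 5, seed = 11),
    list(...))
  do.call(scene_params, args)
}

test_that("identity regimes freeze the landscape; absorbing rows empty a class", {
  legend <- landuse_legend()
  ident <- diag(length(legend))
  dimnames(ident) <- list(names(legend), names(legend))
  p <- tiny_params(transition_regimes = rep(list(ident), 5))
  lu <- generate_landuse_series(p)
  for (k in 2:length(lu))
    expect_identical(lu[[k]]$values, lu[[1]]$values)

  # farmland -> forest with probability 1 wipes farmland out in one step
  absorb <- ident
  absorb["farmland", ] <- 0
  absorb["farmland", "forestland"] <- 1
  p2 <- tiny_params(transition_regimes = rep(list(absorb), 5))
  lu2 <- generate_landuse_series(p2)
  expect_gt(sum(lu2[[1]]$values == legend[["farmland"]]), 0)
  expect_equal(sum(lu2[[2]]$values == legend[["farmland"]]), 0)
})

test_that("a non-stochastic regime is rejected naming the offending row", {
  legend <- landuse_legend()
  bad <- diag(length(legend))
  dimnames(bad) <- list(names(legend), names(legend))
  bad["water", "water"] <- 0.5
  expect_error(tiny_params(transition_regimes = rep(list(bad), 5)),
               "water")
})

test_that("default regimes grow built-up land monotonically", {
  lu <- generate_landuse_series(scene_params(seed = 3))
  built <- vapply(lu, function(r) sum(r$values == landuse_legend()[["builtup"]]),
                  numeric(1))
  expect_true(all(diff(built) >= 0))
  expect_gt(built[length(built)], built[1])
})

test_that("consecutive epochs satisfy the realized flow balance", {
  lu <- small_scene()$landuse_series
  legend <- landuse_legend()
  for (k in seq_len(length(lu) - 1)) {
    tm <- transition_matrix(lu[[k]], lu[[k + 1]])
    px <- tm$pixel_area_km2
    a1 <- vapply(legend, function(cd) sum(lu[[k]]$values == cd) * px, numeric(1))
    a2 <- vapply(legend, function(cd) sum(lu[[k + 1]]$values == cd) * px, numeric(1))
    expect_equal(unname(rowSums(tm$area)), unname(a1))
    expect_equal(unname(colSums(tm$area)), unname(a2))
  }
})

test_that("scene regeneration with the same seed is bit-identical", {
  p <- tiny_params()
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1$landuse_series, s2$landuse_series)
  expect_identical(s1$dem$values, s2$dem$values)
  expect_identical(s1$pop_series, s2$pop_series)
  expect_identical(s1$mines, s2$mines)
  expect_identical(s1$carbonate_mask$values, s2$carbonate_mask$values)
})

test_that("surfaces have the stated structure", {
  sc <- small_scene()
  p <- sc$params

  # flat world: zero relief gives identically zero slope
  p0 <- scene_params(extent = c(0, 8000, 0, 8000), relief_amplitude_m = 0,
                     n_urban_centers = 1, seed = 5)
  s0 <- generate_surfaces(generate_landuse_series(p0), p0)
  expect_true(all(slope_deg(s0$dem)$values == 0))

  # single kernel: POP maximum at the pixel containing the urban center
  sf <- generate_surfaces(sc$landuse_series, p)
  ctr <- scene_centers(p)
  pop <- sf$pop_series[[1]]
  px <- raster_pixels(pop)
  top <- px[which.max(px$value), ]
  expect_lte(abs(top$x - ctr$x[1]), p$cell_size_m / 2)
  expect_lte(abs(top$y - ctr$y[1]), p$cell_size_m / 2)

  # scene-total POP strictly increases epoch over epoch
  totals <- vapply(sf$pop_series, function(r) sum(r$values), numeric(1))
  expect_true(all(diff(totals) > 0))

  # carbonate mask covers the configured fraction (quantile-exact to 1/n)
  frac <- mean(sf$carbonate_mask$values)
  expect_lt(abs(frac - p$carbonate_fraction), 0.01)

  # registration: every raster shares the land-use grid
  lu1 <- sc$landuse_series[[1]]
  for (r in c(list(sf$dem, sf$carbonate_mask), sf$pop_series, sf$gdp_series)) {
    expect_equal(dim(r$values), dim(lu1$values))
    expect_equal(c(r$xmin, r$ymax, r$cell_size), c(lu1$xmin, lu1$ymax, lu1$cell_size))
  }
})

test_that("mines land inside their belts and the extent", {
  p <- tiny_params(n_mines = 0)
  expect_equal(nrow(generate_mines(generate_landuse_series(p), p)), 0)

  p66 <- scene_params(seed = 2)   # default belts, 66 mines
  lu <- generate_landuse_series(p66)
  mines <- generate_mines(lu, p66)
  expect_equal(nrow(mines), 66)
  ext <- p66$extent
  expect_true(all(mines$x >= ext[1] & mines$x <= ext[2] &
                    mines$y >= ext[3] & mines$y <= ext[4]))

  belts <- list(c(0, 3000, 0, 3000), c(9000, 12000, 9000, 12000))
  pb <- tiny_params(n_mines = 10, mining_belts = belts)
  mb <- generate_mines(generate_landuse_series(pb), pb)
  in_belt <- function(b, x, y) x >= b[1] & x <= b[2] & y >= b[3] & y <= b[4]
  expect_true(all(in_belt(belts[[1]], mb$x, mb$y) |
                    in_belt(belts[[2]], mb$x, mb$y)))

  expect_error(generate_mines(lu, tiny_params(
    mining_belts = list(c(-5000, 1000, 0, 1000)))), "belt")
})

test_that("epoch labels must increase and parameters validate", {
  expect_error(scene_params(epochs = c(1990, 1990, 2000)), "increasing")
  expect_error(scene_params(n_urban_centers = 0), "urban center")
  expect_error(scene_params(n_mines = -1))
})
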