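one_cell_grid <- function(km = 2) build_fishnet(c(0, km * 1000, 0, km * 1000), km * 1000)

test_that("area_weighted_index is the coefficient-weighted class mix", {
  g <- one_cell_grid()
  co <- coefficient_table("interference")
  expect_equal(area_weighted_index(make_lu(matrix(8L, 2, 2)), g, co)$value, 1.0)

  # 50% forest (0.2) + 50% farmland (0.6) under a custom table -> 0.4
  co2 <- co; co2[["forestland"]] <- 0.2; co2[["farmland"]] <- 0.6
  mix <- make_lu(matrix(c(2L, 2L, 1L, 1L), 2, 2))
  expect_equal(area_weighted_index(mix, g, co2)$value, 0.4)

  zero <- co * 0
  expect_equal(area_weighted_index(mix, g, zero)$value, 0)

  expect_error(area_weighted_index(mix, g, co[-2]), "forestland")
})

test_that("area_weighted_index is linear in the coefficient table", {
  set.seed(41)
  lu <- make_lu(matrix(sample(1:9, 64, replace = TRUE), 8, 8))
  g <- build_fishnet(c(0, 8000, 0, 8000), 4000)
  c1 <- coefficient_table("interference")
  c2 <- coefficient_table("esv")
  a <- 0.3; b <- 1.7
  lhs <- area_weighted_index(lu, g, a * c1 + b * c2)$value
  rhs <- a * area_weighted_index(lu, g, c1)$value +
    b * area_weighted_index(lu, g, c2)$value
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("steep farmland ratio counts farmland pixels above threshold", {
  g <- one_cell_grid()
  lu <- make_lu(matrix(1L, 2, 2))
  flat <- make_cont(matrix(0, 2, 2))
  expect_equal(steep_farmland_ratio(lu, flat, g)$value, 0)

  one_steep <- make_cont(matrix(c(30, 5, 10, 2), 2, 2))
  expect_equal(steep_farmland_ratio(lu, one_steep, g)$value, 0.25)

  # steep pixels but no farmland -> 0
  forest <- make_lu(matrix(2L, 2, 2))
  expect_equal(steep_farmland_ratio(forest, one_steep, g)$value, 0)

  expect_error(steep_farmland_ratio(lu, make_cont(matrix(0, 3, 3)), g),
               "registration")
})

test_that("vegetation coverage and forest proportion are class fractions", {
  g <- one_cell_grid()
  expect_equal(vegetation_coverage(make_lu(matrix(2L, 2, 2)), g)$value, 1.0)
  expect_equal(vegetation_coverage(make_lu(matrix(8L, 2, 2)), g)$value, 0.0)

  set.seed(42)
  m <- matrix(sample(1:9, 16, replace = TRUE), 4, 4)
  g4 <- build_fishnet(c(0, 4000, 0, 4000), 4000)
  expect_equal(vegetation_coverage(make_lu(m), g4)$value, mean(m %in% 2:6))
  expect_equal(forest_proportion(make_lu(m), g4)$value, mean(m %in% 2:3))
})

test_that("Shannon diversity and evenness match closed forms", {
  expect_equal(shdi(1), 0)
  expect_equal(shdi(c(0.5, 0.5)), log(2))
  expect_equal(shdi(c(0.5, 0.25, 0.25)), 1.5 * log(2))

  expect_equal(shei(rep(1 / 7, 7)), 1.0)
  expect_equal(shei(1), 0)
  expect_equal(shei(c(0.9, 0.1)),
               (-0.9 * log(0.9) - 0.1 * log(0.1)) / log(2))
})

test_that("SHDI is maximized at equal proportions", {
  set.seed(43)
  for (m in c(2, 4, 7)) {
    h_eq <- shdi(rep(1 / m, m))
    for (rep in 1:50) {
      p <- rexp(m); p <- p / sum(p)
      expect_lte(shdi(p), h_eq + 1e-12)
    }
    expect_equal(h_eq, log(m))
  }
})

test_that("contagion matches the brute-force adjacency oracle", {
  expect_equal(contag(matrix(3L, 4, 4)), 100)
  expect_equal(contag(matrix(5L, 1, 1)), 100)

  cb <- outer(1:4, 1:4, function(i, j) ifelse((i + j) %% 2 == 0, 1L, 2L))
  expect_equal(contag(cb), bf_contag(cb), tolerance = 1e-12)

  # aggregation raises contagion relative to a random interspersion of the
  # same 50/50 composition (contagion is 0 at random adjacency, not at the
  # checkerboard, which concentrates all adjacency in one class pair)
  halves <- rbind(matrix(1L, 4, 8), matrix(2L, 4, 8))
  expect_equal(contag(halves), bf_contag(halves), tolerance = 1e-12)
  set.seed(45)
  scramble <- matrix(sample(as.vector(halves)), 8, 8)
  expect_gt(contag(halves), contag(scramble))

  set.seed(44)
  for (rep in 1:20) {
    b <- matrix(sample(1:4, 30, replace = TRUE), 5, 6)
    expect_equal(contag(b), bf_contag(b), tolerance = 1e-12)
  }
})

test_that("rocky desertification sensitivity follows the banded rule", {
  g <- one_cell_grid()
  rule <- rds_rule()
  veg0 <- indicator_layer(g, 0.1)
  carb_full <- kh_raster(matrix(1L, 2, 2), 0, 2000, 1000,
                         type = "categorical",
                         legend = c(non_karst = 0L, karst = 1L), nodata = -1L)
  carb_none <- kh_raster(matrix(0L, 2, 2), 0, 2000, 1000,
                         type = "categorical",
                         legend = c(non_karst = 0L, karst = 1L), nodata = -1L)
  steep <- make_cont(matrix(30, 2, 2))

  expect_equal(rds_sensitivity(steep, veg0, carb_none, g, rule)$value, 0)
  # full carbonate, steepest band (score 4), sparsest cover band (score 4)
  expect_equal(rds_sensitivity(steep, veg0, carb_full, g, rule)$value, 1.0)
  # mid bands: slope 10 deg -> score 2; coverage 0.6 -> score 2; (2+2)/8
  mid <- make_cont(matrix(10, 2, 2))
  veg6 <- indicator_layer(g, 0.6)
  expect_equal(rds_sensitivity(mid, veg6, carb_full, g, rule)$value, 0.5)

  expect_error(rds_rule(slope_scores = c(1, 2)), "score per band")
  expect_error(rds_rule(cover_scores = c(4, 3, 2, -1)), ">= 0")
})

test_that("indicator ranges hold on a generated scene", {
  sc <- small_scene()
  g <- build_fishnet(sc$params$extent, 2000)
  ind <- compute_indicators(sc, g)
  frac <- ind$value[ind$indicator %in%
                      c("reclamation_rate", "steep_farmland",
                        "vegetation_coverage", "forest_proportion",
                        "rds_sensitivity", "shei")]
  expect_true(all(frac >= 0 & frac <= 1, na.rm = TRUE))
  sh <- ind$value[ind$indicator == "shdi"]
  expect_true(all(sh >= 0 & sh <= log(9), na.rm = TRUE))
  # contagion attains 0 exactly at maximal interspersion (uniform q)
  ct <- ind$value[ind$indicator == "contag"]
  expect_true(all(ct >= 0 & ct <= 100, na.rm = TRUE))
  expect_equal(sort(unique(ind$indicator)), sort(weight_scheme()$indicator))
})
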