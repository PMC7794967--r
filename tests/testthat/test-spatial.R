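grid3 <- build_fishnet(c(0, 6000, 0, 6000), 2000)    # 3 x 3 cells

test_that("queen weights have the expected neighbourhood structure", {
  W <- build_weights(grid3, "queen")
  # center cell (id 4) has all 8 neighbours at weight 1/8
  expect_equal(sort(W$nb[[5]]), c(1, 2, 3, 4, 6, 7, 8, 9))
  expect_equal(W$w[[5]], rep(1 / 8, 8))
  # corner cell has 3
  expect_length(W$nb[[1]], 3)

  # rook drops the diagonals
  Wr <- build_weights(grid3, "rook")
  expect_equal(sort(Wr$nb[[5]]), c(2, 4, 6, 8))
  expect_length(Wr$nb[[1]], 2)

  # binary adjacency is symmetric
  Wb <- build_weights(grid3, "queen", row_standardize = FALSE)
  m <- weights_matrix(Wb)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))

  # row-standardized rows sum to 1
  expect_equal(rowSums(weights_matrix(W)), rep(1, 9))

  # excluded (missing) cells are dropped before neighbours are found:
  # with the center removed, corners keep 2 of 3 neighbours, edges 4 of 5
  Wx <- build_weights(grid3, "queen", include = c(0:3, 5:8))
  expect_length(Wx$ids, 8)
  expect_false(4 %in% unlist(lapply(Wx$nb, function(j) Wx$ids[j])))
  expect_equal(lengths(Wx$nb)[Wx$ids == 0], 2L)
  expect_equal(lengths(Wx$nb)[Wx$ids == 1], 4L)
})

test_that("bivariate Moran's I matches the dense-matrix oracle", {
  set.seed(71)
  g5 <- build_fishnet(c(0, 5000, 0, 5000), 1000)
  W <- build_weights(g5, "queen")
  for (rep in 1:20) {
    x <- rnorm(25); y <- rnorm(25)
    expect_equal(bivariate_moran(x, y, W), bf_bivariate_moran(x, y, W),
                 tolerance = 1e-12)
  }

  # y = x reduces to univariate Moran's I; y = -x flips the sign
  x <- rnorm(25)
  expect_equal(bivariate_moran(x, x, W), bf_bivariate_moran(x, x, W))
  expect_equal(bivariate_moran(x, -x, W), -bivariate_moran(x, x, W),
               tolerance = 1e-12)

  # affine invariance under positive rescaling of either variable
  y <- rnorm(25)
  expect_equal(bivariate_moran(2.5 * x + 3, y, W), bivariate_moran(x, y, W),
               tolerance = 1e-10)
  expect_equal(bivariate_moran(x, 0.1 * y - 7, W), bivariate_moran(x, y, W),
               tolerance = 1e-10)

  expect_error(bivariate_moran(rep(1, 25), y, W), "variance")
})

test_that("permutation test p-values follow the rank arithmetic", {
  # strong positive spatial structure: observed I beats every permutation
  g <- build_fishnet(c(0, 10000, 0, 10000), 1000)
  W <- build_weights(g, "queen")
  x <- rep(seq_len(10), each = 10) + 0.01 * seq_len(100)  # smooth gradient
  mt <- moran_permutation_test(x, x, W, n_perm = 999, seed = 9)
  expect_equal(mt$pseudo_p, 0.001)
  expect_gt(mt$z_value, 3)

  # p recomputed from the returned permutation distribution
  set.seed(72)
  y <- rnorm(100)
  mt2 <- moran_permutation_test(x, y, W, n_perm = 199, seed = 10)
  m <- if (mt2$I_obs >= 0) sum(mt2$perm >= mt2$I_obs) else sum(mt2$perm <= mt2$I_obs)
  expect_equal(mt2$pseudo_p, (m + 1) / 200)
  expect_equal(mt2$p_two_sided, min(1, 2 * mt2$pseudo_p))
  expect_gte(mt2$pseudo_p, 1 / 200)
  expect_lte(mt2$pseudo_p, 1)

  # determinism per seed
  mt3 <- moran_permutation_test(x, y, W, n_perm = 199, seed = 10)
  expect_identical(mt2$perm, mt3$perm)

  # all-zero weights: every statistic 0, p = 1
  W0 <- structure(list(ids = 0:3, nb = rep(list(integer(0)), 4),
                       w = rep(list(numeric(0)), 4), scheme = "queen",
                       row_standardized = TRUE), class = "kh_weights_sp")
  z <- c(0.3, -1, 2, 0.1)
  expect_equal(bivariate_moran(z, z, W0), 0)
  mt0 <- moran_permutation_test(z, rnorm(4), W0, n_perm = 99, seed = 1)
  expect_equal(mt0$I_obs, 0)
  expect_true(all(mt0$perm == 0))
  expect_equal(mt0$pseudo_p, 1)

  expect_error(moran_permutation_test(x, y, W, n_perm = 0), "n_perm")
})

test_that("local Moran decomposes the global statistic and classifies quadrants", {
  set.seed(73)
  g <- build_fishnet(c(0, 7000, 0, 7000), 1000)
  W <- build_weights(g, "queen")
  x <- rnorm(49); y <- rnorm(49)
  ls <- bivariate_lisa(x, y, W, n_perm = 99, seed = 4)
  expect_equal(mean(ls$I_local), bivariate_moran(x, y, W), tolerance = 1e-12)

  # quadrant labels agree with the signs of z_x and the lag of z_y
  zx <- (x - mean(x)) / (sd(x) * sqrt(48 / 49))
  zy <- (y - mean(y)) / (sd(y) * sqrt(48 / 49))
  lag <- weights_matrix(W) %*% zy
  sig <- ls$cluster != "not significant"
  lab <- ifelse(zx >= 0, ifelse(lag >= 0, "High-High", "High-Low"),
                ifelse(lag >= 0, "Low-High", "Low-Low"))
  expect_equal(as.character(ls$cluster[sig]), lab[sig])

  # alpha = 0 is unreachable: everything not significant
  ls0 <- bivariate_lisa(x, y, W, n_perm = 99, alpha = 0, seed = 4)
  expect_true(all(ls0$cluster == "not significant"))

  # p floor respected
  expect_true(all(ls$pseudo_p >= 1 / 100 & ls$pseudo_p <= 1))
})
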