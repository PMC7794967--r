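test_that("min-max normalization matches the positive/negative formulas", {
  pool <- c(2, 4, 10)
  expect_equal(normalize_minmax(pool, "positive"), c(0, 0.25, 1))
  expect_equal(normalize_minmax(pool, "negative"), 1 - c(0, 0.25, 1))
  expect_equal(normalize_minmax(c(2, 6, 10), "positive")[2], 0.5)  # midpoint
  expect_equal(normalize_minmax(c(2, 6, 10), "negative")[2], 0.5)

  expect_warning(q <- normalize_minmax(c(3, 3, 3), "positive"), "constant")
  expect_equal(q, c(0.5, 0.5, 0.5))

  # missing propagates, and is excluded from the min/max pool
  v <- c(1, NA, 3)
  expect_equal(normalize_minmax(v, "positive"), c(0, NA, 1))
})

test_that("the default weight scheme conserves mass across layers", {
  w <- weight_scheme()
  expect_equal(sum(w$weight), 1.0)
  expect_equal(sum(w$weight[w$layer == "pressure"]), 0.42)
  expect_equal(sum(w$weight[w$layer == "state"]), 0.43)
  expect_equal(sum(w$weight[w$layer == "response"]), 0.15)
  expect_equal(nrow(w), 12)

  bad <- w; bad$weight[1] <- bad$weight[1] + 0.01
  expect_error(weight_scheme(bad), "sum to 1")
})

test_that("layer subscores are weighted sums over the layer's indicators", {
  w <- weight_scheme()
  q1 <- as.data.frame(setNames(as.list(c(0, rep(1, 12))),
                               c("cell_id", w$indicator)))
  expect_equal(layer_subscore(q1, w, "pressure"), 0.42)
  expect_equal(layer_subscore(q1, w, "state"), 0.43)
  expect_equal(layer_subscore(q1, w, "response"), 0.15)

  q0 <- q1; q0[w$indicator] <- 0
  expect_equal(layer_subscore(q0, w, "state"), 0)

  # single-indicator layer: W = 0.1, Q = 0.5 -> 0.05
  w1 <- weight_scheme(data.frame(
    indicator = c("a", "b"), layer = c("pressure", "state"),
    direction = c("negative", "positive"), weight = c(0.1, 0.9)))
  qq <- data.frame(cell_id = 0, a = 0.5, b = 0.2)
  expect_equal(layer_subscore(qq, w1, "pressure"), 0.05)

  expect_error(layer_subscore(q1[, 1:5], w, "state"), "missing indicator")
})

test_that("ESH is the sum of the three layer subscores", {
  expect_equal(esh_combine(0.321, 0.240, 0.071), 0.632)
  expect_equal(esh_combine(0, 0, 0), 0)
  w <- weight_scheme()
  q1 <- as.data.frame(setNames(as.list(c(0, rep(1, 12))),
                               c("cell_id", w$indicator)))
  expect_equal(esh_combine(layer_subscore(q1, w, "pressure"),
                           layer_subscore(q1, w, "state"),
                           layer_subscore(q1, w, "response")), 1.0)
})

test_that("compute_esh keeps ESH in [0,1], additive and monotone", {
  set.seed(51)
  w <- weight_scheme()
  n_cell <- 30
  ind <- expand.grid(cell_id = 0:(n_cell - 1), epoch = c(1990, 2000),
                     indicator = w$indicator, stringsAsFactors = FALSE)
  ind$value <- runif(nrow(ind), 0, 10)
  tab <- compute_esh(ind, w)
  expect_true(all(tab$ESH >= -1e-12 & tab$ESH <= 1 + 1e-12))
  expect_equal(tab$ESH, tab$P + tab$S + tab$R, tolerance = 1e-12)

  # raising a positive indicator's raw value never lowers ESH
  ind2 <- ind
  sel <- ind2$indicator == "esv" & ind2$cell_id == 3 & ind2$epoch == 1990
  ind2$value[sel] <- ind2$value[sel] + 100
  tab2 <- compute_esh(ind2, w)
  target <- tab2$cell_id == 3 & tab2$epoch == 1990
  expect_gte(tab2$ESH[target], tab$ESH[tab$cell_id == 3 & tab$epoch == 1990] - 1e-12)

  # a monotone transform of one indicator leaves ESH within bounds
  ind3 <- ind
  sel3 <- ind3$indicator == "pop_density"
  ind3$value[sel3] <- exp(ind3$value[sel3] / 5)
  tab3 <- compute_esh(ind3, w)
  expect_true(all(tab3$ESH >= -1e-12 & tab3$ESH <= 1 + 1e-12))
})

test_that("pooled normalization makes epochs comparable", {
  w <- weight_scheme()
  ind <- expand.grid(cell_id = 0:4, epoch = c(1990, 1995),
                     indicator = w$indicator, stringsAsFactors = FALSE)
  ind$value <- 1
  # one positive indicator doubles everywhere in 1995: pooled Q must differ
  # across epochs, per-epoch Q must not
  sel90 <- ind$indicator == "esv" & ind$epoch == 1990
  sel95 <- ind$indicator == "esv" & ind$epoch == 1995
  ind$value[sel90] <- 1:5
  ind$value[sel95] <- 2 * (1:5)
  suppressWarnings({
    q_all <- normalize_indicators(ind, w, pool = "all")
    q_ep <- normalize_indicators(ind, w, pool = "epoch")
  })
  expect_equal(max(q_all$q[sel90]), (5 - 1) / (10 - 1))
  expect_equal(max(q_ep$q[sel90]), 1)
  expect_equal(q_ep$q[sel95], q_ep$q[sel90])
})

test_that("Jenks breaks equal the exhaustive-partition optimum", {
  expect_equal(jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2), 3)

  # k distinct values, k classes: every value its own class
  expect_equal(jenks_breaks(c(4, 9, 2, 7), k = 4), c(2, 4, 7))

  set.seed(52)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    k <- sample(2:min(5, n - 1), 1)
    x <- round(runif(n, 0, 100), 1)
    got <- jenks_breaks(x, k)
    oracle <- bf_jenks(x, k)
    expect_equal(bf_jenks_ssd_of_breaks(x, got), oracle$ssd, tolerance = 1e-9)
  }

  expect_warning(b <- jenks_breaks(c(1, 1, 2, 2), k = 5), "reducing k")
  expect_length(b, 1)
})

test_that("classification respects breaks, boundaries and partitions", {
  breaks <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(as.character(classify_esh(0.1, breaks)), "ill")
  expect_equal(as.character(classify_esh(0.95, breaks)), "excellent healthy")
  # boundary values fall to the lower class
  expect_equal(as.character(classify_esh(0.4, breaks)), "unhealthy")

  set.seed(53)
  esh <- runif(200)
  cls <- classify_esh(esh, jenks_breaks(esh, 5))
  expect_false(anyNA(cls))
  shares <- table(cls) / length(cls)
  expect_equal(sum(shares), 1)
  tab <- data.frame(epoch = rep(1990, 200), class = cls)
  cs <- class_shares(tab)
  expect_equal(sum(cs$share), 1)
})
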