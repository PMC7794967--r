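#' Spatial weights on the fishnet
#'
#' Contiguity (or k-nearest-neighbour) weights over grid cells, optionally
#' restricted to a subset of cells (missing-value cells are dropped before
#' neighbours are found, so cells isolated by missingness get empty weight
#' rows). Queen contiguity (edge or corner, up to 8 neighbours) is the
#' default.
#'
#' @param grid a [build_fishnet()] grid.
#' @param scheme `"queen"`, `"rook"` or `"knn"`.
#' @param row_standardize divide each row by its neighbour count (default
#'   TRUE).
#' @param include optional vector of 0-based cell ids to keep (e.g. cells
#'   with non-missing values); default all.
#' @param k neighbour count for `scheme = "knn"`.
#' @return object of class `kh_weights_sp`: list with `ids` (0-based cell
#'   ids, in order), `nb` (list of integer indices into `ids`), `w` (list
#'   of numeric weights), `scheme`, `row_standardized`.
#' @export
build_weights <- function(grid, scheme = c("queen", "rook", "knn"),
                          row_standardize = TRUE, include = NULL, k = 8) {
  scheme <- match.arg(scheme)
  keep <- if (is.null(include)) seq_len(nrow(grid)) else
    which(grid$cell_id %in% include)
  ids <- grid$cell_id[keep]
  rows <- grid$row[keep]; cols <- grid$col[keep]
  n <- length(keep)
  nb <- vector("list", n)
  if (scheme %in% c("queen", "rook")) {
    key <- rows * (max(cols) + 2L) + cols
    lookup <- stats::setNames(seq_len(n), key)
    offs <- if (scheme == "queen")
      cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
            dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
    else cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
    for (i in seq_len(n)) {
      kk <- (rows[i] + offs[, "dr"]) * (max(cols) + 2L) + (cols[i] + offs[, "dc"])
      hit <- lookup[as.character(kk)]
      nb[[i]] <- sort(unname(hit[!is.na(hit)]))
    }
  } else {
    x <- grid$x[keep]; y <- grid$y[keep]
    k <- min(k, n - 1)
    for (i in seq_len(n)) {
      d <- (x - x[i])^2 + (y - y[i])^2
      d[i] <- Inf
      nb[[i]] <- sort(order(d)[seq_len(k)])
    }
  }
  w <- lapply(nb, function(j) {
    if (length(j) == 0) numeric(0)
    else if (row_standardize) rep(1 / length(j), length(j))
    else rep(1, length(j))
  })
  structure(list(ids = ids, nb = nb, w = w, scheme = scheme,
                 row_standardized = row_standardize),
            class = "kh_weights_sp")
}

#' @export
print.kh_weights_sp <- function(x, ...) {
  cat(sprintf("<kh_weights_sp> %s, n=%d, row-standardized=%s, %d links\n",
              x$scheme, length(x$ids), x$row_standardized,
              sum(lengths(x$nb))))
  invisible(x)
}

#' Dense matrix form of spatial weights
#' @param W a [build_weights()] object.
#' @return n x n numeric matrix.
#' @export
weights_matrix <- function(W) {
  n <- length(W$ids)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) m[i, W$nb[[i]]] <- W$w[[i]]
  m
}

# spatial lag of a vector under list-form weights
spatial_lag <- function(W, z) {
  vapply(seq_along(W$nb), function(i) {
    j <- W$nb[[i]]
    if (length(j) == 0) return(0)
    sum(W$w[[i]] * z[j])
  }, numeric(1))
}

zscore_pop <- function(x) {
  s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
  if (s == 0) stop("zero variance: Moran statistics undefined")
  (x - mean(x)) / s
}

#' Global bivariate Moran's I
#'
#' \eqn{I = \frac{1}{n} \sum_i z_{x,i} \sum_j w_{ij} z_{y,j}} with x and y
#' standardized by their population standard deviations and row-standardized
#' weights: how one variable at a location co-varies with the neighbourhood
#' average of the other. With `y = x` it reduces to univariate Moran's I.
#'
#' @param x,y numeric vectors on the weight object's cell set (no NAs).
#' @param W a [build_weights()] object.
#' @return scalar I.
#' @export
bivariate_moran <- function(x, y, W) {
  n <- length(W$ids)
  if (length(x) != n || length(y) != n)
    stop("x and y must have one value per weighted cell")
  if (n < 2) stop("need at least two cells")
  if (anyNA(x) || anyNA(y)) stop("x and y must be complete (drop missing cells first)")
  zx <- zscore_pop(x); zy <- zscore_pop(y)
  sum(zx * spatial_lag(W, zy)) / n
}

#' Monte-Carlo permutation test of bivariate Moran's I
#'
#' Permutes y uniformly over locations (x and the weights fixed) `n_perm`
#' times. The pseudo p-value is one-sided in the direction of the observed
#' sign, \eqn{p = (m + 1) / (n_{perm} + 1)} with m the count of permuted
#' statistics at least as extreme in that direction — the reporting
#' convention of common spatial-analysis GUIs, with floor 0.001 at 999
#' permutations. A folded two-sided p (`min(1, 2 p)`) is also returned and
#' is the one to threshold when a level-alpha test is wanted, because the
#' direction is chosen by the data.
#'
#' @param x,y numeric vectors on the weight object's cell set.
#' @param W a [build_weights()] object.
#' @param n_perm number of permutations, default 999.
#' @param seed integer seed; the test is deterministic given it.
#' @return object of class `kh_moran`: list with `I_obs`, `permutations`,
#'   `pseudo_p`, `p_two_sided`, `z_value` (permutation mean/sd based),
#'   `perm_mean`, `perm_sd`, `seed`.
#' @export
moran_permutation_test <- function(x, y, W, n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- length(W$ids)
  zx <- zscore_pop(x); zy <- zscore_pop(y)
  # dense weights: one matrix product evaluates all permutations
  wm <- weights_matrix(W)
  I_obs <- sum(zx * as.vector(wm %*% zy)) / n
  perm <- with_seed(seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    as.vector(crossprod(zx, wm %*% matrix(zy[idx], n, n_perm))) / n
  })
  m <- if (I_obs >= 0) sum(perm >= I_obs) else sum(perm <= I_obs)
  pseudo_p <- (m + 1) / (n_perm + 1)
  structure(list(I_obs = I_obs, permutations = n_perm,
                 pseudo_p = pseudo_p,
                 p_two_sided = min(1, 2 * pseudo_p),
                 z_value = (I_obs - mean(perm)) / stats::sd(perm),
                 perm_mean = mean(perm), perm_sd = stats::sd(perm),
                 perm = perm, seed = seed),
            class = "kh_moran")
}

#' @export
print.kh_moran <- function(x, ...) {
  cat(sprintf("<kh_moran> I = %.4f, z = %.3f, pseudo-p = %.4g (%d permutations)\n",
              x$I_obs, x$z_value, x$pseudo_p, x$permutations))
  invisible(x)
}

#' Local bivariate Moran (LISA) with cluster classification
#'
#' Per cell, \eqn{I_i = z_{x,i} \sum_j w_{ij} z_{y,j}}; significance by
#' conditional permutation (the values of y at all other locations are
#' permuted and each cell's neighbour set resampled `n_perm` times).
#' Cluster classes come from the signs of \eqn{z_{x,i}} and of the spatial
#' lag of \eqn{z_y}: High-High, High-Low, Low-High, Low-Low; cells whose
#' pseudo p exceeds `alpha` are "not significant". The mean of the local
#' statistics equals the global bivariate Moran's I.
#'
#' @param x,y numeric vectors on the weight object's cell set.
#' @param W a [build_weights()] object.
#' @param n_perm permutations per cell, default 999.
#' @param alpha significance threshold on the local pseudo p, default 0.05.
#' @param seed integer seed.
#' @return data.frame of class `kh_lisa`: `cell_id`, `I_local`, `pseudo_p`,
#'   `cluster` (factor: High-High, High-Low, Low-High, Low-Low,
#'   not significant).
#' @export
bivariate_lisa <- function(x, y, W, n_perm = 999, alpha = 0.05, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- length(W$ids)
  zx <- zscore_pop(x); zy <- zscore_pop(y)
  lag_y <- spatial_lag(W, zy)
  I_loc <- zx * lag_y
  p_loc <- rep(NA_real_, n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      ki <- length(W$nb[[i]])
      if (ki == 0) next
      others <- zy[-i]
      draws <- matrix(others[vapply(seq_len(n_perm),
                                    function(r) sample.int(n - 1, ki),
                                    integer(ki))],
                      nrow = ki)
      perm_lag <- as.vector(W$w[[i]] %*% draws)
      perm_I <- zx[i] * perm_lag
      m <- if (I_loc[i] >= 0) sum(perm_I >= I_loc[i]) else sum(perm_I <= I_loc[i])
      p_loc[i] <- (m + 1) / (n_perm + 1)
    }
  })
  cls <- ifelse(zx >= 0,
                ifelse(lag_y >= 0, "High-High", "High-Low"),
                ifelse(lag_y >= 0, "Low-High", "Low-Low"))
  cls[is.na(p_loc) | p_loc > alpha] <- "not significant"
  structure(data.frame(cell_id = W$ids, I_local = I_loc, pseudo_p = p_loc,
                       cluster = factor(cls, levels = c("High-High", "High-Low",
                                                        "Low-High", "Low-Low",
                                                        "not significant"))),
            class = c("kh_lisa", "data.frame"))
}
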