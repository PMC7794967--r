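#' Construction-land proportion
#'
#' Fraction of each cell under built-up land: the land-cover component of
#' the urbanization index.
#'
#' @param lu categorical [kh_raster].
#' @param grid a [build_fishnet()] grid.
#' @param epoch year label.
#' @return indicator layer `clp`.
#' @export
clp <- function(lu, grid, epoch = NA) {
  zonal_fraction(lu, grid, "builtup", name = "clp", epoch = epoch)
}

#' Composite urbanization index
#'
#' Per cell, the mean of the min-max normalized population density,
#' per-capita GDP and construction-land proportion, each normalized with
#' the positive formula pooled across all epochs so levels are comparable
#' over time. A cell missing any component is missing.
#'
#' @param pop_layers,gdp_layers,clp_layers lists of indicator layers, one
#'   per epoch (same epoch order), from [pop_density()], [zonal_mean()] on
#'   the GDP raster, and [clp()].
#' @param weights component weights `c(pop, gdp, clp)`, default equal
#'   thirds.
#' @param pool `"all"` (default) or `"epoch"` normalization pool.
#' @return long data.frame `cell_id`, `epoch`, `q_pop`, `q_gdp`, `q_clp`,
#'   `U`.
#' @export
urbanization_index <- function(pop_layers, gdp_layers, clp_layers,
                               weights = c(1, 1, 1) / 3,
                               pool = c("all", "epoch")) {
  pool <- match.arg(pool)
  if (length(pop_layers) != length(gdp_layers) ||
      length(pop_layers) != length(clp_layers))
    stop("component layer lists must cover the same epochs")
  if (abs(sum(weights) - 1) > 1e-9) stop("component weights must sum to 1")
  epochs <- vapply(pop_layers, function(l) attr(l, "epoch"), numeric(1))
  stack <- function(layers) unlist(lapply(layers, function(l) l$value))
  pop <- stack(pop_layers); gdp <- stack(gdp_layers); cl <- stack(clp_layers)
  n_cell <- nrow(pop_layers[[1]])
  ep_col <- rep(epochs, each = n_cell)
  norm <- function(x) {
    if (pool == "all") normalize_minmax(x, "positive")
    else {
      out <- x
      for (ep in unique(ep_col))
        out[ep_col == ep] <- normalize_minmax(x[ep_col == ep], "positive")
      out
    }
  }
  q_pop <- norm(pop); q_gdp <- norm(gdp); q_clp <- norm(cl)
  u <- q_pop * weights[1] + q_gdp * weights[2] + q_clp * weights[3]
  data.frame(cell_id = rep(pop_layers[[1]]$cell_id, length(epochs)),
             epoch = ep_col, q_pop = q_pop, q_gdp = q_gdp, q_clp = q_clp,
             U = u)
}
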