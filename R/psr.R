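#' Indicator weight scheme of the ecosystem-health index
#'
#' The fixed AHP-derived weights, criterion-layer membership and
#' normalization direction of the twelve indicators. The defaults sum to
#' exactly 1.00 (pressure 0.42, state 0.43, response 0.15). Pressure
#' indicators and rocky-desertification sensitivity are negative-direction:
#' after normalization a high subscore means low pressure / low sensitivity,
#' so that a higher ESH is always healthier.
#'
#' @param entries optional replacement data.frame with columns `indicator`,
#'   `layer` (`pressure`/`state`/`response`), `direction`
#'   (`positive`/`negative`), `weight`.
#' @return data.frame of class `kh_weights`.
#' @export
weight_scheme <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- data.frame(
      indicator = c("pop_density", "interference", "reclamation_rate",
                    "steep_farmland",
                    "vegetation_coverage", "shei", "shdi", "contag",
                    "resilience", "esv",
                    "forest_proportion", "rds_sensitivity"),
      layer = c(rep("pressure", 4), rep("state", 6), rep("response", 2)),
      direction = c(rep("negative", 4), rep("positive", 6),
                    "positive", "negative"),
      weight = c(0.11, 0.14, 0.12, 0.05,
                 0.11, 0.03, 0.03, 0.03, 0.10, 0.13,
                 0.10, 0.05),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("indicator", "layer", "direction", "weight") %in%
                  names(entries)))
  if (any(entries$weight <= 0)) stop("weights must be positive")
  if (abs(sum(entries$weight) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(entries$weight)), ")")
  if (anyDuplicated(entries$indicator))
    stop("duplicate indicator in weight scheme")
  if (!all(entries$layer %in% c("pressure", "state", "response")))
    stop("layer must be pressure, state or response")
  if (!all(entries$direction %in% c("positive", "negative")))
    stop("direction must be positive or negative")
  structure(entries, class = c("kh_weights", "data.frame"))
}

#' Min-max normalization of an indicator across epochs
#'
#' Positive direction: \eqn{Q = (X - X_{min}) / (X_{max} - X_{min})};
#' negative direction: \eqn{Q = 1 - (X - X_{min}) / (X_{max} - X_{min})}.
#' The min and max are pooled over the whole normalization pool — by default
#' every epoch jointly — so normalized values are comparable across years.
#' Missing values propagate. A constant indicator degenerates to Q = 0.5
#' with a warning.
#'
#' @param values numeric vector (the pooled values to normalize).
#' @param direction `"positive"` or `"negative"`.
#' @return numeric vector of Q values in \[0, 1\].
#' @export
normalize_minmax <- function(values, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  fin <- is.finite(values)
  if (!any(fin)) return(rep(NA_real_, length(values)))
  xmin <- min(values[fin]); xmax <- max(values[fin])
  if (xmax == xmin) {
    warning("constant indicator: normalization degenerates to 0.5")
    q <- ifelse(fin, 0.5, NA_real_)
    return(q)
  }
  q <- (values - xmin) / (xmax - xmin)
  if (direction == "negative") q <- 1 - q
  q[!fin] <- NA_real_
  q
}

#' Normalize a long indicator table
#'
#' Applies [normalize_minmax()] per indicator with its configured direction,
#' pooling min/max across all epochs (`pool = "all"`) or within each epoch
#' (`pool = "epoch"`).
#'
#' @param ind long data.frame `cell_id`, `epoch`, `indicator`, `value`.
#' @param weights a [weight_scheme()] (supplies directions).
#' @param pool `"all"` (default) or `"epoch"`.
#' @return the input with an extra column `q`.
#' @export
normalize_indicators <- function(ind, weights = weight_scheme(),
                                 pool = c("all", "epoch")) {
  pool <- match.arg(pool)
  miss <- setdiff(unique(ind$indicator), weights$indicator)
  if (length(miss) > 0)
    stop("indicator(s) missing from weight scheme: ",
         paste(miss, collapse = ", "))
  dir_of <- stats::setNames(weights$direction, weights$indicator)
  ind$q <- NA_real_
  groups <- if (pool == "all") ind$indicator else
    interaction(ind$indicator, ind$epoch, drop = TRUE)
  for (g in unique(groups)) {
    sel <- groups == g
    nm <- ind$indicator[sel][1]
    ind$q[sel] <- normalize_minmax(ind$value[sel], dir_of[[nm]])
  }
  ind
}

#' Criterion-layer subscore
#'
#' Per cell, \eqn{\sum_{i \in layer} W_i Q_i} over the indicators assigned
#' to one criterion layer. All of the layer's indicators must be present;
#' a cell missing any of them is missing.
#'
#' @param qtab wide data.frame of normalized values: `cell_id` plus one
#'   column per indicator (one epoch).
#' @param weights a [weight_scheme()].
#' @param layer `"pressure"`, `"state"` or `"response"`.
#' @return numeric vector of subscores, one per row of `qtab`.
#' @export
layer_subscore <- function(qtab, weights = weight_scheme(),
                           layer = c("pressure", "state", "response")) {
  layer <- match.arg(layer)
  w <- weights[weights$layer == layer, ]
  miss <- setdiff(w$indicator, names(qtab))
  if (length(miss) > 0)
    stop("missing indicator(s) for ", layer, " layer: ",
         paste(miss, collapse = ", "))
  as.vector(as.matrix(qtab[, w$indicator, drop = FALSE]) %*% w$weight)
}

#' Combine criterion-layer subscores into the ecosystem-health index
#'
#' \eqn{ESH = P + S + R}: by construction equal to \eqn{\sum_i W_i Q_i}
#' over all twelve indicators, and in \[0, 1\] because the weights sum to 1
#' and every Q is in \[0, 1\].
#'
#' @param p,s,r pressure, state and response subscores (vectors or scalars).
#' @return numeric vector of ESH values.
#' @export
esh_combine <- function(p, s, r) {
  p + s + r
}

#' Compute per-cell ESH for every epoch
#'
#' Full composite pipeline: normalize the long indicator table (pooled
#' across epochs), weight-sum each criterion layer, add the layers.
#'
#' @param ind long indicator table (`cell_id`, `epoch`, `indicator`,
#'   `value`) holding all twelve indicators for all epochs.
#' @param weights a [weight_scheme()].
#' @param pool normalization pool, see [normalize_indicators()].
#' @return data.frame of class `kh_esh`: `cell_id`, `epoch`, `P`, `S`, `R`,
#'   `ESH`, plus one `q_*` column per indicator.
#' @export
compute_esh <- function(ind, weights = weight_scheme(),
                        pool = c("all", "epoch")) {
  qt <- normalize_indicators(ind, weights, match.arg(pool))
  out <- NULL
  for (ep in unique(qt$epoch)) {
    sub <- qt[qt$epoch == ep, ]
    wide <- stats::reshape(sub[, c("cell_id", "indicator", "q")],
                           idvar = "cell_id", timevar = "indicator",
                           direction = "wide")
    names(wide) <- sub("^q\\.", "", names(wide))
    wide <- wide[order(wide$cell_id), ]
    p <- layer_subscore(wide, weights, "pressure")
    s <- layer_subscore(wide, weights, "state")
    r <- layer_subscore(wide, weights, "response")
    res <- data.frame(cell_id = wide$cell_id, epoch = ep,
                      P = p, S = s, R = r, ESH = esh_combine(p, s, r))
    qcols <- wide[, setdiff(names(wide), "cell_id"), drop = FALSE]
    names(qcols) <- paste0("q_", names(qcols))
    out <- rbind(out, cbind(res, qcols))
  }
  structure(out, class = c("kh_esh", "data.frame"))
}

#' Jenks (Fisher) natural-breaks classification
#'
#' Optimal 1-D partition of the values into `k` classes minimizing the
#' within-class sum of squared deviations, by dynamic programming over the
#' sorted unique values (exact, deterministic). Returns the k-1 inner break
#' points as upper bounds of the lower classes, so classification assigns
#' boundary values to the lower class.
#'
#' @param values numeric vector (NAs dropped).
#' @param k number of classes, default 5.
#' @return numeric vector of k-1 breaks (class upper bounds). If fewer than
#'   `k` distinct values exist, `k` is reduced with a warning.
#' @export
jenks_breaks <- function(values, k = 5) {
  x <- sort(values[is.finite(values)])
  ux <- unique(x)
  if (length(ux) < k) {
    warning("fewer than ", k, " distinct values; reducing k to ", length(ux))
    k <- length(ux)
  }
  if (k <= 1) return(numeric(0))
  # weighted DP over unique values
  wts <- as.vector(table(match(x, ux)))
  n <- length(ux)
  cw <- cumsum(wts)
  cwx <- cumsum(wts * ux)
  cwx2 <- cumsum(wts * ux^2)
  # ssq of unique-value range a..b (1-based, inclusive)
  ssq <- function(a, b) {
    W <- cw[b] - if (a > 1) cw[a - 1] else 0
    Sx <- cwx[b] - if (a > 1) cwx[a - 1] else 0
    Sx2 <- cwx2[b] - if (a > 1) cwx2[a - 1] else 0
    Sx2 - Sx^2 / W
  }
  cost <- matrix(Inf, k, n)      # cost[c, i]: best SSD of first i values in c classes
  back <- matrix(0L, k, n)
  for (i in seq_len(n)) cost[1, i] <- ssq(1, i)
  if (k > 1) {
    for (cc in 2:k) {
      for (i in cc:n) {
        # last class spans j..i; vectorized over j
        js <- cc:i
        prev <- cost[cc - 1, js - 1]
        W <- cw[i] - cw[js - 1]
        Sx <- cwx[i] - cwx[js - 1]
        Sx2 <- cwx2[i] - cwx2[js - 1]
        tot <- prev + (Sx2 - Sx^2 / W)
        b <- which.min(tot)
        cost[cc, i] <- tot[b]
        back[cc, i] <- js[b]
      }
    }
  }
  # recover class boundaries
  breaks <- numeric(k - 1)
  i <- n
  for (cc in k:2) {
    j <- back[cc, i]
    breaks[cc - 1] <- ux[j - 1]   # upper bound of class cc-1
    i <- j - 1
  }
  breaks
}

#' Health-class labels, from worst to best
#' @return character vector of the five health levels.
#' @export
health_levels <- function() {
  c("ill", "unhealthy", "middle", "healthy", "excellent healthy")
}

#' Classify ESH values into health levels
#'
#' Interval membership against natural breaks computed on the pooled
#' multi-epoch ESH distribution (single legend for all years); boundary
#' values fall in the lower class.
#'
#' @param esh numeric vector of ESH values.
#' @param breaks inner break points from [jenks_breaks()] (k-1 values).
#' @param labels class labels from worst to best; default the five health
#'   levels (truncated if fewer breaks).
#' @return factor of health classes (NA for missing ESH).
#' @export
classify_esh <- function(esh, breaks, labels = health_levels()) {
  k <- length(breaks) + 1
  labels <- if (k == 5) labels else labels[seq_len(k)]
  # left-open intervals put a value equal to a break in the lower class
  idx <- findInterval(esh, breaks, left.open = TRUE) + 1L
  factor(labels[idx], levels = labels)
}

#' Per-epoch share of each health class
#'
#' @param esh_tab a [compute_esh()] result with a `class` column, or a
#'   data.frame with `epoch` and `class`.
#' @return data.frame `epoch`, `class`, `n`, `share` (share of non-missing
#'   cells; shares sum to 1 within epoch).
#' @export
class_shares <- function(esh_tab) {
  ok <- !is.na(esh_tab$class)
  tab <- as.data.frame(table(epoch = esh_tab$epoch[ok],
                             class = esh_tab$class[ok]))
  names(tab)[3] <- "n"
  tot <- stats::ave(tab$n, tab$epoch, FUN = sum)
  tab$share <- tab$n / tot
  tab
}
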