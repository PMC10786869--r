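# Skill assessment: seasonal climatologies, the Liu-mean efficiency score
# over spatial fields, and comparison against point observations.

#' Seasonal climatology of a monthly field
#'
#' Per-cell mean over all months of each meteorological season (DJF = Dec,
#' Jan, Feb; MAM; JJA; SON) within the period. Months pool by calendar month,
#' so the result is idempotent over repeated identical years.
#'
#' @param field a \code{\link{gridded_field}}.
#' @param period numeric \code{c(first_year, last_year)} or \code{NULL}.
#' @return named list of four single-time \code{gridded_field}s
#'   (\code{DJF}, \code{MAM}, \code{JJA}, \code{SON}).
#' @export
seasonal_climatology <- function(field, period = NULL) {
  keep <- in_period(field$times, period)
  if (!any(keep)) stop_validation("period selects no time steps")
  mo <- month_of(field$times)
  seasons <- list(DJF = c(12, 1, 2), MAM = 3:5, JJA = 6:8, SON = 9:11)
  rep_month <- c(DJF = 1, MAM = 4, JJA = 7, SON = 10)
  y0 <- min(year_of(field$times[keep]))
  out <- lapply(names(seasons), function(s) {
    idx <- keep & mo %in% seasons[[s]]
    if (!any(idx)) stop_validation("season ", s, " absent from the period")
    m <- apply(field$values[idx, , , drop = FALSE], c(2, 3), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    gridded_field(field$grid, array(m, dim = c(1, dim(m))),
                  as.Date(sprintf("%04d-%02d-01", y0, rep_month[[s]])),
                  field$variable, field$units, field$depth_label)
  })
  stats::setNames(out, names(seasons))
}

#' Liu-mean efficiency skill score
#'
#' \code{LSE = 1 - sqrt((rho * alpha - 1)^2 + (beta - 1)^2)} where \code{rho}
#' is the spatial Pearson correlation, \code{alpha} the ratio of model mean to
#' observed mean and \code{beta} the ratio of model to observed standard
#' deviation. 1 is a perfect comparison; no clamping is applied, so strongly
#' biased fields can score below 0.
#'
#' @param rho spatial Pearson correlation.
#' @param alpha model mean / observed mean.
#' @param beta model std / observed std (must be >= 0).
#' @return the combined score (<= 1).
#' @export
lse <- function(rho, alpha, beta) {
  if (!all(is.finite(c(rho, alpha, beta))))
    stop_validation("lse requires finite rho, alpha, beta")
  1 - sqrt((rho * alpha - 1)^2 + (beta - 1)^2)
}

.metric_one <- function(m, o, w = NULL) {
  ok <- !is.na(m) & !is.na(o)
  if (sum(ok) < 3) stop_domain("fewer than 3 jointly valid cells")
  m <- m[ok]; o <- o[ok]
  if (is.null(w)) w <- rep(1, length(m)) else w <- w[ok]
  w <- w / sum(w)
  mbar <- sum(w * m); obar <- sum(w * o)
  msd <- sqrt(sum(w * (m - mbar)^2)); osd <- sqrt(sum(w * (o - obar)^2))
  if (obar == 0 || osd == 0)
    stop_domain("degenerate observed field (zero mean or zero std)")
  rho <- sum(w * (m - mbar) * (o - obar)) / (msd * osd)
  alpha <- mbar / obar
  beta <- msd / osd
  c(alpha = alpha, beta = beta, rho = rho, lse = lse(rho, alpha, beta))
}

#' Spatial skill of a model climatology against an observed climatology
#'
#' Computes, for each meteorological season, the mean ratio \code{alpha}, the
#' standard-deviation ratio \code{beta}, the spatial Pearson correlation
#' \code{rho} and the combined Liu-mean efficiency score over the jointly
#' valid cells, plus the arithmetic mean of the four seasonal values of each
#' metric. The model is regridded bilinearly to the observation grid when the
#' grids differ. Temperature fields in Celsius are shifted to Kelvin before
#' the ratios are formed (the ratio of means is unstable near 0 degC).
#'
#' @param model a \code{\link{gridded_field}} (multi-month).
#' @param obs the observed/reference \code{gridded_field}.
#' @param period climatology period \code{c(first_year, last_year)} or NULL.
#' @param kelvin shift Celsius temperatures by 273.15 before scoring
#'   (default TRUE; only applied when \code{variable == "temperature"} and the
#'   units look like Celsius).
#' @param weight_lat use cos(latitude) cell weights (default FALSE:
#'   equal-weight cells).
#' @return an object of class \code{skill_score}: a data.frame with rows
#'   \code{DJF}, \code{MAM}, \code{JJA}, \code{SON}, \code{mean}.
#' @export
spatial_skill <- function(model, obs, period = NULL, kelvin = TRUE,
                          weight_lat = FALSE) {
  stopifnot(inherits(model, "gridded_field"), inherits(obs, "gridded_field"))
  if (!isTRUE(all.equal(model$grid$lats, obs$grid$lats)) ||
      !isTRUE(all.equal(model$grid$lons, obs$grid$lons)))
    model <- regrid_bilinear(model, obs$grid)
  offset <- 0
  if (kelvin && identical(model$variable, "temperature") &&
      grepl("c", model$units, ignore.case = TRUE) &&
      !grepl("k", model$units, ignore.case = TRUE))
    offset <- 273.15
  cm <- seasonal_climatology(model, period)
  co <- seasonal_climatology(obs, period)
  w <- if (weight_lat)
    rep(cos(obs$grid$lats * pi / 180), times = length(obs$grid$lons)) else NULL
  rows <- lapply(names(cm), function(s)
    .metric_one(as.vector(cm[[s]]$values) + offset,
                as.vector(co[[s]]$values) + offset, w))
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- rbind(tab, colMeans(tab))
  rownames(tab) <- c(names(cm), "mean")
  tab$season <- rownames(tab)
  structure(tab[c("season", "alpha", "beta", "rho", "lse")],
            class = c("skill_score", "data.frame"))
}

#' @export
print.skill_score <- function(x, digits = 4, ...) {
  cat("Seasonal spatial skill (alpha = mean ratio, beta = std ratio,\n")
  cat("rho = spatial correlation, lse = Liu-mean efficiency):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Match point observations to a gridded product
#'
#' Pairs each observation record with its nearest grid node if the
#' great-circle distance is at most \code{h_tol} metres and the depth differs
#' from the product depth by at most \code{v_tol} metres. Time stamps are not
#' matched: all records inside the comparison period pool into one
#' distribution, and the model side of each pair is the climatological
#' distribution of all monthly values at the matched cell (its median is
#' reported as \code{model_value}).
#'
#' @param obs data.frame with columns \code{lon}, \code{lat}, \code{depth},
#'   \code{time}, \code{value} (and optionally \code{source}).
#' @param product a \code{\link{gridded_field}}.
#' @param product_depth depth of the product level in metres (default 5).
#' @param period comparison period \code{c(first_year, last_year)} or NULL.
#' @param h_tol horizontal tolerance in metres (default 100).
#' @param v_tol vertical tolerance in metres (default 1).
#' @return an object of class \code{matched_pairs}: a data.frame with one row
#'   per matched record (\code{obs_value}, \code{model_value}, \code{cell_i},
#'   \code{cell_j}, \code{depth}, \code{dist_m}) and the pooled per-pair model
#'   distributions in \code{attr(, "model_pool")}.
#' @export
match_observations <- function(obs, product, product_depth = 5, period = NULL,
                               h_tol = 100, v_tol = 1) {
  stopifnot(is.data.frame(obs), inherits(product, "gridded_field"))
  if (!nrow(obs)) stop_validation("obs is empty")
  g <- product$grid
  keep_t <- in_period(product$times, period)
  vflat <- flat_values(product)[keep_t, , drop = FALSE]
  node_lat <- rep(g$lats, times = length(g$lons))
  node_lon <- rep(g$lons, each = length(g$lats))
  ocean <- as.vector(g$mask) & colSums(!is.na(vflat)) > 0
  obs_t <- as.Date(obs$time)
  in_p <- if (is.null(period)) rep(TRUE, nrow(obs)) else
    year_of(obs_t) >= period[1] & year_of(obs_t) <= period[2]
  rows <- list(); pools <- list()
  for (r in which(in_p)) {
    if (abs(obs$depth[r] - product_depth) > v_tol) next
    d <- gc_dist(obs$lon[r], obs$lat[r], node_lon[ocean], node_lat[ocean])
    k <- which.min(d)
    if (d[k] > h_tol) next
    cell <- which(ocean)[k]
    pool <- vflat[, cell]
    pool <- pool[!is.na(pool)]
    if (!length(pool)) next
    i <- (cell - 1L) %% length(g$lats) + 1L
    j <- (cell - 1L) %/% length(g$lats) + 1L
    rows[[length(rows) + 1L]] <-
      data.frame(obs_value = obs$value[r], model_value = stats::median(pool),
                 cell_i = i, cell_j = j, depth = obs$depth[r], dist_m = d[k])
    pools[[length(pools) + 1L]] <- pool
  }
  if (!length(rows)) {
    warning("no observations matched the product within the tolerances")
    out <- data.frame(obs_value = numeric(0), model_value = numeric(0),
                      cell_i = integer(0), cell_j = integer(0),
                      depth = numeric(0), dist_m = numeric(0))
    attr(out, "model_pool") <- list()
    attr(out, "product_depth") <- product_depth
    class(out) <- c("matched_pairs", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  attr(out, "model_pool") <- pools
  attr(out, "product_depth") <- product_depth
  class(out) <- c("matched_pairs", "data.frame")
  out
}

#' Observed-versus-model distribution summary of matched pairs
#'
#' Bins the observed values and the pooled model values on a common grid of
#' equal-width bins and reports both frequency tables, the overlap
#' coefficient of the two (normalised) value histograms, and depth histograms
#' for both sides.
#'
#' @param pairs a \code{\link{match_observations}} result with >= 1 pair.
#' @param n_bins number of value bins (default 20).
#' @return list with \code{value_breaks}, \code{obs_freq}, \code{model_freq}
#'   (proportions), \code{overlap}, \code{depth_breaks}, \code{obs_depth_freq},
#'   \code{model_depth_freq}.
#' @export
distribution_summary <- function(pairs, n_bins = 20) {
  if (!nrow(pairs)) stop_validation("no matched pairs")
  o <- pairs$obs_value
  m <- unlist(attr(pairs, "model_pool"))
  rng <- range(c(o, m))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  ho <- graphics::hist(o, breaks = breaks, plot = FALSE)$counts
  hm <- graphics::hist(m, breaks = breaks, plot = FALSE)$counts
  po <- ho / sum(ho); pm <- hm / sum(hm)
  dmax <- max(c(pairs$depth, attr(pairs, "product_depth"), 1))
  dbreaks <- seq(0, dmax * 1.001, length.out = 11)
  hd_o <- graphics::hist(pairs$depth, breaks = dbreaks, plot = FALSE)$counts
  hd_m <- graphics::hist(rep(attr(pairs, "product_depth"), nrow(pairs)),
               breaks = dbreaks, plot = FALSE)$counts
  list(value_breaks = breaks, obs_freq = po, model_freq = pm,
       overlap = sum(pmin(po, pm)),
       depth_breaks = dbreaks, obs_depth_freq = hd_o / sum(hd_o),
       model_depth_freq = hd_m / sum(hd_m))
}

#' Read point observations from delimited text
#' @param path file with columns lon, lat, depth, time, value, source.
#' @param sep field separator (default tab).
#' @return data.frame of observation records.
#' @export
read_observations <- function(path, sep = "\t") {
  obs <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("lon", "lat", "depth", "time", "value")
  if (!all(need %in% names(obs)))
    stop_validation("observation file must have columns ",
                    paste(need, collapse = ", "))
  obs$time <- as.Date(obs$time)
  obs
}

#' Write point observations as delimited text
#' @param obs data.frame of observation records.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_observations <- function(obs, path, sep = "\t") {
  utils::write.table(obs, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
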