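# Seeded synthetic-data generators with known truth: a fine-grid reference
# (emulating a high-resolution reanalysis), coarse model members with known
# bias / variance distortion / per-scenario trend, and point observations.
# Every generator is a pure function of (config, seed).

#' Configuration for the synthetic study setup
#'
#' Defaults emulate the study conditions at desk scale: a 24 x 24 fine grid
#' at nominal 1/12 degree, coarsening factor 6 (coarse 4 x 4 at 0.5 degree,
#' mirroring the resolution ratio between a global ESM and the reference),
#' monthly data 1993-2100 with the historical window ending in 2014,
#' AR(1) monthly noise, and per-scenario warming trends of 0.1 / 0.2 / 0.4
#' units per decade (1, 2 and 4 units per century for the low, middle and
#' high emission pathways).
#'
#' @param nx,ny fine grid size (lon x lat); the coarsening factor must divide
#'   both.
#' @param lon0,lat0 south-west corner of the domain, degrees.
#' @param res fine grid resolution in degrees (default 1/12).
#' @param coarsen_factor fine cells per coarse cell per axis (default 6).
#' @param hist_years historical window \code{c(first, last)} (default
#'   1993-2014).
#' @param proj_end last projection year (default 2100).
#' @param base_value domain-mean value (default 10, e.g. degC).
#' @param large_amp amplitude of the smooth large-scale pattern.
#' @param fine_amp amplitude of the stationary fine-scale (sub-grid) pattern.
#' @param seasonal_amp amplitude of the seasonal sinusoid.
#' @param trend_hist historical trend, units per decade.
#' @param scenario_trends named per-scenario trends (units per decade)
#'   applied after the historical window.
#' @param ar1 AR(1) coefficient of the monthly noise (default 0.6).
#' @param noise_sd marginal standard deviation of the reference noise.
#' @param var_factor variance inflation of member noise relative to the
#'   reference (default 1).
#' @param bias member bias: a number for a constant bias map shared by all
#'   members, or \code{NULL} to draw a per-model map (random constant plus a
#'   smooth gradient) from the seed.
#' @param land_frac fraction of cells masked as land in a connected coastal
#'   blob (default 0.1).
#' @param variable,units,depth_label product metadata.
#' @param seed base random seed; all member streams derive from it.
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(nx = 24, ny = 24, lon0 = 2, lat0 = 54, res = 1 / 12,
                         coarsen_factor = 6, hist_years = c(1993, 2014),
                         proj_end = 2100, base_value = 10, large_amp = 3,
                         fine_amp = 0.5, seasonal_amp = 2, trend_hist = 0.1,
                         scenario_trends = c(ssp126 = 0.1, ssp245 = 0.2,
                                             ssp585 = 0.4),
                         ar1 = 0.6, noise_sd = 0.5, var_factor = 1,
                         bias = NULL, land_frac = 0.1,
                         variable = "temperature", units = "degC",
                         depth_label = "surface", seed = 1) {
  if (ar1 < 0 || ar1 >= 1) stop_validation("ar1 must be in [0, 1)")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  if (nx %% coarsen_factor != 0 || ny %% coarsen_factor != 0)
    stop_validation("coarsen_factor must divide nx and ny")
  if (is.null(names(scenario_trends)) || !length(scenario_trends))
    stop_validation("scenario_trends must be a named vector")
  if (hist_years[1] >= hist_years[2] || proj_end <= hist_years[2])
    stop_validation("need hist_years[1] < hist_years[2] < proj_end")
  structure(as.list(environment()), class = "synth_config")
}

# Deterministic spatial ingredients: fine grid + mask, large- and fine-scale
# patterns as [lat, lon] matrices.
.synth_patterns <- function(cfg) {
  lats <- cfg$lat0 + (seq_len(cfg$ny) - 0.5) * cfg$res
  lons <- cfg$lon0 + (seq_len(cfg$nx) - 0.5) * cfg$res
  iy <- matrix(seq_len(cfg$ny), cfg$ny, cfg$nx)
  ix <- matrix(seq_len(cfg$nx), cfg$ny, cfg$nx, byrow = TRUE)
  large <- cfg$base_value +
    cfg$large_amp * (sin(pi * (iy - 0.5) / cfg$ny) - 2 / pi) +
    0.5 * cfg$large_amp * cos(pi * (ix - 0.5) / cfg$nx)
  fine <- cfg$fine_amp * sin(2 * pi * 5 * (iy - 0.5) / cfg$ny) *
    sin(2 * pi * 5 * (ix - 0.5) / cfg$nx)
  # connected land blob in the south-west corner sized to ~land_frac
  mask <- matrix(TRUE, cfg$ny, cfg$nx)
  if (cfg$land_frac > 0) {
    r2 <- (iy - 0.5)^2 + (ix - 0.5)^2
    ncells <- cfg$ny * cfg$nx
    cut <- stats::quantile(r2, cfg$land_frac, type = 1)
    mask[r2 <= cut] <- FALSE
  }
  list(lats = lats, lons = lons, large = large, fine = fine, mask = mask)
}

.seasonal <- function(months, amp) amp * cos(2 * pi * (months - 8) / 12)

# Piecewise-linear climate trend: historical rate up to the scenario
# divergence point (Jan of the year after the historical window), the
# scenario rate afterwards; continuous at the break. Rates in units/decade.
.trend_values <- function(tyears, cfg, scenario_rate) {
  t0 <- cfg$hist_years[1]
  tb <- cfg$hist_years[2] + 1
  rh <- cfg$trend_hist / 10
  rs <- scenario_rate / 10
  rh * (pmin(tyears, tb) - t0) + rs * pmax(tyears - tb, 0)
}

# AR(1) noise matrix [time, cell] with marginal sd `sd`.
.ar1_noise <- function(nt, ncell, ar1, sd) {
  if (sd == 0) return(matrix(0, nt, ncell))
  innov_sd <- sd * sqrt(1 - ar1^2)
  eps <- matrix(stats::rnorm(nt * ncell, sd = innov_sd), nt, ncell)
  if (ar1 > 0) {
    eps[1, ] <- eps[1, ] / sqrt(1 - ar1^2)   # stationary start
    eps <- apply(eps, 2, function(e) as.numeric(stats::filter(e, ar1, method = "recursive")))
  }
  matrix(eps, nt, ncell)
}

.member_seed <- function(cfg, member_id, scenario) {
  h <- sum(utf8ToInt(paste(member_id, scenario)) *
             seq_along(utf8ToInt(paste(member_id, scenario))))
  (cfg$seed * 10007 + h * 131) %% 2147483647L
}

#' Generate the fine-grid synthetic reference
#'
#' value(t, x) = large-scale smooth pattern + stationary fine-scale pattern +
#' seasonal sinusoid + historical linear trend + AR(1) monthly noise, on the
#' fine grid over the historical window. Deterministic given the config seed.
#'
#' @param config a \code{\link{synth_config}}.
#' @return a \code{\link{gridded_field}} with the realised truth in
#'   \code{attr(, "truth")} (patterns, trend, config).
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  p <- .synth_patterns(config)
  times <- monthly_times(config$hist_years[1], config$hist_years[2])
  ty <- frac_year(times)
  nt <- length(times)
  ncell <- config$ny * config$nx
  det <- outer(rep(1, nt), as.vector(p$large + p$fine)) +
    outer(.seasonal(month_of(times), config$seasonal_amp) +
            .trend_values(ty, config, config$trend_hist), rep(1, ncell))
  set.seed(config$seed %% 2147483647L)
  v <- det + .ar1_noise(nt, ncell, config$ar1, config$noise_sd)
  dim(v) <- c(nt, config$ny, config$nx)
  out <- gridded_field(md_grid(p$lats, p$lons, p$mask), v, times,
                       config$variable, config$units, config$depth_label)
  attr(out, "truth") <- list(large = p$large, fine = p$fine,
                             trend = config$trend_hist, config = config)
  out
}

#' Generate one coarse synthetic model member
#'
#' Coarsened large-scale signal + member bias map + seasonal cycle +
#' piecewise trend (historical rate, then the scenario rate) + AR(1) noise
#' with \code{var_factor} times the reference noise variance. Each
#' (member_id, scenario) pair gets an independent noise stream derived from
#' the config seed.
#'
#' @param config a \code{\link{synth_config}}.
#' @param member_id member label (e.g. \code{"model1_r1"}).
#' @param scenario a name of \code{config$scenario_trends}.
#' @param bias override of the config bias spec (number = constant map).
#' @param var_factor override of the config variance inflation.
#' @return a coarse-grid \code{\link{gridded_field}} spanning historical +
#'   projection years, with \code{attr(, "truth")} (bias map, trend,
#'   var_factor).
#' @export
make_member <- function(config, member_id = "model1_r1", scenario = "ssp245",
                        bias = config$bias, var_factor = config$var_factor) {
  stopifnot(inherits(config, "synth_config"))
  if (!scenario %in% names(config$scenario_trends))
    stop_validation("unknown scenario label: ", scenario)
  p <- .synth_patterns(config)
  f <- config$coarsen_factor
  nyc <- config$ny / f; nxc <- config$nx / f
  block_mean <- function(m) {
    bi <- (seq_len(config$ny) - 1L) %/% f + 1L
    bj <- (seq_len(config$nx) - 1L) %/% f + 1L
    t(rowsum(t(rowsum(m, bi) / f), bj) / f)
  }
  largeC <- block_mean(p$large)
  latsC <- as.numeric(tapply(p$lats, (seq_len(config$ny) - 1L) %/% f + 1L, mean))
  lonsC <- as.numeric(tapply(p$lons, (seq_len(config$nx) - 1L) %/% f + 1L, mean))
  maskC <- block_mean(p$mask + 0) > 0
  seed_m <- .member_seed(config, member_id, scenario)
  set.seed(seed_m)
  if (is.null(bias)) {
    bias_map <- stats::rnorm(1) +
      0.5 * outer((seq_len(nyc) - (nyc + 1) / 2) / max(nyc - 1, 1) * stats::rnorm(1),
                  rep(1, nxc))
  } else {
    bias_map <- matrix(bias, nyc, nxc)
  }
  bias_map <- matrix(bias_map, nyc, nxc)
  times <- monthly_times(config$hist_years[1], config$proj_end)
  ty <- frac_year(times)
  nt <- length(times)
  ncell <- nyc * nxc
  det <- outer(rep(1, nt), as.vector(largeC + bias_map)) +
    outer(.seasonal(month_of(times), config$seasonal_amp) +
            .trend_values(ty, config, config$scenario_trends[[scenario]]),
          rep(1, ncell))
  v <- det + .ar1_noise(nt, ncell, config$ar1,
                        config$noise_sd * sqrt(var_factor))
  dim(v) <- c(nt, nyc, nxc)
  out <- gridded_field(md_grid(latsC, lonsC, maskC), v, times,
                       config$variable, config$units, config$depth_label)
  attr(out, "truth") <- list(bias = bias_map,
                             trend = config$scenario_trends[[scenario]],
                             var_factor = var_factor, seed = seed_m,
                             member_id = member_id, scenario = scenario)
  out
}

#' Sample synthetic point observations from a reference field
#'
#' Draws \code{n} records at grid nodes and times of the reference with
#' Gaussian observation noise. A configurable fraction is jittered off-node
#' by more than the matching tolerance to exercise rejection.
#'
#' @param reference a \code{\link{gridded_field}} (typically
#'   \code{\link{make_reference}} output).
#' @param n number of records.
#' @param noise_sd observation noise standard deviation.
#' @param jitter_frac fraction of records displaced off-node.
#' @param jitter_m displacement of jittered records in metres (default 150,
#'   beyond the 100 m matching tolerance).
#' @param depth record depth in metres (default 5, the surface product level).
#' @param seed random seed.
#' @return data.frame with columns lon, lat, depth, time, value, source and a
#'   logical \code{jittered} column.
#' @export
make_observations <- function(reference, n, noise_sd = 0.1, jitter_frac = 0,
                              jitter_m = 150, depth = 5, seed = 1) {
  if (n < 1) stop_validation("n must be >= 1")
  g <- reference$grid
  vflat <- flat_values(reference)
  ok_cells <- which(as.vector(g$mask) & colSums(!is.na(vflat)) > 0)
  set.seed(seed %% 2147483647L)
  cells <- sample(ok_cells, n, replace = TRUE)
  tidx <- sample(seq_along(reference$times), n, replace = TRUE)
  i <- (cells - 1L) %% length(g$lats) + 1L
  j <- (cells - 1L) %/% length(g$lats) + 1L
  val <- vflat[cbind(tidx, cells)] + stats::rnorm(n, sd = noise_sd)
  lat <- g$lats[i]; lon <- g$lons[j]
  jit <- seq_len(n) <= round(jitter_frac * n)
  lat[jit] <- lat[jit] + jitter_m / 111195   # ~ metres to degrees latitude
  data.frame(lon = lon, lat = lat, depth = depth,
             time = reference$times[tidx], value = val,
             source = "synthetic", jittered = jit)
}

#' Generate a full factorial synthetic ensemble suite
#'
#' One reference plus \code{n_models x realizations_per_model x scenarios}
#' members sharing deterministic components per model (bias map) with
#' independent noise per realization.
#'
#' @param config a \code{\link{synth_config}}.
#' @param n_models number of synthetic models (>= 1).
#' @param realizations_per_model realizations of each model.
#' @param scenarios scenario labels (names of \code{config$scenario_trends}).
#' @return list with \code{reference}, \code{members} (flat list of fields
#'   with \code{model}, \code{realization}, \code{scenario} attributes) and
#'   \code{truth}.
#' @export
make_ensemble_suite <- function(config, n_models = 2,
                                realizations_per_model = 2,
                                scenarios = names(config$scenario_trends)) {
  if (n_models < 1) stop_validation("n_models must be >= 1")
  if (!length(scenarios)) stop_validation("scenario list is empty")
  reference <- make_reference(config)
  members <- list()
  for (m in seq_len(n_models)) {
    # per-model bias map drawn once so realizations share it
    bias_m <- config$bias
    if (is.null(bias_m)) {
      set.seed((config$seed * 7919 + m * 104729) %% 2147483647L)
      bias_m <- stats::rnorm(1)
    }
    for (r in seq_len(realizations_per_model)) for (sc in scenarios) {
      id <- sprintf("model%d_r%d", m, r)
      fld <- make_member(config, member_id = id, scenario = sc, bias = bias_m)
      attr(fld, "model") <- sprintf("model%d", m)
      attr(fld, "realization") <- sprintf("r%d", r)
      attr(fld, "scenario") <- sc
      members[[paste(id, sc, sep = "_")]] <- fld
    }
  }
  list(reference = reference, members = members,
       truth = list(scenario_trends = config$scenario_trends[scenarios],
                    config = config))
}
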