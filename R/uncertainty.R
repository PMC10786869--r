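# Time-slice change maps, three-source uncertainty (scenario range, model
# range, internal variability), significance ratios and basin-mean series.

# Single-time-step field wrapper for static maps.
static_field <- function(template, m, when = template$times[1]) {
  gridded_field(template$grid, array(m, dim = c(1, dim(m))), when,
                template$variable, template$units, template$depth_label)
}

#' Time-slice change map
#'
#' Per-cell difference between the time-mean of a future period and the
#' time-mean of a present-day period.
#'
#' @param ensemble_mean a \code{\link{gridded_field}} spanning both periods.
#' @param future_period,present_period numeric \code{c(first_year, last_year)}.
#' @return a single-time \code{gridded_field} holding the change map.
#' @export
change_map <- function(ensemble_mean, future_period, present_period) {
  stopifnot(inherits(ensemble_mean, "gridded_field"))
  fut <- time_mean(ensemble_mean, future_period)
  pre <- time_mean(ensemble_mean, present_period)
  static_field(ensemble_mean, fut - pre)
}

#' Per-cell min-max range across fields
#'
#' @param fields non-empty list of \code{\link{gridded_field}}s on one grid
#'   and time axis (typically single-time change maps).
#' @return a \code{gridded_field}: per cell/time max - min across the list.
#' @export
minmax_range <- function(fields) {
  if (!length(fields)) stop_validation("need at least one field")
  ref <- fields[[1]]
  for (f in fields[-1])
    if (!isTRUE(all.equal(f$grid$lats, ref$grid$lats)) ||
        !isTRUE(all.equal(f$grid$lons, ref$grid$lons)))
      stop_validation("fields must share one grid")
  A <- vapply(fields, function(f) as.vector(f$values), numeric(length(ref$values)))
  A <- matrix(A, ncol = length(fields))
  rng <- apply(A, 1, function(v) if (all(is.na(v))) NA_real_ else
    diff(range(v, na.rm = TRUE)))
  out <- array(rng, dim = dim(ref$values))
  field_like(ref, out)
}

# Per-cell annual means; years with fewer than 12 non-missing months are NA.
annual_means <- function(field) {
  yrs <- year_of(field$times)
  uy <- sort(unique(yrs))
  vflat <- flat_values(field)
  cnt <- rowsum((!is.na(vflat)) + 0, yrs)
  sm <- rowsum(ifelse(is.na(vflat), 0, vflat), yrs)
  am <- sm / cnt
  am[cnt < 12] <- NA_real_
  list(years = uy, values = am)   # [year, cell]
}

#' Internal variability from detrended annual means
#'
#' Per cell: annual means of the ensemble-mean series are detrended by
#' removing a centred running mean over \code{window} years (computed only on
#' the interior where the full window fits; the first and last
#' \code{(window - 1)/2} years are dropped), and the internal variability is
#' the max minus min of the residuals.
#'
#' @param ensemble_mean a \code{\link{gridded_field}} with at least
#'   \code{window} full calendar years.
#' @param window running-mean window in years (odd; default 21).
#' @return a single-time \code{gridded_field} of internal variability (>= 0).
#' @export
internal_variability <- function(ensemble_mean, window = 21) {
  stopifnot(inherits(ensemble_mean, "gridded_field"))
  am <- annual_means(ensemble_mean)
  ny <- length(am$years)
  if (ny < window)
    stop_validation("need at least ", window, " years of data")
  run <- stats::filter(am$values, rep(1 / window, window), sides = 2)
  resid <- am$values - run
  rng <- apply(resid, 2, function(v) if (all(is.na(v))) NA_real_ else
    diff(range(v, na.rm = TRUE)))
  g <- ensemble_mean$grid
  static_field(ensemble_mean, matrix(rng, length(g$lats), length(g$lons)))
}

#' Change/uncertainty significance ratio
#'
#' Ratio of absolute change to an uncertainty range; a change is considered
#' significant where the ratio exceeds 1. Zero uncertainty with non-zero
#' change is flagged missing with a warning; 0/0 is missing.
#'
#' @param change single-time change \code{\link{gridded_field}}.
#' @param uncertainty uncertainty \code{gridded_field} on the same grid.
#' @return list with \code{ratio} (a \code{gridded_field}) and
#'   \code{significant} (logical matrix, \code{NA} where the ratio is missing).
#' @export
significance_ratio <- function(change, uncertainty) {
  if (!isTRUE(all.equal(change$grid$lats, uncertainty$grid$lats)) ||
      !isTRUE(all.equal(change$grid$lons, uncertainty$grid$lons)))
    stop_validation("change and uncertainty grids differ")
  ch <- change$values[1, , ]
  un <- uncertainty$values[1, , ]
  ratio <- abs(ch) / un
  zero_unc <- !is.na(un) & un == 0 & !is.na(ch) & ch != 0
  if (any(zero_unc)) {
    warning(sum(zero_unc), " cells have zero uncertainty with non-zero change; flagged missing")
    ratio[zero_unc] <- NA_real_
  }
  ratio[!is.na(un) & un == 0 & !is.na(ch) & ch == 0] <- NA_real_
  rf <- static_field(change, ratio)
  rf$units <- "1"
  list(ratio = rf, significant = ratio > 1)
}

#' Basin-mean time series with ensemble spread
#'
#' Unweighted spatial mean of the ensemble mean and of the 2.5/97.5 percentile
#' fields over a basin mask, per time step.
#'
#' @param stats an \code{\link{ensemble_stats}}.
#' @param mask logical matrix on the product grid (\code{TRUE} = inside basin).
#' @return an object of class \code{basin_series}: data.frame with columns
#'   \code{time}, \code{mean}, \code{lo}, \code{hi}.
#' @export
basin_series <- function(stats, mask) {
  stopifnot(inherits(stats, "ensemble_stats"))
  g <- stats$mean$grid
  mask <- as.matrix(mask)
  if (!identical(dim(mask), c(length(g$lats), length(g$lons))))
    stop_validation("mask shape must match the product grid")
  cells <- which(as.vector(mask))
  if (!length(cells)) stop_validation("basin mask is empty")
  smean <- function(f) rowMeans(flat_values(f)[, cells, drop = FALSE], na.rm = TRUE)
  out <- data.frame(time = stats$mean$times, mean = smean(stats$mean),
                    lo = smean(stats$p2_5), hi = smean(stats$p97_5))
  if (all(is.na(out$mean))) stop_validation("basin mask overlaps no valid cells")
  class(out) <- c("basin_series", "data.frame")
  out
}

#' @export
plot.basin_series <- function(x, main = "basin mean with ensemble spread", ...) {
  graphics::plot(x$time, x$mean, type = "n", xlab = "time", ylab = "value",
                 ylim = range(c(x$lo, x$hi), na.rm = TRUE), main = main, ...)
  graphics::polygon(c(x$time, rev(x$time)), c(x$lo, rev(x$hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$time, x$mean, col = "steelblue4")
  invisible(x)
}

#' Three-source uncertainty assessment for one time horizon
#'
#' Builds, for one future horizon against the present-day baseline: the
#' ensemble-mean change map of a chosen scenario; scenario uncertainty as the
#' per-cell min-max range of the per-scenario ensemble-mean changes; model
#' uncertainty as the min-max range of per-member changes under the baseline
#' scenario; internal variability from the 21-year running-mean detrended
#' annual means of the baseline-scenario ensemble mean; and the three
#' change/uncertainty ratio maps.
#'
#' @param members_by_scenario named list (scenario -> list of member
#'   \code{\link{gridded_field}}s) spanning baseline and horizon.
#' @param future_period,present_period numeric year pairs; defaults are the
#'   mid-term horizon 2041-2060 against 1995-2014.
#' @param scenario scenario whose change map is assessed; default the first.
#' @param window internal-variability running-mean window (years).
#' @return an object of class \code{change_assessment}.
#' @export
uncertainty_assessment <- function(members_by_scenario,
                                   future_period = c(2041, 2060),
                                   present_period = c(1995, 2014),
                                   scenario = names(members_by_scenario)[1],
                                   window = 21) {
  if (!length(members_by_scenario) || is.null(names(members_by_scenario)))
    stop_validation("members_by_scenario must be a named list of scenarios")
  if (!scenario %in% names(members_by_scenario))
    stop_validation("unknown scenario: ", scenario)
  ens_means <- lapply(members_by_scenario, function(mm)
    ensemble_statistics(mm)$mean)
  scen_changes <- lapply(ens_means, change_map, future_period, present_period)
  scenario_unc <- minmax_range(scen_changes)
  if (length(scen_changes) == 1)
    warning("single scenario: scenario uncertainty range is 0")
  member_changes <- lapply(members_by_scenario[[scenario]], change_map,
                           future_period, present_period)
  model_unc <- minmax_range(member_changes)
  internal <- internal_variability(ens_means[[scenario]], window = window)
  change <- scen_changes[[scenario]]
  structure(list(change = change,
                 scenario_unc = scenario_unc, model_unc = model_unc,
                 internal_var = internal,
                 ratio_scenario = significance_ratio(change, scenario_unc)$ratio,
                 ratio_model = significance_ratio(change, model_unc)$ratio,
                 ratio_internal = significance_ratio(change, internal)$ratio,
                 scenario = scenario, horizon = future_period,
                 baseline = present_period),
            class = "change_assessment")
}

#' @export
print.change_assessment <- function(x, ...) {
  med <- function(f) stats::median(f$values, na.rm = TRUE)
  cat(sprintf("<change_assessment> scenario %s, horizon %d-%d vs %d-%d\n",
              x$scenario, x$horizon[1], x$horizon[2], x$baseline[1], x$baseline[2]))
  cat(sprintf("  median change %.4g %s; median uncertainty: scenario %.4g, model %.4g, internal %.4g\n",
              med(x$change), x$change$units, med(x$scenario_unc),
              med(x$model_unc), med(x$internal_var)))
  sig <- function(r) mean(r$values > 1, na.rm = TRUE)
  cat(sprintf("  fraction significant (ratio > 1): scenario %.2f, model %.2f, internal %.2f\n",
              sig(x$ratio_scenario), sig(x$ratio_model), sig(x$ratio_internal)))
  invisible(x)
}
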