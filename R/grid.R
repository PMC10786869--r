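#' Rectilinear latitude-longitude grid
#'
#' A light container for the rectilinear grids used throughout the package:
#' strictly increasing cell-centre coordinates plus a land/ocean mask
#' (\code{TRUE} = ocean). Longitudes are normalised to [-180, 180); domains
#' crossing the antimeridian are not supported.
#'
#' @param lats numeric, degrees north, strictly increasing.
#' @param lons numeric, degrees east, strictly increasing after normalisation.
#' @param mask logical matrix \code{length(lats) x length(lons)}; default all ocean.
#' @return an object of class \code{md_grid}.
#' @export
md_grid <- function(lats, lons, mask = NULL) {
  lons <- ((lons + 180) %% 360) - 180
  if (length(lats) < 1 || length(lons) < 1)
    stop_validation("grid needs at least one point per axis")
  if (is.unsorted(lats, strictly = TRUE))
    stop_validation("lats must be strictly increasing")
  if (is.unsorted(lons, strictly = TRUE))
    stop_validation("lons must be strictly increasing (antimeridian crossing unsupported)")
  if (is.null(mask)) mask <- matrix(TRUE, length(lats), length(lons))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), c(length(lats), length(lons))))
    stop_validation("mask shape must be length(lats) x length(lons)")
  res <- if (length(lats) > 1) stats::median(diff(lats)) else
    if (length(lons) > 1) stats::median(diff(lons)) else NA_real_
  structure(list(lats = as.numeric(lats), lons = as.numeric(lons),
                 resolution = res, mask = mask),
            class = "md_grid")
}

#' @export
print.md_grid <- function(x, ...) {
  cat(sprintf("<md_grid> %d x %d (lat x lon), ~%.4g deg, %d ocean cells\n",
              length(x$lats), length(x$lons), x$resolution, sum(x$mask)))
  invisible(x)
}

#' Monthly gridded field at one depth level
#'
#' Values are stored as a 3-d array \code{[time, lat, lon]}. Land cells
#' (mask \code{FALSE}) are always \code{NA}; ocean cells may be \code{NA}
#' where the source product has gaps (e.g. an unresolved coastline), which is
#' what \code{\link{idw_extrapolate}} fills.
#'
#' @param grid an \code{\link{md_grid}}.
#' @param values numeric array \code{[time, lat, lon]}.
#' @param times \code{Date} vector, first-of-month, strictly increasing with
#'   monthly spacing.
#' @param variable variable name (e.g. \code{"temperature"}).
#' @param units units string, non-empty.
#' @param depth_label one of \code{"surface"}, \code{"subsurface"},
#'   \code{"seafloor"}, or a free label.
#' @return an object of class \code{gridded_field}.
#' @export
gridded_field <- function(grid, values, times, variable = "temperature",
                          units = "degC", depth_label = "surface") {
  stopifnot(inherits(grid, "md_grid"))
  times <- as.Date(times)
  if (length(times) > 1) {
    if (is.unsorted(times, strictly = TRUE))
      stop_validation("times must be strictly increasing")
    ym <- year_of(times) * 12L + month_of(times)
    if (any(diff(ym) != 1L))
      stop_validation("times must have monthly spacing")
  }
  values <- array(as.numeric(values),
                  dim = c(length(times), length(grid$lats), length(grid$lons)))
  if (!nzchar(units)) stop_validation("units must be non-empty")
  # enforce land = missing
  land <- which(!grid$mask)
  if (length(land)) {
    nt <- length(times)
    idx <- rep(land - 1L, each = nt) * nt + seq_len(nt)
    values[idx] <- NA_real_
  }
  structure(list(grid = grid, values = values, times = times,
                 variable = variable, units = units, depth_label = depth_label),
            class = "gridded_field")
}

# Rebuild a field with new values (and optionally new times/grid).
field_like <- function(field, values, times = field$times, grid = field$grid) {
  gridded_field(grid, values, times, field$variable, field$units, field$depth_label)
}

#' @export
print.gridded_field <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<gridded_field> %s [%s] at %s: %d months (%s..%s), %d x %d grid, range [%.4g, %.4g]\n",
              x$variable, x$units, x$depth_label, length(x$times),
              format(x$times[1], "%Y-%m"), format(x$times[length(x$times)], "%Y-%m"),
              length(x$grid$lats), length(x$grid$lons), rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.gridded_field <- function(x, period = NULL, main = NULL, ...) {
  m <- time_mean(x, period)
  graphics::image(x$grid$lons, x$grid$lats, t(m),
                  xlab = "longitude", ylab = "latitude",
                  main = main %||% sprintf("%s (%s), time mean", x$variable, x$units), ...)
  invisible(x)
}

#' Restrict a field to a calendar-year period
#' @param field a \code{gridded_field}.
#' @param period numeric \code{c(first_year, last_year)} inclusive, or
#'   \code{NULL} for no restriction.
#' @return a \code{gridded_field}.
#' @export
subset_period <- function(field, period) {
  keep <- in_period(field$times, period)
  if (!any(keep)) stop_validation("period selects no time steps")
  field_like(field, field$values[keep, , , drop = FALSE], times = field$times[keep])
}

#' Per-cell time mean over a period
#' @inheritParams subset_period
#' @return numeric matrix \code{[lat, lon]}.
#' @export
time_mean <- function(field, period = NULL) {
  keep <- in_period(field$times, period)
  if (!any(keep)) stop_validation("period selects no time steps")
  apply(field$values[keep, , , drop = FALSE], c(2, 3), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
}

# Extract one cell as a monthly series.
cell_series <- function(field, i, j) {
  md_series(field$times, field$values[, i, j])
}

#' Monthly scalar series
#' @param times Date vector, strictly increasing.
#' @param values numeric, \code{NA} allowed.
#' @return an object of class \code{md_series}.
#' @export
md_series <- function(times, values) {
  times <- as.Date(times)
  if (length(times) != length(values))
    stop_validation("times and values lengths differ")
  if (length(times) > 1 && is.unsorted(times, strictly = TRUE))
    stop_validation("times must be strictly increasing")
  structure(list(times = times, values = as.numeric(values)), class = "md_series")
}

#' @export
print.md_series <- function(x, ...) {
  cat(sprintf("<md_series> %d months (%s..%s), %d missing\n", length(x$times),
              format(x$times[1], "%Y-%m"), format(x$times[length(x$times)], "%Y-%m"),
              sum(is.na(x$values))))
  invisible(x)
}

#' Multi-level depth stack with bathymetry
#'
#' @param grid an \code{\link{md_grid}}.
#' @param depth_levels metres, strictly increasing (positive down).
#' @param values numeric array \code{[time, depth, lat, lon]}.
#' @param bathymetry metres per cell, matrix \code{[lat, lon]}; \code{NA} = land.
#' @param times Date vector as in \code{\link{gridded_field}}.
#' @param variable,units,depth_label metadata as in \code{\link{gridded_field}}.
#' @return an object of class \code{depth_stack}.
#' @export
depth_stack <- function(grid, depth_levels, values, bathymetry, times,
                        variable = "temperature", units = "degC",
                        depth_label = "stack") {
  stopifnot(inherits(grid, "md_grid"))
  if (is.unsorted(depth_levels, strictly = TRUE))
    stop_validation("depth_levels must be strictly increasing")
  times <- as.Date(times)
  values <- array(as.numeric(values),
                  dim = c(length(times), length(depth_levels),
                          length(grid$lats), length(grid$lons)))
  bathymetry <- as.matrix(bathymetry)
  if (!identical(dim(bathymetry), c(length(grid$lats), length(grid$lons))))
    stop_validation("bathymetry shape must match grid")
  # Levels below the local bathymetry are retained in storage: model levels
  # commonly extend below the reference bathymetry and the seafloor
  # extraction interpolates into them. Products at a fixed depth z mask
  # bathymetry-shallower cells at extraction time (see interp_to_depth).
  structure(list(grid = grid, depth_levels = as.numeric(depth_levels),
                 values = values, bathymetry = bathymetry, times = times,
                 variable = variable, units = units, depth_label = depth_label),
            class = "depth_stack")
}
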