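# Detrended quantile mapping (DQM): bias correction at coarse resolution and
# statistical downscaling onto a fine reference grid.
#
# The per-cell procedure is the standard six-step DQM:
#   1. a scaling factor equalises the historical model mean with the reference
#      mean (offset in additive mode, ratio in multiplicative mode);
#   2. both historical series are detrended (OLS linear trend, mean-preserving);
#   3. quantile-wise adjustment factors are taken between the detrended
#      reference and detrended model quantiles;
#   4. the scaling factor is applied to the projection;
#   5. the projection is detrended with its own trend and each value is
#      corrected by the adjustment at its quantile (linear interpolation
#      between trained quantiles, constant beyond the tails);
#   6. the projection's trend is added back, so the model's long-term trend
#      passes through the correction unchanged.

# ---- internal numeric cores (hot path: plain vectors, no containers) ----

.trend_fit <- function(t, v) {
  ok <- !is.na(v)
  n <- sum(ok)
  if (n < 2) stop_validation("trend fit needs >= 2 non-missing values")
  tt <- t[ok]; vv <- v[ok]
  tbar <- mean(tt); vbar <- mean(vv)
  sxx <- sum((tt - tbar)^2)
  if (sxx == 0) stop_validation("trend fit needs >= 2 distinct times")
  slope <- sum((tt - tbar) * (vv - vbar)) / sxx
  list(slope = slope, tbar = tbar, vbar = vbar, n = n)
}

# Detrending is anchored at `level` (default: the series' own mean, i.e.
# mean-preserving). When a transform is applied to a projection, the anchor is
# the training-period level instead, so that historical values of the scaled
# projection land on the trained quantiles and future values are corrected at
# the probability of their detrended anomaly — the standard DQM construction.
.detrend <- function(tf, t, v, mode, level = tf$vbar) {
  fit <- tf$vbar + tf$slope * (t - tf$tbar)
  if (mode == "additive") return(v - fit + level)
  if (any(fit <= 0, na.rm = TRUE))
    stop_domain("multiplicative detrending hit a non-positive trend line")
  v * level / fit
}

.retrend <- function(tf, t, v, mode, level = tf$vbar) {
  fit <- tf$vbar + tf$slope * (t - tf$tbar)
  if (mode == "additive") return(v + fit - level)
  v * fit / level
}

# Piecewise-linear adjustment lookup with constant tails; collapses duplicate
# model quantiles (ties in small samples) by averaging their adjustments.
.map_adjust <- function(mq, adj, x) {
  ux <- unique(mq)
  if (length(ux) == 1) {
    out <- rep(mean(adj), length(x))
    out[is.na(x)] <- NA_real_
    return(out)
  }
  ua <- vapply(split(adj, match(mq, ux)), mean, numeric(1))
  stats::approx(ux, ua, xout = x, rule = 2)$y
}

.dqm_fit_core <- function(tm, vm, tr, vr, n_quantiles, mode) {
  okm <- !is.na(vm); okr <- !is.na(vr)
  if (sum(okm) < 2 || sum(okr) < 2)
    stop_validation("DQM training needs >= 2 non-missing values in each series")
  if (mode == "multiplicative" && (any(vm[okm] <= 0) || any(vr[okr] <= 0)))
    stop_domain("multiplicative DQM requires strictly positive training data")
  scaling <- if (mode == "additive") mean(vr[okr]) - mean(vm[okm])
             else mean(vr[okr]) / mean(vm[okm])
  vms <- if (mode == "additive") vm + scaling else vm * scaling
  tfm <- .trend_fit(tm, vms)
  tfr <- .trend_fit(tr, vr)
  dm <- .detrend(tfm, tm, vms, mode)
  dr <- .detrend(tfr, tr, vr, mode)
  probs <- dqm_probs(n_quantiles)
  mq <- equantile(dm[!is.na(dm)], probs)
  rq <- equantile(dr[!is.na(dr)], probs)
  adj <- if (mode == "additive") rq - mq else rq / mq
  list(mode = mode, scaling = scaling, probs = probs,
       model_quantiles = mq, adjustments = adj, level = tfm$vbar)
}

.dqm_apply_core <- function(fit, t, v, clamp_zero = FALSE) {
  vs <- if (fit$mode == "additive") v + fit$scaling else v * fit$scaling
  ok <- !is.na(vs)
  tf <- if (sum(ok) >= 2 && length(unique(t[ok])) >= 2) .trend_fit(t, vs)
        else list(slope = 0, tbar = 0, vbar = fit$level)  # too short to detrend
  dv <- .detrend(tf, t, vs, fit$mode, level = fit$level)
  a <- .map_adjust(fit$model_quantiles, fit$adjustments, dv)
  dc <- if (fit$mode == "additive") dv + a else dv * a
  out <- .retrend(tf, t, dc, fit$mode, level = fit$level)
  if (clamp_zero) out <- pmax(out, 0)
  out
}

# ---- user-facing estimator interface ----

#' Fit an ordinary-least-squares linear trend to a monthly series
#'
#' Time enters as fractional years at mid-month; the fit is the standard OLS
#' line, reported as slope (units per year) plus the centroid
#' (\code{tbar}, \code{vbar}) it passes through. At least 24 months are
#' recommended for a stable climate trend; the hard requirement is two
#' distinct non-missing time points.
#'
#' @param series an \code{\link{md_series}}.
#' @return an object of class \code{trend_model} with elements \code{slope},
#'   \code{intercept}, \code{tbar}, \code{vbar}, \code{n}.
#' @export
fit_linear_trend <- function(series) {
  stopifnot(inherits(series, "md_series"))
  tf <- .trend_fit(frac_year(series$times), series$values)
  structure(list(slope = tf$slope, intercept = tf$vbar - tf$slope * tf$tbar,
                 tbar = tf$tbar, vbar = tf$vbar, n = tf$n),
            class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("<trend_model> slope %.6g per year, intercept %.6g (n = %d)\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}

#' Train a detrended quantile-mapping transform
#'
#' Learns the scaling factor and quantile-wise adjustment factors that map the
#' (detrended) historical model distribution onto the (detrended) historical
#' reference distribution. Use \code{\link{predict.dqm}} (or its alias
#' \code{\link{apply_dqm}}) to correct a projection.
#'
#' @param model_hist historical model series (\code{\link{md_series}}).
#' @param ref_hist historical reference series on the same window.
#' @param n_quantiles number of equally spaced quantile probabilities
#'   \code{(i - 0.5)/n}; default 100.
#' @param mode \code{"additive"} (temperature, salinity, pH) or
#'   \code{"multiplicative"} (strictly positive variables such as oxygen and
#'   chlorophyll).
#' @param month calendar month 1..12 to train on that month's values only, or
#'   \code{"all"} to pool the year.
#' @param training_window numeric \code{c(first_year, last_year)}; default is
#'   the full overlap of the two series.
#' @return an object of class \code{dqm}.
#' @export
fit_dqm <- function(model_hist, ref_hist, n_quantiles = 100,
                    mode = c("additive", "multiplicative"), month = "all",
                    training_window = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model_hist, "md_series"), inherits(ref_hist, "md_series"))
  if (n_quantiles < 2) stop_validation("n_quantiles must be >= 2")
  if (is.null(training_window)) {
    training_window <- c(max(min(year_of(model_hist$times)), min(year_of(ref_hist$times))),
                         min(max(year_of(model_hist$times)), max(year_of(ref_hist$times))))
    if (training_window[1] > training_window[2])
      stop_validation("model and reference series do not overlap in time")
  }
  pick <- function(s) {
    keep <- in_period(s$times, training_window)
    if (!identical(month, "all")) keep <- keep & month_of(s$times) == as.integer(month)
    list(t = frac_year(s$times)[keep], v = s$values[keep])
  }
  m <- pick(model_hist); r <- pick(ref_hist)
  fit <- .dqm_fit_core(m$t, m$v, r$t, r$v, n_quantiles, mode)
  structure(c(fit, list(month = month, training_window = training_window,
                        n_train = c(model = sum(!is.na(m$v)), ref = sum(!is.na(r$v))))),
            class = "dqm")
}

#' @export
print.dqm <- function(x, ...) {
  cat(sprintf("<dqm> %s mode, month %s, %d quantiles, training %d-%d\n",
              x$mode, as.character(x$month), length(x$probs),
              x$training_window[1], x$training_window[2]))
  cat(sprintf("  scaling %.6g; adjustments range [%.4g, %.4g]\n",
              x$scaling, min(x$adjustments), max(x$adjustments)))
  invisible(x)
}

#' @export
summary.dqm <- function(object, ...) {
  q <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  data.frame(prob = q,
             model_quantile = .map_adjust(object$probs, object$model_quantiles, q),
             adjustment = .map_adjust(object$probs, object$adjustments, q))
}

#' @export
plot.dqm <- function(x, ...) {
  graphics::plot(x$probs, x$adjustments, type = "l",
                 xlab = "probability", ylab = "adjustment",
                 main = sprintf("DQM adjustment factors (%s)", x$mode), ...)
  invisible(x)
}

#' Apply a trained DQM transform to a projection series
#'
#' Scales the projection, removes its own OLS trend, corrects each value by
#' the adjustment at its quantile (constant beyond the trained tails), and
#' adds the trend back, so the projection's trend is preserved. Missing values
#' stay missing; output times equal input times.
#'
#' @param object a fitted \code{\link{fit_dqm}} transform.
#' @param newdata the projection \code{\link{md_series}}; when the transform
#'   was trained on a single calendar month, all of \code{newdata} must fall
#'   in that month.
#' @param clamp_zero clamp the corrected series at zero (for additive-mode
#'   corrections of strictly positive variables).
#' @param ... unused.
#' @return the corrected \code{md_series}.
#' @export
predict.dqm <- function(object, newdata, clamp_zero = FALSE, ...) {
  stopifnot(inherits(newdata, "md_series"))
  if (!identical(object$month, "all") &&
      any(month_of(newdata$times) != as.integer(object$month)))
    stop_validation("projection months do not match the transform's calendar month")
  if (object$mode == "multiplicative" && any(newdata$values <= 0, na.rm = TRUE))
    stop_domain("multiplicative transform applied to non-positive values")
  out <- .dqm_apply_core(object, frac_year(newdata$times), newdata$values,
                         clamp_zero = clamp_zero)
  md_series(newdata$times, out)
}

#' @rdname predict.dqm
#' @param transform a fitted \code{dqm} object.
#' @param projection the projection \code{md_series}.
#' @export
apply_dqm <- function(transform, projection, clamp_zero = FALSE) {
  predict(transform, projection, clamp_zero = clamp_zero)
}

# ---- gridded drivers ----

# Correct one full cell series with per-month (or pooled) transforms. The
# correction is applied separately to the historical segment (up to the end
# of the training window) and to the projection segment: the projected
# forcing makes the full trajectory piecewise-linear, so detrending each
# application segment by its own OLS line keeps the linear-trend assumption
# of DQM valid on both sides of the scenario divergence.
.correct_cell <- function(t_model, v_model, months_model, t_ref, v_ref,
                          months_ref, train_m, train_r, n_quantiles, mode,
                          per_month, clamp_zero, train_end = Inf) {
  out <- rep(NA_real_, length(v_model))
  segment <- t_model > train_end + 1   # fractional years; +1: end of last year
  groups <- if (per_month) 1:12 else list(1:12)
  for (g in groups) {
    im <- months_model %in% g
    ir <- months_ref %in% g
    fit <- .dqm_fit_core(t_model[im & train_m], v_model[im & train_m],
                         t_ref[ir & train_r], v_ref[ir & train_r],
                         n_quantiles, mode)
    for (seg in unique(segment[im])) {
      k <- im & segment == seg
      out[k] <- .dqm_apply_core(fit, t_model[k], v_model[k], clamp_zero)
    }
  }
  out
}

#' Bias-correct a coarse model field against a coarse reference
#'
#' Fits and applies an independent DQM transform per ocean cell (and, by
#' default, per calendar month) between the model and reference historical
#' series, then corrects the model's full time span. Land cells are untouched.
#'
#' @param model coarse-grid \code{\link{gridded_field}} covering the training
#'   window and any projection span.
#' @param ref_coarse reference \code{gridded_field} on the identical grid.
#' @param n_quantiles,mode,training_window as in \code{\link{fit_dqm}}.
#' @param per_month fit 12 per-calendar-month transforms per cell (default)
#'   rather than one pooled transform.
#' @param clamp_zero clamp corrected values at zero.
#' @return the corrected \code{gridded_field} on the model's grid and times.
#' @export
bias_correct <- function(model, ref_coarse, n_quantiles = 100,
                         mode = c("additive", "multiplicative"),
                         per_month = TRUE, training_window = NULL,
                         clamp_zero = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "gridded_field"), inherits(ref_coarse, "gridded_field"))
  if (!isTRUE(all.equal(model$grid$lats, ref_coarse$grid$lats)) ||
      !isTRUE(all.equal(model$grid$lons, ref_coarse$grid$lons)))
    stop_validation("model and reference grids differ")
  if (is.null(training_window))
    training_window <- c(max(min(year_of(model$times)), min(year_of(ref_coarse$times))),
                         min(max(year_of(model$times)), max(year_of(ref_coarse$times))))
  tm <- frac_year(model$times); mm <- month_of(model$times)
  tr <- frac_year(ref_coarse$times); mr <- month_of(ref_coarse$times)
  train_m <- in_period(model$times, training_window)
  train_r <- in_period(ref_coarse$times, training_window)
  if (!any(train_m) || !any(train_r))
    stop_validation("training window absent from model or reference")
  out <- model$values
  for (i in seq_along(model$grid$lats)) for (j in seq_along(model$grid$lons)) {
    if (!model$grid$mask[i, j]) next
    vm <- model$values[, i, j]
    vr <- ref_coarse$values[, i, j]
    if (all(is.na(vm)) || all(is.na(vr))) next
    out[, i, j] <- .correct_cell(tm, vm, mm, tr, vr, mr, train_m, train_r,
                                 n_quantiles, mode, per_month, clamp_zero,
                                 train_end = training_window[2])
  }
  field_like(model, out)
}

#' Statistically downscale a bias-corrected coarse field to a fine grid
#'
#' The coarse field is first regridded bilinearly to the fine reference grid
#' and coastal gaps are filled by IDW extrapolation; then an independent DQM
#' transform is trained per fine cell between the regridded coarse historical
#' series and the fine reference historical series, and applied to the full
#' regridded series. The fine reference is never degraded, so its sub-grid
#' spatial variability is transferred onto the projection while the coarse
#' model's trend is preserved.
#'
#' @param bias_corrected_coarse coarse \code{\link{gridded_field}} (output of
#'   \code{\link{bias_correct}}) covering training + projection span.
#' @param ref_fine fine-grid reference \code{gridded_field} covering the
#'   training window.
#' @param n_quantiles,mode,per_month,training_window,clamp_zero as in
#'   \code{\link{bias_correct}}.
#' @param n_neighbors IDW neighbours for the coastal fill.
#' @return a \code{gridded_field} on the fine grid over the full time span.
#' @export
downscale <- function(bias_corrected_coarse, ref_fine, n_quantiles = 100,
                      mode = c("additive", "multiplicative"), per_month = TRUE,
                      training_window = NULL, clamp_zero = FALSE,
                      n_neighbors = 8) {
  mode <- match.arg(mode)
  stopifnot(inherits(bias_corrected_coarse, "gridded_field"),
            inherits(ref_fine, "gridded_field"))
  if (is.null(training_window))
    training_window <- c(max(min(year_of(bias_corrected_coarse$times)), min(year_of(ref_fine$times))),
                         min(max(year_of(bias_corrected_coarse$times)), max(year_of(ref_fine$times))))
  if (!any(in_period(ref_fine$times, training_window)))
    stop_validation("training window absent from the fine reference")
  coarse_on_fine <- regrid_bilinear(bias_corrected_coarse, ref_fine$grid)
  coarse_on_fine <- idw_extrapolate(coarse_on_fine, n_neighbors = n_neighbors)
  tm <- frac_year(coarse_on_fine$times); mm <- month_of(coarse_on_fine$times)
  tr <- frac_year(ref_fine$times); mr <- month_of(ref_fine$times)
  train_m <- in_period(coarse_on_fine$times, training_window)
  train_r <- in_period(ref_fine$times, training_window)
  if (!any(train_m)) stop_validation("training window absent from the coarse field")
  out <- coarse_on_fine$values
  g <- ref_fine$grid
  for (i in seq_along(g$lats)) for (j in seq_along(g$lons)) {
    if (!g$mask[i, j]) next
    vm <- coarse_on_fine$values[, i, j]
    vr <- ref_fine$values[, i, j]
    if (all(is.na(vm)) || all(is.na(vr))) next
    out[, i, j] <- .correct_cell(tm, vm, mm, tr, vr, mr, train_m, train_r,
                                 n_quantiles, mode, per_month, clamp_zero,
                                 train_end = training_window[2])
  }
  field_like(coarse_on_fine, out)
}
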