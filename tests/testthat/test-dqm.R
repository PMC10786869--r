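# Detrended quantile mapping: trend fitting, transform training, application,
# and the gridded bias-correction / downscaling drivers.

test_that("OLS trend fitting recovers exact and noisy linear trends", {
  times <- mt(2000, 2005)
  v <- 0.1 * (seq_along(times) - 1)          # 0.1 per month
  tm <- fit_linear_trend(md_series(times, v))
  expect_equal(tm$slope, 1.2, tolerance = 1e-12)

  expect_equal(fit_linear_trend(md_series(times, rep(3, length(times))))$slope, 0)

  set.seed(5)
  noise <- rnorm(length(times), sd = 0.5)
  vy <- 2 + 0.3 * (seq_along(times) - 0.5) / 12 + noise
  tmn <- fit_linear_trend(md_series(times, vy))
  # oracle: lm() standard error on the same fractional-year regressor
  ty <- 2000 + (seq_along(times) - 0.5) / 12
  fit <- lm(vy ~ ty)
  se <- summary(fit)$coefficients["ty", "Std. Error"]
  expect_equal(tmn$slope, unname(coef(fit)["ty"]), tolerance = 1e-10)
  expect_lt(abs(tmn$slope - 0.3), 2 * se)

  expect_error(fit_linear_trend(md_series(times, rep(NA_real_, length(times)))),
               class = "md_validation_error")
})

test_that("training on identical series yields a null transform", {
  s <- toy_series(seed = 2)
  tr <- fit_dqm(s, s, n_quantiles = 50)
  expect_equal(tr$scaling, 0)
  expect_equal(max(abs(tr$adjustments)), 0)
  out <- apply_dqm(tr, s)
  expect_lt(max(abs(out$values - s$values)), 1e-6)
})

test_that("a constant offset is learned as the scaling factor", {
  ref <- toy_series(seed = 3)
  model <- md_series(ref$times, ref$values + 2)
  tr <- fit_dqm(model, ref, n_quantiles = 50)
  expect_equal(tr$scaling, -2, tolerance = 1e-12)
  # oracle: empirical quantiles of the shifted series differ by exactly 2,
  # so after scaling the adjustments vanish
  expect_lt(max(abs(tr$adjustments)), 1e-12)
  out <- apply_dqm(tr, model)
  expect_equal(out$values, ref$values, tolerance = 1e-9)
})

test_that("a multiplicative factor is learned as a ratio scaling", {
  ref <- toy_series(mean = 10, sd = 0.5, seed = 4)
  model <- md_series(ref$times, 2 * ref$values)
  tr <- fit_dqm(model, ref, n_quantiles = 50, mode = "multiplicative")
  expect_equal(tr$scaling, 0.5, tolerance = 1e-12)
  expect_equal(max(abs(tr$adjustments - 1)), 0, tolerance = 1e-9)
  out <- apply_dqm(tr, model)
  expect_equal(out$values, ref$values, tolerance = 1e-8)
  expect_error(fit_dqm(md_series(ref$times, ref$values - 20), ref,
                       mode = "multiplicative"),
               class = "md_domain_error")
})

test_that("the offset transform removes the offset from any trended input and preserves its slope", {
  ref <- toy_series(seed = 6)
  model <- md_series(ref$times, ref$values + 2)
  tr <- fit_dqm(model, ref, n_quantiles = 50)
  for (slope_m in c(0.05, -0.02, 0.3)) {
    n <- length(ref$times)
    proj <- md_series(ref$times, model$values + slope_m * (seq_len(n) - 1) / 12)
    out <- apply_dqm(tr, proj)
    expect_equal(out$values, proj$values - 2, tolerance = 1e-9)
    s_in <- fit_linear_trend(proj)$slope
    s_out <- fit_linear_trend(out)$slope
    expect_lt(abs(s_out - s_in) / abs(s_in), 1e-9)
  }
})

test_that("values beyond the trained tails get the constant boundary adjustment", {
  set.seed(7)
  times <- mt(1995, 2004)
  ref <- md_series(times, rnorm(length(times), 10, 1))
  model <- md_series(times, rnorm(length(times), 12, 2))
  tr <- fit_dqm(model, ref, n_quantiles = 20)
  nq <- length(tr$adjustments)
  # an extreme outlier detrends far beyond the trained quantiles, so its
  # correction is the constant boundary adjustment (additive mode satisfies
  # corrected = scaled input + adjustment(detrended value) identically)
  for (sign in c(-1, 1)) {
    proj <- model
    proj$values[60] <- proj$values[60] + sign * 50
    out <- apply_dqm(tr, proj)
    got <- out$values[60] - proj$values[60] - tr$scaling
    expect_equal(got, if (sign < 0) tr$adjustments[1] else tr$adjustments[nq],
                 tolerance = 1e-12)
  }
})

test_that("quantile mapping is monotone non-decreasing in the input value", {
  set.seed(8)
  times <- mt(1995, 2004)
  ref <- md_series(times, rnorm(length(times), 10, 1))
  model <- md_series(times, 11 + 1.6 * rnorm(length(times)))
  tr <- fit_dqm(model, ref, n_quantiles = 30)
  x <- sort(runif(200, min(tr$model_quantiles) - 2, max(tr$model_quantiles) + 2))
  # constant-time mapping via the adjustment lookup (fixed transform)
  a <- marindown:::.map_adjust(tr$model_quantiles, tr$adjustments, x)
  expect_true(all(diff(x + a) >= -1e-12))
})

test_that("the scaled historical model mean equals the reference mean (step-1 contract)", {
  ref <- toy_series(seed = 9)
  model <- md_series(ref$times, ref$values * 1.3 + 4)
  tr <- fit_dqm(model, ref, n_quantiles = 50)
  expect_equal(mean(model$values + tr$scaling), mean(ref$values),
               tolerance = 1e-14)
  trm <- fit_dqm(md_series(ref$times, abs(model$values)),
                 md_series(ref$times, abs(ref$values)),
                 n_quantiles = 50, mode = "multiplicative")
  expect_equal(mean(abs(model$values)) * trm$scaling, mean(abs(ref$values)),
               tolerance = 1e-12)
})

test_that("quantile mapping matches an independent empirical-CDF oracle on short series", {
  set.seed(10)
  for (n_mon in c(36, 48)) {
    times <- mt(2000, 2000 + n_mon / 12 - 1)
    n <- length(times)
    ref <- md_series(times, rnorm(n, 8, 1.5))
    model <- md_series(times, rnorm(n, 10, 1))
    nq <- n
    tr <- fit_dqm(model, ref, n_quantiles = nq)
    out <- apply_dqm(tr, model)

    # oracle: scale, detrend with lm(), push each value through the
    # piecewise-linear empirical CDF of the detrended model and the inverse
    # CDF of the detrended reference (probability-space route), re-add trend
    ty <- 2000 + (seq_len(n) - 0.5) / 12
    vs <- model$values + tr$scaling
    fm <- lm(vs ~ ty); fr <- lm(ref$values ~ ty)
    dm <- vs - fitted(fm) + mean(vs)
    dr <- ref$values - fitted(fr) + mean(ref$values)
    probs <- (seq_len(nq) - 0.5) / nq
    mq <- unname(quantile(dm, probs, type = 7))
    rq <- unname(quantile(dr, probs, type = 7))
    oracle <- vapply(dm, function(v) {
      if (v <= mq[1]) return(v + (rq[1] - mq[1]))
      if (v >= mq[nq]) return(v + (rq[nq] - mq[nq]))
      p <- approx(mq, probs, v, ties = "ordered")$y
      approx(probs, rq, p)$y
    }, numeric(1))
    oracle <- unname(oracle + fitted(fm) - mean(vs))
    expect_equal(out$values, oracle, tolerance = 1e-9)
  }
})

test_that("per-month transforms refuse projections from other months", {
  s <- toy_series(seed = 11)
  jan_model <- md_series(s$times[marindown:::month_of(s$times) == 1],
                         s$values[marindown:::month_of(s$times) == 1])
  tr <- fit_dqm(s, s, n_quantiles = 10, month = 1)
  expect_error(apply_dqm(tr, s), class = "md_validation_error")
  expect_silent(apply_dqm(tr, jan_model))
})

test_that("gridded bias correction reduces to fit+apply on a single cell and skips land", {
  g1 <- md_grid(54.25, 2.25)
  times_m <- mt(1993, 2030)
  times_r <- mt(1993, 2014)
  set.seed(12)
  vm <- 12 + 0.02 * seq_along(times_m) / 12 + rnorm(length(times_m), sd = 0.5)
  vr <- 10 + 0.01 * seq_along(times_r) / 12 + rnorm(length(times_r), sd = 0.4)
  fm <- gridded_field(g1, array(vm, c(length(times_m), 1, 1)), times_m)
  fr <- gridded_field(g1, array(vr, c(length(times_r), 1, 1)), times_r)
  bc <- bias_correct(fm, fr, n_quantiles = 20, per_month = FALSE)

  tr <- fit_dqm(md_series(times_m, vm), md_series(times_r, vr),
                n_quantiles = 20, training_window = c(1993, 2014))
  hist_idx <- marindown:::year_of(times_m) <= 2014
  manual <- c(apply_dqm(tr, md_series(times_m[hist_idx], vm[hist_idx]))$values,
              apply_dqm(tr, md_series(times_m[!hist_idx], vm[!hist_idx]))$values)
  expect_equal(as.numeric(bc$values), manual, tolerance = 1e-12)

  # all-land mask passes through untouched
  gl <- md_grid(c(54, 55), c(2, 3), matrix(FALSE, 2, 2))
  fl <- gridded_field(gl, array(NA_real_, c(length(times_m), 2, 2)), times_m)
  rl <- gridded_field(gl, array(NA_real_, c(length(times_r), 2, 2)), times_r)
  expect_identical(bias_correct(fl, rl)$values, fl$values)
  # grid mismatch
  expect_error(bias_correct(fm, gridded_field(md_grid(10, 10),
                                              array(vr, c(length(times_r), 1, 1)),
                                              times_r)),
               class = "md_validation_error")
})

test_that("bias correction aligns detrended quantiles with the reference", {
  cfg <- synth_config(nx = 12, ny = 12, coarsen_factor = 6, bias = 1.5,
                      var_factor = 1.3, land_frac = 0, seed = 21)
  ref <- make_reference(cfg)
  mem <- make_member(cfg, "m1", "ssp245")
  refC <- coarsen(ref, 6)
  bc <- bias_correct(mem, refC)
  hw <- cfg$hist_years
  keep <- marindown:::in_period(bc$times, hw)
  probs <- seq(0.05, 0.95, by = 0.05)
  for (cell in list(c(1, 1), c(2, 2))) {
    vb <- bc$values[keep, cell[1], cell[2]]
    vr <- refC$values[, cell[1], cell[2]]
    db <- residuals(lm(vb ~ seq_along(vb)))
    dr <- residuals(lm(vr ~ seq_along(vr)))
    qb <- quantile(db, probs); qr <- quantile(dr, probs)
    # Monte-Carlo quantile standard error of the reference sample (bootstrap)
    set.seed(99)
    B <- vapply(1:200, function(b) quantile(sample(dr, replace = TRUE), probs),
                numeric(length(probs)))
    # both sides carry sampling error of the same scale
    se <- sqrt(2) * apply(B, 1, sd)
    expect_true(all(abs(qb - qr) < 2 * se))
  }
})

test_that("downscaling is the identity when the fine reference equals the regridded coarse field", {
  cfg <- synth_config(nx = 12, ny = 12, coarsen_factor = 3, land_frac = 0,
                      noise_sd = 0.3, seed = 13)
  ref <- make_reference(cfg)
  memC <- coarsen(ref, 3)
  reg <- idw_extrapolate(regrid_bilinear(memC, ref$grid))
  out <- downscale(memC, reg)
  expect_lt(max(abs(out$values - reg$values), na.rm = TRUE), 1e-6)
})

test_that("downscaling reconstructs the stationary fine-scale pattern", {
  cfg <- synth_config(nx = 18, ny = 18, coarsen_factor = 6, bias = 1,
                      land_frac = 0, seed = 14)
  ref <- make_reference(cfg)
  mem <- make_member(cfg, "m1", "ssp585")
  bc <- bias_correct(mem, coarsen(ref, 6))
  ds <- downscale(bc, ref)
  hw <- cfg$hist_years
  cm <- time_mean(ds, hw); cr <- time_mean(ref, hw)
  ok <- !is.na(cm) & !is.na(cr)
  expect_gt(cor(cm[ok], cr[ok]), 0.99)
  # projection trend at a fine cell tracks the coarse cell's trend within 5%
  pidx <- marindown:::year_of(ds$times) >= cfg$hist_years[2] + 1
  fy <- marindown:::frac_year(ds$times)
  s_in <- marindown:::.trend_fit(fy[pidx], mem$values[pidx, 2, 2])$slope
  s_out <- marindown:::.trend_fit(fy[pidx], ds$values[pidx, 8, 8])$slope
  expect_lt(abs(s_out - s_in) / abs(s_in), 0.05)
})
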