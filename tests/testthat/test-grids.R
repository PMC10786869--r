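# Spatial plumbing: bilinear regridding, coarsening, IDW extrapolation,
# depth interpolation and bottom extraction.

test_that("bilinear regridding preserves constants and reproduces bilinear functions exactly", {
  src <- toy_grid(11, 11, res = 0.5)
  tgt <- md_grid(src$lats[1] + 0.25 + 0:9 * 0.5, src$lons[1] + 0.25 + 0:9 * 0.5)
  times <- mt(2000, 2000, 1, 2)
  fc <- toy_field(src, times, function(t, la, lo) 7.5)
  rc <- regrid_bilinear(fc, tgt)
  expect_equal(max(abs(rc$values - 7.5)), 0)

  fb <- toy_field(src, times, function(t, la, lo) 2 * la + 3 * lo)
  rb <- regrid_bilinear(fb, tgt)
  expected <- outer(2 * tgt$lats, rep(1, 10)) + outer(rep(1, 10), 3 * tgt$lons)
  expect_equal(rb$values[1, , ], expected, tolerance = 1e-12)
  # never outside the source's valid range
  expect_gte(min(rb$values), min(fb$values))
  expect_lte(max(rb$values), max(fb$values))
})

test_that("bilinear value at a 2x2 cell centre is the equal-weight corner mean", {
  src <- md_grid(c(54, 55), c(2, 3))
  v <- array(0, c(1, 2, 2)); v[1, 2, 2] <- 4
  f <- gridded_field(src, v, as.Date("2000-01-01"))
  tgt <- md_grid(54.5, 2.5)
  out <- regrid_bilinear(f, tgt)
  expect_equal(as.numeric(out$values), 1)
})

test_that("regridding renormalises over valid corners and propagates all-missing corners", {
  mask <- matrix(TRUE, 2, 2); mask[1, 1] <- FALSE
  src <- md_grid(c(54, 55), c(2, 3), mask)
  v <- array(c(NA, 2, 4, 6), c(1, 2, 2))  # [lat, lon] filled column-major
  f <- gridded_field(src, v, as.Date("2000-01-01"))
  out <- regrid_bilinear(f, md_grid(54.5, 2.5))
  expect_equal(as.numeric(out$values), mean(c(2, 4, 6)))
  # all corners missing -> missing
  mask0 <- matrix(FALSE, 2, 2)
  src0 <- md_grid(c(54, 55), c(2, 3), mask0)
  f0 <- gridded_field(src0, array(NA_real_, c(1, 2, 2)), as.Date("2000-01-01"))
  out0 <- regrid_bilinear(f0, md_grid(54.5, 2.5))
  expect_true(is.na(out0$values[1, 1, 1]))
})

test_that("regridding rejects disjoint domains and bad grids", {
  src <- toy_grid(4, 4)
  f <- toy_field(src, as.Date("2000-01-01"), function(t, la, lo) 1)
  far <- md_grid(10 + 1:4, 100 + 1:4)
  expect_error(regrid_bilinear(f, far), class = "md_domain_error")
  expect_error(md_grid(c(2, 1), 1:3), class = "md_validation_error")
})

test_that("coarsening averages blocks, handles missing children, and rejects non-divisible shapes", {
  g <- toy_grid(4, 4, res = 0.25)
  times <- as.Date("2000-01-01")
  fu <- toy_field(g, times, function(t, la, lo) 3.25)
  expect_equal(max(abs(coarsen(fu, 2)$values - 3.25)), 0)

  # checkerboard {0,1;1,0} averages to 0.5
  g2 <- toy_grid(2, 2)
  v <- array(c(0, 1, 1, 0), c(1, 2, 2))
  fc <- gridded_field(g2, v, times)
  expect_equal(as.numeric(coarsen(fc, 2)$values), 0.5)

  # block {1,2;3,6} -> 3
  v2 <- array(c(1, 2, 3, 6), c(1, 2, 2))
  f2 <- gridded_field(g2, v2, times)
  expect_equal(as.numeric(coarsen(f2, 2)$values), 3)

  # one missing child -> mean of the rest; all-missing -> missing
  mask <- matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2)
  fm <- gridded_field(md_grid(g2$lats, g2$lons, mask),
                      array(c(NA, 2, 3, 6), c(1, 2, 2)), times)
  expect_equal(as.numeric(coarsen(fm, 2)$values), mean(c(2, 3, 6)))
  fall <- gridded_field(md_grid(g2$lats, g2$lons, matrix(FALSE, 2, 2)),
                        array(NA_real_, c(1, 2, 2)), times)
  expect_true(is.na(as.numeric(coarsen(fall, 2)$values)))

  expect_error(coarsen(toy_field(toy_grid(3, 3), times), 2),
               class = "md_validation_error")
})

test_that("coarsen after nearest-neighbour refine is the identity on valid cells", {
  set.seed(11)
  g <- toy_grid(3, 5, res = 0.5)
  f <- toy_field(g, mt(2000, 2000, 1, 3),
                 function(t, la, lo) sin(la) + cos(lo) + t)
  for (fac in c(2, 3)) {
    back <- coarsen(refine_nearest(f, fac), fac)
    expect_equal(back$values, f$values, tolerance = 1e-12)
    expect_equal(back$grid$lats, g$lats, tolerance = 1e-12)
  }
})

test_that("IDW fills gaps with inverse-square great-circle weights", {
  # equal neighbours -> that constant
  g <- toy_grid(3, 3)
  v <- array(5, c(1, 3, 3)); v[1, 2, 2] <- NA
  f <- gridded_field(g, v, as.Date("2000-01-01"))
  expect_equal(idw_extrapolate(f)$values[1, 2, 2], 5)

  # two sources on one meridian at distance ratio 1:2, values 0 and 3 -> 0.6
  gm <- md_grid(c(50, 51, 52), c(3, 4), matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 3, 2))
  vv <- array(NA_real_, c(1, 3, 2))
  vv[1, 2, 1] <- 0   # 1 degree away from target (50, 3)
  vv[1, 3, 1] <- 3   # 2 degrees away
  fm <- gridded_field(gm, vv, as.Date("2000-01-01"))
  out <- idw_extrapolate(fm)
  expect_equal(out$values[1, 1, 1], 0.6, tolerance = 1e-12)

  # a target coincident with a valid source keeps that value untouched
  expect_equal(out$values[1, 2, 1], 0)
  expect_error(idw_extrapolate(gridded_field(g, array(NA_real_, c(1, 3, 3)),
                                             as.Date("2000-01-01"))),
               class = "md_domain_error")
})

test_that("IDW matches an independent brute-force oracle and stays within neighbour bounds", {
  set.seed(42)
  # irregular spacing so no two source distances tie exactly
  nlat <- 6; nlon <- 6
  g <- md_grid(54 + cumsum(runif(nlat, 0.2, 0.6)),
               2 + cumsum(runif(nlon, 0.2, 0.6)))
  v <- array(rnorm(36), c(1, nlat, nlon))
  holes <- cbind(sample(nlat, 8, TRUE), sample(nlon, 8, TRUE))
  for (k in seq_len(nrow(holes))) v[1, holes[k, 1], holes[k, 2]] <- NA
  f <- gridded_field(g, v, as.Date("2000-01-01"))
  out <- idw_extrapolate(f, n_neighbors = 8, power = 2)
  src <- which(!is.na(v[1, , ]), arr.ind = TRUE)
  for (k in seq_len(nrow(holes))) {
    i <- holes[k, 1]; j <- holes[k, 2]
    if (!is.na(v[1, i, j])) next  # duplicate sampled hole positions
    d <- oracle_haversine(g$lons[j], g$lats[i], g$lons[src[, 2]], g$lats[src[, 1]])
    nn <- order(d)[1:8]
    w <- d[nn]^-2
    vals <- v[1, , ][src[nn, , drop = FALSE]]
    expect_equal(out$values[1, i, j], sum(w * vals) / sum(w), tolerance = 1e-12)
    expect_gte(out$values[1, i, j], min(vals))
    expect_lte(out$values[1, i, j], max(vals))
    expect_equal(sum(w / sum(w)), 1)
  }
})

test_that("depth interpolation is linear, exact at levels, and refuses extrapolation", {
  g <- toy_grid(2, 2)
  levels <- c(0, 10, 50)
  v <- array(NA_real_, c(1, 3, 2, 2))   # value == depth at each level
  for (k in 1:3) v[1, k, , ] <- levels[k]
  st <- depth_stack(g, levels, v, matrix(100, 2, 2), as.Date("2000-01-01"))
  expect_equal(max(abs(interp_to_depth(st, 5)$values - 5)), 0)
  expect_equal(max(abs(interp_to_depth(st, 10)$values - 10)), 0)
  expect_equal(max(abs(interp_to_depth(st, 30)$values - 30)), 0)
  expect_error(interp_to_depth(st, 60), class = "md_domain_error")
  # cells shallower than z are missing
  bathy <- matrix(c(20, 100, 100, 100), 2, 2)
  st2 <- depth_stack(g, levels, v, bathy, as.Date("2000-01-01"))
  out <- interp_to_depth(st2, 30)
  expect_true(is.na(out$values[1, 1, 1]))
  expect_equal(out$values[1, 2, 2], 30)
})

test_that("bottom extraction interpolates to bathymetry and clamps at the deepest valid level", {
  g <- toy_grid(2, 2)
  levels <- c(0, 10, 50)
  v <- array(NA_real_, c(1, 3, 2, 2))
  for (k in 1:3) v[1, k, , ] <- levels[k]
  bathy <- matrix(c(30, 10, 200, NA), 2, 2)
  st <- depth_stack(g, levels, v, bathy, as.Date("2000-01-01"))
  bot <- extract_bottom(st)
  expect_equal(bot$values[1, 1, 1], 30)    # interpolated on the 10..50 segment
  expect_equal(bot$values[1, 2, 1], 10)    # bathymetry exactly at a level
  expect_equal(bot$values[1, 1, 2], 50)    # deeper than the stack: clamped
  expect_true(is.na(bot$values[1, 2, 2]))  # land column
  expect_identical(bot$depth_label, "seafloor")
})
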