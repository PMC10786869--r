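# Spatial and vertical plumbing: regridding, coarsening, coastal IDW
# extrapolation, depth interpolation, bottom extraction.

EARTH_RADIUS_M <- 6371000

# Great-circle distance (m) from one point to many, spherical Earth.
gc_dist <- function(lon1, lat1, lons, lats) {
  geosphere::distHaversine(c(lon1, lat1), cbind(lons, lats), r = EARTH_RADIUS_M)
}

# Flatten [time, lat, lon] to [time, cell] (cell = lat-major as in R arrays).
flat_values <- function(field) {
  v <- field$values
  dim(v) <- c(dim(v)[1], dim(v)[2] * dim(v)[3])
  v
}

# A source cell is treated as valid when it has any non-missing value;
# validity is assumed time-invariant (mask-driven), per the data model.
valid_cells <- function(vflat) colSums(!is.na(vflat)) > 0

# Bracketing index and weight along one axis; NA index where x is outside.
axis_weights <- function(src, tgt) {
  k <- findInterval(tgt, src)
  lo <- k
  lo[tgt < src[1] | tgt > src[length(src)]] <- NA_integer_
  lo[!is.na(lo) & lo == length(src)] <- length(src) - 1L   # exact top endpoint
  if (length(src) == 1) { lo[tgt == src] <- 1L }
  w <- rep(NA_real_, length(tgt))
  ok <- !is.na(lo)
  if (length(src) > 1)
    w[ok] <- (tgt[ok] - src[lo[ok]]) / (src[lo[ok] + 1L] - src[lo[ok]])
  else w[ok] <- 0
  list(lo = lo, w = w)
}

#' Bilinear regridding to a target grid
#'
#' Interpolates each target node bilinearly within the enclosing source cell.
#' If some of the four enclosing source nodes are missing, weights are
#' renormalised over the valid ones; a node whose four enclosing nodes are all
#' missing (or which falls outside the source node hull) becomes missing.
#' Land cells of the target mask stay missing.
#'
#' @param field a \code{\link{gridded_field}}.
#' @param target an \code{\link{md_grid}}.
#' @return a \code{gridded_field} on \code{target}.
#' @export
regrid_bilinear <- function(field, target) {
  stopifnot(inherits(field, "gridded_field"), inherits(target, "md_grid"))
  src <- field$grid
  if (length(src$lats) < 2 || length(src$lons) < 2)
    stop_validation("source grid needs at least 2 points per axis")
  if (max(target$lats) < min(src$lats) || min(target$lats) > max(src$lats) ||
      max(target$lons) < min(src$lons) || min(target$lons) > max(src$lons))
    stop_domain("source and target domains are disjoint")
  ala <- axis_weights(src$lats, target$lats)
  alo <- axis_weights(src$lons, target$lons)
  nt <- length(field$times)
  nlatT <- length(target$lats); nlonT <- length(target$lons)
  nlatS <- length(src$lats)
  vs <- flat_values(field)
  vv <- valid_cells(vs)
  vs0 <- vs; vs0[is.na(vs0)] <- 0
  num <- matrix(0, nt, nlatT * nlonT)
  den <- matrix(0, nt, nlatT * nlonT)
  # corner offsets: (di, dj) in {0,1}^2 with bilinear weights
  tgt_i <- rep(seq_len(nlatT), times = nlonT)
  tgt_j <- rep(seq_len(nlonT), each = nlatT)
  li <- ala$lo[tgt_i]; wi <- ala$w[tgt_i]
  lj <- alo$lo[tgt_j]; wj <- alo$w[tgt_j]
  inside <- !is.na(li) & !is.na(lj)
  for (di in 0:1) for (dj in 0:1) {
    w <- (if (di == 0) 1 - wi else wi) * (if (dj == 0) 1 - wj else wj)
    scell <- (lj + dj - 1L) * nlatS + (li + di)
    use <- which(inside & w > 0 & vv[scell])
    if (!length(use)) next
    sc <- scell[use]
    vsub <- vs[, sc, drop = FALSE]
    ok <- !is.na(vsub)
    vsub[!ok] <- 0
    num[, use] <- num[, use] + sweep(vsub, 2, w[use], `*`)
    den[, use] <- den[, use] + sweep(ok + 0, 2, w[use], `*`)
  }
  out <- num / den
  out[den == 0] <- NA_real_
  dim(out) <- c(nt, nlatT, nlonT)
  field_like(field, out, grid = target)
}

#' Block-mean coarsening
#'
#' Each coarse cell is the unweighted mean of its \code{factor x factor}
#' non-missing children; an all-missing block is missing. The coarse grid's
#' coordinates are block-mean coordinates and a coarse cell is ocean if any
#' child is ocean.
#'
#' @param field a \code{\link{gridded_field}}.
#' @param factor positive integer dividing both axis lengths.
#' @return a \code{gridded_field} on the coarsened grid.
#' @export
coarsen <- function(field, factor) {
  g <- field$grid
  nlat <- length(g$lats); nlon <- length(g$lons)
  factor <- as.integer(factor)
  if (factor < 1 || nlat %% factor != 0 || nlon %% factor != 0)
    stop_validation("coarsening factor must divide both axis lengths")
  bi <- (seq_len(nlat) - 1L) %/% factor + 1L
  bj <- (seq_len(nlon) - 1L) %/% factor + 1L
  block <- rep(bi, times = nlon) + (rep(bj, each = nlat) - 1L) * max(bi)
  vs <- flat_values(field)
  vs0 <- vs; vs0[is.na(vs0)] <- 0
  num <- t(rowsum(t(vs0), block))
  cnt <- t(rowsum(t(!is.na(vs)) + 0, block))
  out <- num / cnt
  out[cnt == 0] <- NA_real_
  latsC <- as.numeric(tapply(g$lats, bi, mean))
  lonsC <- as.numeric(tapply(g$lons, bj, mean))
  maskC <- t(rowsum(t(rowsum(g$mask + 0, bi)), bj)) > 0
  gC <- md_grid(latsC, lonsC, maskC)
  dim(out) <- c(length(field$times), length(latsC), length(lonsC))
  field_like(field, out, grid = gC)
}

#' Nearest-neighbour refinement (upsampling)
#'
#' Replicates each cell into a \code{factor x factor} block on a finer grid;
#' the companion of \code{\link{coarsen}} used in round-trip checks.
#'
#' @inheritParams coarsen
#' @return a \code{gridded_field} on the refined grid.
#' @export
refine_nearest <- function(field, factor) {
  g <- field$grid
  factor <- as.integer(factor)
  if (factor < 1) stop_validation("factor must be >= 1")
  step_lat <- if (length(g$lats) > 1) stats::median(diff(g$lats)) else 1
  step_lon <- if (length(g$lons) > 1) stats::median(diff(g$lons)) else 1
  off <- (seq_len(factor) - (factor + 1) / 2) / factor
  latsF <- as.numeric(sapply(g$lats, function(x) x + off * step_lat))
  lonsF <- as.numeric(sapply(g$lons, function(x) x + off * step_lon))
  ii <- rep(seq_along(g$lats), each = factor)
  jj <- rep(seq_along(g$lons), each = factor)
  maskF <- g$mask[ii, jj, drop = FALSE]
  gF <- md_grid(latsF, lonsF, maskF)
  out <- field$values[, ii, jj, drop = FALSE]
  field_like(field, out, grid = gF)
}

#' Inverse-distance-weighted extrapolation
#'
#' Fills each missing target node with the weighted average of the
#' \code{n_neighbors} nearest valid source points, weights proportional to
#' great-circle distance raised to \code{-power}. A target node coincident
#' with a valid source point takes that value; nodes already valid are left
#' untouched; land cells of the target mask stay missing. Fewer than
#' \code{n_neighbors} valid points means all available are used.
#'
#' @param field source \code{\link{gridded_field}}.
#' @param target an \code{\link{md_grid}}; defaults to the field's own grid
#'   (gap filling).
#' @param n_neighbors number of nearest valid source points (default 8).
#' @param power exponent of the inverse-distance weights (default 2).
#' @return a \code{gridded_field} on \code{target}.
#' @export
idw_extrapolate <- function(field, target = field$grid, n_neighbors = 8, power = 2) {
  stopifnot(inherits(field, "gridded_field"), inherits(target, "md_grid"))
  src <- field$grid
  nt <- length(field$times)
  vs <- flat_values(field)
  vv <- which(valid_cells(vs))
  if (!length(vv)) stop_domain("no valid source points for IDW extrapolation")
  same_grid <- isTRUE(all.equal(src$lats, target$lats)) &&
    isTRUE(all.equal(src$lons, target$lons))
  nlatT <- length(target$lats); nlonT <- length(target$lons)
  ncellT <- nlatT * nlonT
  out <- matrix(NA_real_, nt, ncellT)
  if (same_grid) out[] <- vs
  src_lat <- rep(src$lats, times = length(src$lons))[vv]
  src_lon <- rep(src$lons, each = length(src$lats))[vv]
  tgt_lat <- rep(target$lats, times = nlonT)
  tgt_lon <- rep(target$lons, each = nlatT)
  ocean <- as.vector(target$mask)
  todo <- which(ocean & colSums(!is.na(out)) == 0)
  for (cell in todo) {
    d <- gc_dist(tgt_lon[cell], tgt_lat[cell], src_lon, src_lat)
    if (any(d == 0)) {
      out[, cell] <- vs[, vv[which(d == 0)[1]]]
      next
    }
    k <- min(n_neighbors, length(d))
    nn <- order(d)[seq_len(k)]
    w <- d[nn]^(-power)
    vsub <- vs[, vv[nn], drop = FALSE]
    ok <- !is.na(vsub)
    vsub[!ok] <- 0
    den <- as.vector((ok + 0) %*% w)
    val <- as.vector(vsub %*% w) / den
    val[den == 0] <- NA_real_
    out[, cell] <- val
  }
  out[, !ocean] <- NA_real_
  dim(out) <- c(nt, nlatT, nlonT)
  field_like(field, out, grid = target)
}

#' Linear interpolation of a depth stack to a fixed depth
#'
#' @param stack a \code{\link{depth_stack}}.
#' @param z depth in metres, within the stack's level range.
#' @return a \code{gridded_field} at depth \code{z}; cells shallower than
#'   \code{z} (bathymetry < z) are missing.
#' @export
interp_to_depth <- function(stack, z) {
  stopifnot(inherits(stack, "depth_stack"))
  zl <- stack$depth_levels
  if (z < zl[1] || z > zl[length(zl)])
    stop_domain(sprintf("depth %g outside level range [%g, %g]; no extrapolation", z, zl[1], zl[length(zl)]))
  k <- findInterval(z, zl)
  if (zl[k] == z) {
    out <- stack$values[, k, , ]
  } else {
    w <- (z - zl[k]) / (zl[k + 1] - zl[k])
    out <- (1 - w) * stack$values[, k, , ] + w * stack$values[, k + 1, , ]
  }
  nt <- length(stack$times)
  out <- array(out, dim = c(nt, length(stack$grid$lats), length(stack$grid$lons)))
  shallow <- which(is.na(stack$bathymetry) | stack$bathymetry < z)
  if (length(shallow))
    out[rep(shallow - 1L, each = nt) * nt + seq_len(nt)] <- NA_real_
  gridded_field(stack$grid, out, stack$times, stack$variable, stack$units,
                sprintf("%gm", z))
}

#' Extract the seafloor (bottom) field from a depth stack
#'
#' Interpolates each water column linearly to its bathymetric depth. Where the
#' bathymetry exceeds the column's deepest valid level, the value is clamped
#' to that deepest level; columns with no valid values (land) are missing.
#'
#' @param stack a \code{\link{depth_stack}}.
#' @return a \code{gridded_field} labelled \code{"seafloor"}.
#' @export
extract_bottom <- function(stack) {
  stopifnot(inherits(stack, "depth_stack"))
  zl <- stack$depth_levels
  nt <- length(stack$times)
  nlat <- length(stack$grid$lats); nlon <- length(stack$grid$lons)
  out <- array(NA_real_, dim = c(nt, nlat, nlon))
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    col <- stack$values[, , i, j, drop = FALSE]
    dim(col) <- c(nt, length(zl))
    ok <- colSums(!is.na(col)) > 0
    if (!any(ok)) next
    b <- stack$bathymetry[i, j]
    if (is.na(b)) next
    zok <- zl[ok]
    z <- min(max(b, zok[1]), zok[length(zok)])
    ks <- which(ok)
    kk <- findInterval(z, zok)
    if (zok[kk] == z || kk == length(zok)) {
      out[, i, j] <- col[, ks[kk]]
    } else {
      w <- (z - zok[kk]) / (zok[kk + 1] - zok[kk])
      out[, i, j] <- (1 - w) * col[, ks[kk]] + w * col[, ks[kk + 1]]
    }
  }
  gridded_field(stack$grid, out, stack$times, stack$variable, stack$units, "seafloor")
}
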