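# Equal-weight ensemble product: mean, spread and percentile fields.

#' Equal-weight ensemble statistics
#'
#' Combines downscaled member fields into the ensemble product: per cell and
#' time step the unweighted mean, the population standard deviation, and the
#' 2.5, 50 and 97.5 percentiles (linear interpolation between order
#' statistics). Every member carries equal weight — realizations of the same
#' model are not down-weighted. A cell/time missing in any member is missing
#' in all outputs.
#'
#' @param members list of \code{\link{gridded_field}}s sharing grid, times,
#'   variable and units.
#' @param member_ids optional character labels; defaults to names of
#'   \code{members} or \code{member_1..n}.
#' @return an object of class \code{ensemble_stats} with fields \code{mean},
#'   \code{std}, \code{p2_5}, \code{p50}, \code{p97_5} (each a
#'   \code{gridded_field}), \code{n_members} and \code{member_ids}.
#' @export
ensemble_statistics <- function(members, member_ids = NULL) {
  if (!length(members)) stop_validation("need at least one member")
  lapply(members, function(m) stopifnot(inherits(m, "gridded_field")))
  ref <- members[[1]]
  for (m in members[-1]) {
    if (!isTRUE(all.equal(m$grid$lats, ref$grid$lats)) ||
        !isTRUE(all.equal(m$grid$lons, ref$grid$lons)) ||
        !identical(m$times, ref$times) ||
        !identical(m$variable, ref$variable) || !identical(m$units, ref$units))
      stop_validation("members must share grid, times, variable and units")
  }
  if (is.null(member_ids))
    member_ids <- names(members) %||% paste0("member_", seq_along(members))
  if (is.null(names(members)) && length(member_ids) == length(members))
    member_ids <- as.character(member_ids)
  n <- length(members)
  M <- vapply(members, function(m) as.vector(m$values),
              numeric(length(ref$values)))
  M <- matrix(M, ncol = n)
  bad <- rowSums(is.na(M)) > 0
  mu <- rowMeans(M)
  sd_pop <- sqrt(pmax(rowMeans((M - mu)^2), 0))
  # vectorised row sort for order-statistic percentiles
  S <- matrix(M[order(row(M), M)], nrow = nrow(M), byrow = TRUE)
  pct <- function(p) {
    if (n == 1) return(S[, 1])
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    S[, lo] * (1 - (h - lo)) + S[, hi] * (h - lo)
  }
  shape <- dim(ref$values)
  wrap <- function(v) { v[bad] <- NA_real_; dim(v) <- shape; field_like(ref, v) }
  structure(list(mean = wrap(mu), std = wrap(sd_pop), p2_5 = wrap(pct(0.025)),
                 p50 = wrap(pct(0.5)), p97_5 = wrap(pct(0.975)),
                 n_members = n, member_ids = member_ids),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("<ensemble_stats> %d members (%s)\n", x$n_members,
              paste(x$member_ids, collapse = ", ")))
  print(x$mean)
  invisible(x)
}

#' Write an ensemble product to a compressed NetCDF file
#'
#' Stores the five statistic fields as \code{<variable>_mean|std|p2_5|p50|p97_5}
#' in one CF-style, zlib-compressed NetCDF4 file, carrying member ids and
#' provenance (training window, software version, configuration hash) as
#' global attributes. The file round-trips losslessly through
#' \code{\link{read_product}}.
#'
#' @param stats an \code{\link{ensemble_stats}}.
#' @param path output file path.
#' @param provenance named list of global attributes; missing standard keys
#'   are defaulted with a warning-free note in the file.
#' @return the path, invisibly.
#' @export
write_product <- function(stats, path, provenance = list()) {
  stopifnot(inherits(stats, "ensemble_stats"))
  fields <- list(mean = stats$mean, std = stats$std, p2_5 = stats$p2_5,
                 p50 = stats$p50, p97_5 = stats$p97_5)
  prov <- provenance
  prov$member_ids <- paste(stats$member_ids, collapse = ",")
  prov$n_members <- stats$n_members
  if (is.null(prov$software)) prov$software <-
    paste0("marindown ", as.character(utils::packageVersion("marindown")))
  if (is.null(prov$config_hash)) prov$config_hash <- "unspecified"
  write_fields_nc(fields, path, name_prefix = paste0(stats$mean$variable, "_"),
                  global_attrs = prov)
  invisible(path)
}

#' Read an ensemble product written by \code{\link{write_product}}
#' @param path NetCDF file path.
#' @return an \code{ensemble_stats} object.
#' @export
read_product <- function(path) {
  got <- read_fields_nc(path)
  att <- attr(got, "global_attrs")
  ids <- strsplit(att$member_ids %||% "", ",")[[1]]
  nm <- names(got)
  pick <- function(suffix) got[[grep(paste0("_", suffix, "$"), nm)[1]]]
  st <- list(mean = pick("mean"), std = pick("std"), p2_5 = pick("p2_5"),
             p50 = pick("p50"), p97_5 = pick("p97_5"),
             n_members = as.integer(att$n_members %||% length(ids)),
             member_ids = ids)
  base_var <- sub("_mean$", "", nm[grep("_mean$", nm)[1]])
  for (k in c("mean", "std", "p2_5", "p50", "p97_5")) st[[k]]$variable <- base_var
  structure(st, class = "ensemble_stats")
}
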