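# CF-style NetCDF reading and writing (ncdf4). One depth level per file;
# coordinates latitude/longitude/time, _FillValue honoured, units required.

NC_FILL <- 1e35
NC_TIME_UNITS <- "days since 1900-01-01"

nc_time_encode <- function(times) as.numeric(times - as.Date("1900-01-01"))
nc_time_decode <- function(x, units = NC_TIME_UNITS) {
  origin <- sub("days since ", "", units)
  as.Date(round(x), origin = as.Date(substr(origin, 1, 10)))
}

# Write a named list of gridded_fields sharing one grid/time axis.
write_fields_nc <- function(fields, path, name_prefix = "", global_attrs = list(),
                            compression = 5) {
  f1 <- fields[[1]]
  g <- f1$grid
  dl_lon <- ncdf4::ncdim_def("longitude", "degrees_east", g$lons)
  dl_lat <- ncdf4::ncdim_def("latitude", "degrees_north", g$lats)
  dl_time <- ncdf4::ncdim_def("time", NC_TIME_UNITS, nc_time_encode(f1$times),
                              unlim = FALSE, calendar = "standard")
  vars <- lapply(names(fields), function(nm) {
    ncdf4::ncvar_def(paste0(name_prefix, nm), fields[[nm]]$units,
                     list(dl_lon, dl_lat, dl_time), missval = NC_FILL,
                     longname = paste(fields[[nm]]$variable, nm),
                     prec = "double", compression = compression)
  })
  vmask <- ncdf4::ncvar_def("mask", "1", list(dl_lon, dl_lat), missval = NULL,
                            longname = "ocean mask (1 = ocean)", prec = "integer",
                            compression = compression)
  nc <- tryCatch(ncdf4::nc_create(path, c(vars, list(vmask)), force_v4 = TRUE),
                 error = function(e) stop("cannot create NetCDF at ", path, ": ",
                                          conditionMessage(e)))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (k in seq_along(fields)) {
    v <- aperm(fields[[k]]$values, c(3, 2, 1))    # [lon, lat, time]
    ncdf4::ncvar_put(nc, vars[[k]], v)
    ncdf4::ncatt_put(nc, vars[[k]], "depth_label", fields[[k]]$depth_label)
    ncdf4::ncatt_put(nc, vars[[k]], "standard_variable", fields[[k]]$variable)
  }
  ncdf4::ncvar_put(nc, vmask, t(g$mask) + 0L)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8")
  for (nm in names(global_attrs))
    ncdf4::ncatt_put(nc, 0, nm, as.character(global_attrs[[nm]]))
  invisible(path)
}

read_fields_nc <- function(path) {
  if (!file.exists(path)) stop("NetCDF file not found: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  lons <- as.numeric(ncdf4::ncvar_get(nc, "longitude"))
  lats <- as.numeric(ncdf4::ncvar_get(nc, "latitude"))
  tdim <- nc$dim$time
  times <- nc_time_decode(as.numeric(tdim$vals), tdim$units)
  mask <- NULL
  if ("mask" %in% names(nc$var))
    mask <- t(matrix(ncdf4::ncvar_get(nc, "mask"), length(lons), length(lats))) > 0
  g <- md_grid(lats, lons, mask)
  out <- list()
  for (nm in names(nc$var)) {
    if (nm == "mask") next
    units <- ncdf4::ncatt_get(nc, nm, "units")
    if (!units$hasatt) stop("variable ", nm, " lacks a units attribute")
    v <- ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)
    v <- array(v, dim = c(length(lons), length(lats), length(times)))
    dl <- ncdf4::ncatt_get(nc, nm, "depth_label")
    sv <- ncdf4::ncatt_get(nc, nm, "standard_variable")
    out[[nm]] <- gridded_field(g, aperm(v, c(3, 2, 1)), times,
                               variable = if (sv$hasatt) sv$value else nm,
                               units = units$value,
                               depth_label = if (dl$hasatt) dl$value else "surface")
  }
  ga <- ncdf4::ncatt_get(nc, 0)
  attr(out, "global_attrs") <- ga
  out
}

#' Write a gridded field to a CF-style NetCDF file
#'
#' @param field a \code{\link{gridded_field}}.
#' @param path output path (NetCDF4, zlib-compressed).
#' @param global_attrs named list of extra global attributes.
#' @return the path, invisibly.
#' @export
write_field <- function(field, path, global_attrs = list()) {
  fields <- stats::setNames(list(field), field$variable)
  write_fields_nc(fields, path, global_attrs = global_attrs)
  invisible(path)
}

#' Read a gridded field from a NetCDF file written by \code{\link{write_field}}
#'
#' @param path NetCDF file path.
#' @param variable variable name to read; default: the first non-coordinate
#'   variable.
#' @return a \code{gridded_field}.
#' @export
read_field <- function(path, variable = NULL) {
  got <- read_fields_nc(path)
  if (is.null(variable)) return(got[[1]])
  got[[variable]]
}
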