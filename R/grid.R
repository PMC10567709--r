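#' Define a regular global latitude-longitude grid
#'
#' The raster lattice every field in the package lives on. The default is the
#' 0.5 degree CRU-style grid (360 x 720) with cell centers at
#' -89.75 ... 89.75 and -179.75 ... 179.75; tests and the synthetic world use
#' a coarse 5 degree grid (\code{grid_spec(36, 72, 5)}).
#'
#' @param n_lat number of latitude bands (default 360).
#' @param n_lon number of longitude columns (default 720).
#' @param resolution cell size in degrees (default 0.5).
#' @param lat_origin,lon_origin southern / western grid edge in degrees.
#' @return an object of class \code{grid_spec} with center coordinate vectors
#'   \code{lat} (south to north) and \code{lon} (west to east).
#' @examples
#' sp <- grid_spec()
#' range(sp$lat)  # -89.75 89.75
#' coarse <- grid_spec(36, 72, 5)
#' @export
grid_spec <- function(n_lat = 360L, n_lon = 720L, resolution = 0.5,
                      lat_origin = -90, lon_origin = -180) {
  n_lat <- as.integer(n_lat)
  n_lon <- as.integer(n_lon)
  if (abs(n_lat * resolution - 180) > 1e-9) {
    stop("n_lat * resolution must equal 180 degrees")
  }
  if (abs(n_lon * resolution - 360) > 1e-9) {
    stop("n_lon * resolution must equal 360 degrees")
  }
  lat <- lat_origin + resolution * (seq_len(n_lat) - 0.5)
  lon <- lon_origin + resolution * (seq_len(n_lon) - 0.5)
  if (any(lat <= -90) || any(lat >= 90)) stop("cell centers outside [-90, 90]")
  structure(
    list(n_lat = n_lat, n_lon = n_lon, resolution = resolution,
         lat_origin = lat_origin, lon_origin = lon_origin,
         lat = lat, lon = lon),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d at %g deg, lat %g..%g, lon %g..%g\n",
              x$n_lat, x$n_lon, x$resolution,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

same_spec <- function(a, b) {
  isTRUE(all.equal(a[c("n_lat", "n_lon", "resolution",
                       "lat_origin", "lon_origin")],
                   b[c("n_lat", "n_lon", "resolution",
                       "lat_origin", "lon_origin")]))
}

#' Create a single-variable gridded field
#'
#' A field is a numeric matrix (rows = latitude bands south to north,
#' columns = longitude west to east) on a \code{\link{grid_spec}}, with a
#' units string. Ocean / no-data cells are \code{NA} — never 0 — so zeros
#' remain meaningful fluxes; \code{NA} cells are excluded from all
#' aggregations.
#'
#' @param values numeric matrix of dim \code{c(n_lat, n_lon)} or a scalar to
#'   recycle.
#' @param spec a \code{\link{grid_spec}}.
#' @param units non-empty unit string (e.g. \code{"g m-2 yr-1"}).
#' @param name short variable name used when writing NetCDF.
#' @return an object of class \code{grid_field}.
#' @export
grid_field <- function(values, spec, units, name = "field") {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L) {
    values <- matrix(as.numeric(values), spec$n_lat, spec$n_lon)
  }
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_lat, spec$n_lon))) {
    stop(sprintf("values must be %d x %d, got %d x %d",
                 spec$n_lat, spec$n_lon, nrow(values), ncol(values)))
  }
  if (!is.character(units) || length(units) != 1L || !nzchar(units)) {
    stop("units must be a non-empty string")
  }
  storage.mode(values) <- "double"
  structure(list(spec = spec, values = values, units = units, name = name),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<grid_field '%s'> %d x %d [%s]; %d missing; range %s\n",
              x$name, nrow(x$values), ncol(x$values), x$units,
              sum(is.na(x$values)),
              if (length(v)) paste(signif(range(v), 4), collapse = " .. ")
              else "all missing"))
  invisible(x)
}

#' Spherical area of the cells in one latitude band
#'
#' Area of a single grid cell in band \code{band} (1 = southernmost), from
#' the spherical formula A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))
#' with R = 6371 km. All cells in a band share the same area.
#'
#' @param band integer band index (vectorised), 1-based from the south.
#' @param spec a \code{\link{grid_spec}}.
#' @return cell area(s) in km^2.
#' @examples
#' sp <- grid_spec()
#' cell_area(181, sp)  # 0-0.5N band, ~3091 km2
#' @export
cell_area <- function(band, spec) {
  band <- as.integer(band)
  if (any(band < 1L) || any(band > spec$n_lat)) {
    stop("band index out of range")
  }
  deg2rad <- pi / 180
  phi_bot <- (spec$lat_origin + (band - 1L) * spec$resolution) * deg2rad
  phi_top <- (spec$lat_origin + band * spec$resolution) * deg2rad
  dlambda <- spec$resolution * deg2rad
  EARTH_RADIUS_KM^2 * dlambda * (sin(phi_top) - sin(phi_bot))
}

#' Matrix of cell areas for a whole grid
#'
#' @param spec a \code{\link{grid_spec}}.
#' @return matrix (n_lat x n_lon) of areas in km^2; rows are constant.
#' @export
cell_area_field <- function(spec) {
  a <- cell_area(seq_len(spec$n_lat), spec)
  matrix(a, spec$n_lat, spec$n_lon)
}

#' Label grid cells with region names
#'
#' @param labels character matrix of dim (n_lat, n_lon); \code{NA} for cells
#'   outside every region is not allowed — use an explicit catch-all label.
#' @param spec a \code{\link{grid_spec}}.
#' @return object of class \code{region_mask} with a \code{labels} matrix and
#'   the label \code{levels}.
#' @export
region_mask <- function(labels, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  labels <- as.matrix(labels)
  if (!all(dim(labels) == c(spec$n_lat, spec$n_lon))) {
    stop("labels must match the grid dimensions")
  }
  if (anyNA(labels)) stop("every cell needs exactly one region label")
  structure(list(spec = spec, labels = labels,
                 levels = sort(unique(as.vector(labels)))),
            class = "region_mask")
}

#' Bounding-box region mask for the synthetic world
#'
#' Three-region partition used with synthetic drivers: an "Africa-like"
#' tropical box (lon -20..50, lat -35..35), a "South-America-like" box
#' (lon -80..-35, lat -55..12), and "Other". Real-continent masks for
#' observational runs are user-supplied, not shipped.
#'
#' @param spec a \code{\link{grid_spec}}.
#' @return a \code{\link{region_mask}}.
#' @export
synthetic_regions <- function(spec) {
  lon <- matrix(spec$lon, spec$n_lat, spec$n_lon, byrow = TRUE)
  lat <- matrix(spec$lat, spec$n_lat, spec$n_lon)
  lab <- matrix("Other", spec$n_lat, spec$n_lon)
  lab[lon >= -20 & lon <= 50 & lat >= -35 & lat <= 35] <- "Africa"
  lab[lon >= -80 & lon <= -35 & lat >= -55 & lat <= 12] <- "South America"
  region_mask(lab, spec)
}

#' Area-weighted global or regional total of a per-area flux field
#'
#' Converts a per-m^2 annual rate to a global (or one region's) total:
#' sum over non-missing cells of value x cell area, with km^2 -> m^2 and
#' g -> Tg scaling, so a field in g m-2 yr-1 yields Tg yr-1.
#'
#' @param field a \code{\link{grid_field}} whose units are a per-m^2 rate
#'   (the units string must contain \code{"m-2"}).
#' @param mask optional \code{\link{region_mask}}.
#' @param label optional region label; with \code{mask}, restricts the sum to
#'   that region.
#' @return scalar total in Tg yr-1 (for g m-2 yr-1 input).
#' @examples
#' sp <- grid_spec(36, 72, 5)
#' f <- grid_field(1, sp, "g m-2 yr-1")
#' area_weighted_total(f)  # 4 pi R^2 in Tg: ~510.06
#' @export
area_weighted_total <- function(field, mask = NULL, label = NULL) {
  stopifnot(inherits(field, "grid_field"))
  if (!grepl("m-2|m\\^-2|m⁻²", field$units)) {
    stop(sprintf("field units '%s' are not a per-m2 rate", field$units))
  }
  v <- field$values
  keep <- !is.na(v)
  if (!is.null(mask)) {
    if (!same_spec(mask$spec, field$spec)) stop("mask grid mismatch")
    if (is.null(label)) stop("a region label is required with a mask")
    if (!label %in% mask$levels) stop(sprintf("unknown region '%s'", label))
    keep <- keep & (mask$labels == label)
  }
  a <- cell_area_field(field$spec)
  sum(v[keep] * a[keep]) * KM2_TO_M2 * G_TO_TG
}

format_g17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a gridded field to NetCDF or CSV
#'
#' NetCDF output (extension \code{.nc}) is CF-style: \code{lat}/\code{lon}
#' coordinate variables in degrees and one data variable carrying the units
#' attribute. Any other extension writes the plain-text fallback: a
#' \code{lat,lon,value} CSV with the variable name and units on
#' \code{#}-comment header lines. Both round-trip bit-exactly through
#' \code{\link{read_field}}.
#'
#' @param field a \code{\link{grid_field}}.
#' @param path output path; format chosen from the extension.
#' @return \code{path}, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  if (grepl("\\.nc$", path, ignore.case = TRUE)) {
    dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$spec$lon)
    dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$spec$lat)
    var <- ncdf4::ncvar_def(field$name, field$units, list(dim_lon, dim_lat),
                            missval = 1e30, prec = "double")
    nc <- ncdf4::nc_create(path, var)
    on.exit(ncdf4::nc_close(nc), add = TRUE)
    # internal layout is (lat, lon); NetCDF variable is (lon, lat)
    ncdf4::ncvar_put(nc, var, t(field$values))
  } else {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c(sprintf("# variable: %s", field$name),
                 sprintf("# units: %s", field$units),
                 "lat,lon,value"), con)
    grid <- expand.grid(lat = field$spec$lat, lon = field$spec$lon)
    writeLines(sprintf("%.10g,%.10g,%s", grid$lat, grid$lon,
                       format_g17(as.vector(field$values))), con)
  }
  invisible(path)
}

#' Read a gridded field from NetCDF or CSV
#'
#' @param path file written by \code{\link{write_field}} (or any CF-style
#'   NetCDF with \code{lat}/\code{lon} coordinates).
#' @param spec a \code{\link{grid_spec}} the file must match; coordinate or
#'   shape mismatches are errors, not silently regridded.
#' @param variable variable name to read from NetCDF; default: the first
#'   non-coordinate variable.
#' @return a \code{\link{grid_field}}. A file with no units attribute yields
#'   units \code{"unknown"} with a warning.
#' @export
read_field <- function(path, spec, variable = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (grepl("\\.nc$", path, ignore.case = TRUE)) {
    nc <- ncdf4::nc_open(path)
    on.exit(ncdf4::nc_close(nc), add = TRUE)
    lat <- tryCatch(as.vector(ncdf4::ncvar_get(nc, "lat")),
                    error = function(e) stop("file has no 'lat' coordinate"))
    lon <- tryCatch(as.vector(ncdf4::ncvar_get(nc, "lon")),
                    error = function(e) stop("file has no 'lon' coordinate"))
    if (length(lat) != spec$n_lat || length(lon) != spec$n_lon ||
        max(abs(lat - spec$lat)) > 1e-6 || max(abs(lon - spec$lon)) > 1e-6) {
      stop("file grid does not match the requested grid_spec")
    }
    vars <- names(nc$var)
    vars <- setdiff(vars, c("lat", "lon"))
    if (is.null(variable)) variable <- vars[1]
    if (!variable %in% names(nc$var)) {
      stop(sprintf("variable '%s' not found (has: %s)", variable,
                   paste(vars, collapse = ", ")))
    }
    vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
    vals <- t(matrix(as.vector(vals), length(lon), length(lat)))
    units <- ncdf4::ncatt_get(nc, variable, "units")
    if (isTRUE(units$hasatt) && nzchar(units$value)) {
      u <- units$value
    } else {
      warning(sprintf("no units attribute on '%s'; using 'unknown'", variable))
      u <- "unknown"
    }
    grid_field(vals, spec, u, name = variable)
  } else {
    header <- readLines(path, n = 10L)
    cmt <- header[startsWith(header, "#")]
    name <- sub("^# variable: *", "", grep("^# variable:", cmt, value = TRUE))
    uline <- grep("^# units:", cmt, value = TRUE)
    if (length(uline)) {
      u <- sub("^# units: *", "", uline[1])
    } else {
      warning("no units line in CSV; using 'unknown'")
      u <- "unknown"
    }
    df <- read.csv(path, comment.char = "#")
    if (!all(c("lat", "lon", "value") %in% names(df))) {
      stop("CSV must have lat,lon,value columns")
    }
    if (nrow(df) != spec$n_lat * spec$n_lon) {
      stop("file grid does not match the requested grid_spec")
    }
    i <- match(round(df$lat, 6), round(spec$lat, 6))
    j <- match(round(df$lon, 6), round(spec$lon, 6))
    if (anyNA(i) || anyNA(j)) {
      stop("file coordinates do not match the requested grid_spec")
    }
    vals <- matrix(NA_real_, spec$n_lat, spec$n_lon)
    vals[cbind(i, j)] <- df$value
    grid_field(vals, spec,
               u, name = if (length(name)) name[1] else "field")
  }
}
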