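#' Per-cell minimum monthly mean temperature
#'
#' @param months list of exactly 12 aligned \code{\link{grid_field}}s
#'   (degrees C); a cell missing in any month is missing in the result.
#' @return a \code{\link{grid_field}} of the per-cell minima (degrees C).
#' @export
min_monthly_temperature <- function(months) {
  if (!is.list(months) || length(months) != 12L) {
    stop("exactly 12 monthly fields are required")
  }
  spec <- months[[1]]$spec
  for (m in months) {
    if (!inherits(m, "grid_field") || !same_spec(m$spec, spec)) {
      stop("monthly fields must share one grid")
    }
  }
  stack <- vapply(months, function(m) as.vector(m$values),
                  numeric(spec$n_lat * spec$n_lon))
  tmin <- apply(stack, 1L, function(r) if (anyNA(r)) NA_real_ else min(r))
  grid_field(matrix(tmin, spec$n_lat, spec$n_lon), spec, units = "degC",
             name = "tmin")
}

#' Climate-envelope habitat mask
#'
#' A cell is potential termite habitat iff its (climatological) minimum
#' monthly mean temperature is strictly above the threshold — the envelope
#' beyond which colonies cannot overwinter. The default threshold is -8 C;
#' a cell at exactly -8.0 is excluded. Cold-limited density-0 classes
#' (tundra, polar desert) are additionally zeroed downstream by their
#' densities, not by this mask.
#'
#' @param tmin minimum monthly temperature field (degrees C), e.g. from
#'   \code{\link{min_monthly_temperature}} over a climatology.
#' @param threshold degrees C (default -8).
#' @return a \code{\link{grid_field}} with values 1 (habitat), 0 (not), NA
#'   (missing input).
#' @export
potential_habitat_mask <- function(tmin, threshold = -8) {
  stopifnot(inherits(tmin, "grid_field"))
  m <- ifelse(is.na(tmin$values), NA_real_,
              as.numeric(tmin$values > threshold))
  grid_field(m, tmin$spec, units = "1", name = "habitat_mask")
}

#' Potential and actual habitat areas
#'
#' Potential area sums the cell areas under the mask; the actual habitat
#' discounts each cell by its cropland areal fraction (land converted to
#' agriculture is counted out of habitat area, although cropland still
#' carries its own density and EF in the emission bookkeeping).
#'
#' @param mask habitat mask field (\code{\link{potential_habitat_mask}}).
#' @param cropland_fraction fraction field in [0, 1] on the same grid.
#' @return object of class \code{habitat_result}: the mask, a per-cell
#'   actual-area field (km^2), and scalar totals
#'   \code{potential_area_total}, \code{actual_area_total} in km^2.
#' @export
habitat_areas <- function(mask, cropland_fraction) {
  stopifnot(inherits(mask, "grid_field"),
            inherits(cropland_fraction, "grid_field"))
  if (!same_spec(mask$spec, cropland_fraction$spec)) {
    stop("mask and cropland fraction must share one grid")
  }
  f <- cropland_fraction$values
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    stop("cropland fraction outside [0, 1]")
  }
  a <- cell_area_field(mask$spec)
  m <- mask$values
  pot <- m * a
  act <- m * a * (1 - f)
  structure(
    list(potential_mask = mask,
         actual_area_field = grid_field(act, mask$spec, units = "km2",
                                        name = "actual_habitat_area"),
         potential_area_total = sum(pot, na.rm = TRUE),
         actual_area_total = sum(act, na.rm = TRUE)),
    class = "habitat_result")
}

#' @export
print.habitat_result <- function(x, ...) {
  cat(sprintf(
    "<habitat_result> potential %.4g km2, actual %.4g km2 (%.1f%% retained)\n",
    x$potential_area_total, x$actual_area_total,
    100 * x$actual_area_total / max(x$potential_area_total, 1e-300)))
  invisible(x)
}

#' Trailing climatological monthly means for a synthetic world
#'
#' Mean monthly temperature over the trailing \code{window} years ending at
#' \code{year} (the habitat envelope is defined on a climatological mean,
#' not a single year's weather). At the start of the series the window is
#' truncated to the available years.
#'
#' @param config a \code{\link{world_config}}.
#' @param year target year.
#' @param window climatology length in years (default 20).
#' @param cache optional environment of precomputed monthly fields keyed by
#'   year (used by \code{\link{run_scenario}} to avoid regeneration).
#' @return list of 12 climatological-mean \code{\link{grid_field}}s.
#' @export
climatology_months <- function(config, year, window = 20L, cache = NULL) {
  year_index(config, year)
  yrs <- seq(max(config$years[1], year - window + 1L), year)
  get_months <- function(y) {
    key <- as.character(y)
    if (!is.null(cache)) {
      if (is.null(cache[[key]])) cache[[key]] <- gen_monthly_temperature(config, y)
      cache[[key]]
    } else {
      gen_monthly_temperature(config, y)
    }
  }
  fields <- lapply(yrs, get_months)
  lapply(seq_len(12L), function(m) {
    acc <- Reduce(`+`, lapply(fields, function(f) f[[m]]$values))
    grid_field(acc / length(yrs), config$spec, units = "degC",
               name = sprintf("tas_clim_%02d", m))
  })
}
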