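#' Configure a multi-year emission scenario run
#'
#' Drives the habitat -> density -> ensemble pipeline over a year range on a
#' synthetic world, under one of four estimator variants: \code{control}
#' (GPP-responsive tropical density, EFs sampled from the dataset),
#' \code{sanderson_ef} (fixed per-class EFs instead of sampling),
#' \code{landuse_density} (density from land use only, no GPP response), and
#' \code{sanderson_ef_and_landuse_density} (both).
#'
#' @param world a \code{\link{world_config}} (or preset name for
#'   \code{\link{world_preset}}).
#' @param years subset of years to run (default: all world years).
#' @param variant estimator variant.
#' @param n_members ensemble size per year (default 1000).
#' @param ef_dataset EF sample for the empirical variants; default a
#'   calibrated synthetic sample of n = 1000 seeded from \code{seed}.
#' @param climatology_window trailing years for the habitat climatology
#'   (default 20).
#' @param threshold habitat temperature threshold, degrees C.
#' @param seed base seed; each year's ensemble seed derives from
#'   (seed, year) so adding years never perturbs existing ones.
#' @return object of class \code{scenario_config}.
#' @export
scenario_config <- function(world, years = NULL,
                            variant = c("control", "sanderson_ef",
                                        "landuse_density",
                                        "sanderson_ef_and_landuse_density"),
                            n_members = 1000L, ef_dataset = NULL,
                            climatology_window = 20L, threshold = -8,
                            seed = 1L) {
  if (is.character(world)) world <- world_preset(world, seed = seed)
  stopifnot(inherits(world, "world_config"))
  variant <- match.arg(variant)
  if (is.null(years)) years <- world$years
  years <- as.integer(years)
  if (!all(years %in% world$years)) stop("years outside the world's range")
  if (is.unsorted(years, strictly = TRUE)) stop("years must be increasing")
  if (is.null(ef_dataset)) {
    ef_dataset <- gen_ef_sample(ef_config(n = 1000L,
                                          seed = derive_seed(seed, "ef")))
  }
  structure(list(world = world, years = years, variant = variant,
                 n_members = as.integer(n_members), ef_dataset = ef_dataset,
                 climatology_window = as.integer(climatology_window),
                 threshold = threshold, seed = as.integer(seed)),
            class = "scenario_config")
}

variant_settings <- function(variant) {
  list(scheme = if (grepl("sanderson_ef", variant)) {
         "prescribed_per_class"
       } else {
         "empirical_sample"
       },
       use_gpp = !grepl("landuse_density", variant))
}

#' Run a multi-year scenario
#'
#' For every year: trailing-climatology habitat mask, density map, and a
#' Monte-Carlo (or prescribed-EF) ensemble; collects the annual series of
#' ensemble mean and s.d., habitat areas and total biomass. Fully
#' reproducible from the config seed.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param regions optional \code{\link{region_mask}}.
#' @param verbose print per-year progress to stderr.
#' @return object of class \code{termite_scenario}: a \code{series} data
#'   frame (year, mean_tg, ensemble_sd_tg, potential_area_km2,
#'   actual_area_km2, biomass_tg, regional columns if requested) plus the
#'   config.
#' @examples
#' w <- world_config(years = 2000:2004, seed = 5)
#' sc <- run_scenario(scenario_config(w, n_members = 50, seed = 5,
#'                                    climatology_window = 3))
#' sc$series
#' @export
run_scenario <- function(config, regions = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  vs <- variant_settings(config$variant)
  dc <- density_config(use_gpp = vs$use_gpp)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(config$years))
  for (i in seq_along(config$years)) {
    yr <- config$years[i]
    if (verbose) message(sprintf("[%s] year %d", config$variant, yr))
    drivers <- synthetic_drivers(config$world, yr,
                                 climatology_window = config$climatology_window,
                                 cache = cache)
    est <- run_ensemble(drivers, config$ef_dataset,
                        n_members = config$n_members,
                        seed = derive_seed(config$seed, "ensemble", yr),
                        density_config = dc, threshold = config$threshold,
                        regions = regions, scheme = vs$scheme)
    row <- data.frame(year = yr, mean_tg = est$mean,
                      ensemble_sd_tg = est$sd,
                      potential_area_km2 = est$potential_area_km2,
                      actual_area_km2 = est$actual_area_km2,
                      biomass_tg = est$biomass_tg)
    if (!is.null(est$regional_means)) {
      reg <- as.data.frame(as.list(est$regional_means))
      names(reg) <- paste0("mean_tg_", gsub("[^A-Za-z0-9]+", "_",
                                            names(est$regional_means)))
      row <- cbind(row, reg)
    }
    rows[[i]] <- row
  }
  structure(list(series = do.call(rbind, rows), config = config),
            class = "termite_scenario")
}

#' @export
print.termite_scenario <- function(x, ...) {
  s <- x$series
  cat(sprintf("<termite_scenario> %s, years %d..%d, %d members/yr\n",
              x$config$variant, min(s$year), max(s$year),
              x$config$n_members))
  cat(sprintf("  emission %.2f -> %.2f Tg CH4 yr-1; biomass %.1f -> %.1f Tg\n",
              s$mean_tg[1], s$mean_tg[nrow(s)],
              s$biomass_tg[1], s$biomass_tg[nrow(s)]))
  invisible(x)
}

#' @export
summary.termite_scenario <- function(object, ...) {
  s <- object$series
  data.frame(
    variable = c("emission_tg", "biomass_tg", "potential_area_km2",
                 "actual_area_km2"),
    first = c(s$mean_tg[1], s$biomass_tg[1], s$potential_area_km2[1],
              s$actual_area_km2[1]),
    last = c(s$mean_tg[nrow(s)], s$biomass_tg[nrow(s)],
             s$potential_area_km2[nrow(s)], s$actual_area_km2[nrow(s)]))
}

#' @export
plot.termite_scenario <- function(x, ...) {
  s <- x$series
  graphics::plot(s$year, s$mean_tg, type = "l", lwd = 2,
                 ylim = range(c(s$mean_tg - s$ensemble_sd_tg,
                                s$mean_tg + s$ensemble_sd_tg)),
                 xlab = "year", ylab = "Tg CH4 yr-1",
                 main = sprintf("Global termite CH4 emission (%s)",
                                x$config$variant), ...)
  graphics::polygon(c(s$year, rev(s$year)),
                    c(s$mean_tg - s$ensemble_sd_tg,
                      rev(s$mean_tg + s$ensemble_sd_tg)),
                    col = grDevices::adjustcolor("grey", 0.4), border = NA)
  graphics::lines(s$year, s$mean_tg, lwd = 2)
  invisible(x)
}

get_series <- function(series) {
  if (inherits(series, "termite_scenario")) series$series else series
}

#' Decadal mean and interannual variability of an annual series
#'
#' Mean and s.d. (n-1) of the annual ensemble-mean totals within a year
#' window. This interannual s.d. is a different statistic from the per-year
#' ensemble s.d.: the former measures year-to-year variation of the mean
#' estimate, the latter the EF-sampling spread within one year.
#'
#' @param series a \code{termite_scenario} or its \code{series} data frame.
#' @param start_year,end_year inclusive window, at least 2 years, inside the
#'   series.
#' @param column series column to average (default \code{"mean_tg"}).
#' @return named vector \code{(mean, sd, n_years)}.
#' @export
decadal_stats <- function(series, start_year, end_year, column = "mean_tg") {
  s <- get_series(series)
  if (!column %in% names(s)) stop(sprintf("no column '%s'", column))
  win <- s$year >= start_year & s$year <= end_year
  if (start_year > end_year || start_year < min(s$year) ||
      end_year > max(s$year)) {
    stop(sprintf("window %d..%d outside series years %d..%d",
                 start_year, end_year, min(s$year), max(s$year)))
  }
  v <- s[[column]][win]
  if (length(v) < 2L) stop("window must contain at least 2 years")
  c(mean = mean(v), sd = sd(v), n_years = length(v))
}

#' Change in decadal-mean emission between two windows
#'
#' @param series a \code{termite_scenario} or its \code{series} data frame.
#' @param base_window,end_window length-2 integer vectors (start, end year).
#' @param column series column (default \code{"mean_tg"}).
#' @return scalar change (end-window decadal mean minus base), Tg CH4 yr-1.
#' @export
scenario_delta <- function(series, base_window, end_window,
                           column = "mean_tg") {
  b <- decadal_stats(series, base_window[1], base_window[2], column)
  e <- decadal_stats(series, end_window[1], end_window[2], column)
  unname(e["mean"] - b["mean"])
}

#' Write an annual series to tidy CSV
#'
#' @param scenario a \code{termite_scenario}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_series_csv <- function(scenario, path) {
  write.csv(get_series(scenario), path, row.names = FALSE)
  invisible(path)
}
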