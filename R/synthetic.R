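#' Configure a synthetic driver world
#'
#' The synthetic world stands in for the external driver datasets of a real
#' run (gridded observational climate, harmonised land use, process-model
#' GPP): a zonal temperature climatology with seasonal cycle, hemispheric
#' phase and an optional secular warming trend; a static zonal biome mosaic
#' over all 15 natural land-cover classes; a cropland fraction concentrated
#' in subtropical/temperate belts with a secular trend; and a GPP field tied
#' to land cover and temperature with a CO2-fertilization multiplier. All
#' generators are pure functions of (config, year): a fixed seed gives
#' bit-identical fields.
#'
#' @param spec a \code{\link{grid_spec}}; default the coarse 5-degree grid
#'   (36 x 72) used throughout the test suite.
#' @param years integer vector of simulation years (continuous range).
#' @param warming_rate surface warming trend in degrees C per decade
#'   (default 0.1, a historical-period magnitude).
#' @param cropland_trend cropland-fraction growth per decade, applied
#'   multiplicatively to the zonal cropland shape (default 0.01).
#' @param co2_fertilization either a per-decade fractional GPP growth rate
#'   (scalar, default 0.022 — compounding to roughly +30 percent over
#'   12 decades), or an explicit vector of multipliers, one per year of
#'   \code{years}.
#' @param temp_noise_sd standard deviation (degrees C) of the seeded monthly
#'   temperature noise, truncated at plus/minus 4 sd.
#' @param gpp_noise_sd relative sd of the multiplicative GPP noise.
#' @param seed base RNG seed; every (year, month, variable) stream is derived
#'   from it deterministically.
#' @return an object of class \code{world_config}.
#' @examples
#' w <- world_config(years = 2001:2020, seed = 42)
#' t_jan <- gen_monthly_temperature(w, 2001)[[1]]
#' @export
world_config <- function(spec = grid_spec(36, 72, 5),
                         years = 1901:2021,
                         warming_rate = 0.1,
                         cropland_trend = 0.01,
                         co2_fertilization = 0.022,
                         temp_noise_sd = 0.5,
                         gpp_noise_sd = 0.05,
                         seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"))
  years <- as.integer(years)
  if (!length(years)) stop("years must be non-empty")
  if (!all(diff(years) == 1L)) stop("years must be a continuous range")
  if (!is.finite(warming_rate) || !is.finite(cropland_trend)) {
    stop("warming_rate and cropland_trend must be finite")
  }
  if (is.numeric(co2_fertilization) && length(co2_fertilization) > 1L &&
      length(co2_fertilization) != length(years)) {
    stop("an explicit co2_fertilization path needs one multiplier per year")
  }
  structure(
    list(spec = spec, years = years, warming_rate = warming_rate,
         cropland_trend = cropland_trend,
         co2_fertilization = co2_fertilization,
         temp_noise_sd = temp_noise_sd, gpp_noise_sd = gpp_noise_sd,
         seed = as.integer(seed)),
    class = "world_config")
}

#' Preset synthetic worlds for scenario contrasts
#'
#' \code{"historical"} uses the default trends; \code{"mitigation-like"} and
#' \code{"high-end-like"} mimic the divergence between a mitigation-oriented
#' and a high-emission future pathway through stronger warming,
#' CO2-fertilization and cropland trends — they are presets of the synthetic
#' world, not ingested climate-model output.
#'
#' @param name preset name.
#' @param years year range.
#' @param seed base seed.
#' @param ... overrides passed to \code{\link{world_config}}.
#' @return a \code{\link{world_config}}.
#' @export
world_preset <- function(name = c("historical", "mitigation-like",
                                  "high-end-like"),
                         years = NULL, seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    "historical" = list(years = 1901:2021, warming_rate = 0.1,
                        cropland_trend = 0.01, co2_fertilization = 0.022),
    "mitigation-like" = list(years = 2021:2100, warming_rate = 0.1,
                             cropland_trend = 0.005,
                             co2_fertilization = 0.01),
    "high-end-like" = list(years = 2021:2100, warming_rate = 0.45,
                           cropland_trend = 0.02,
                           co2_fertilization = 0.05))
  if (!is.null(years)) args$years <- years
  args$seed <- seed
  do.call(world_config, modifyList(args, list(...)))
}

year_index <- function(config, year) {
  year <- as.integer(year)
  if (year < min(config$years) || year > max(config$years)) {
    stop(sprintf("year %d outside the configured range %d..%d",
                 year, min(config$years), max(config$years)))
  }
  year - config$years[1L]
}

#' CO2-fertilization GPP multiplier for a year
#'
#' @param config a \code{\link{world_config}}.
#' @param year simulation year.
#' @return scalar multiplier (1 at the first year for the rate form).
#' @export
co2_multiplier <- function(config, year) {
  idx <- year_index(config, year)
  f <- config$co2_fertilization
  if (length(f) > 1L) f[[idx + 1L]] else (1 + f)^(idx / 10)
}

lat_matrix <- function(spec) matrix(spec$lat, spec$n_lat, spec$n_lon)
lon_matrix <- function(spec) matrix(spec$lon, spec$n_lat, spec$n_lon,
                                    byrow = TRUE)

# deterministic zonal annual-mean temperature (seasonal cycle averages out)
zonal_mean_temp <- function(config, year) {
  phi <- lat_matrix(config$spec) * pi / 180
  27 * cos(phi) - 3 + config$warming_rate * year_index(config, year) / 10
}

#' Generate monthly mean surface air temperature fields
#'
#' Zonal-mean structure 27 cos(phi) - 3 degrees C, a seasonal cycle of
#' amplitude 25 sin^2(phi) with opposite hemispheric phase (warmest month 7
#' north, 1 south), the configured warming trend, and seeded truncated
#' Gaussian noise. At baseline the equator sits near 24 C and the
#' coldest-month polar means are far below -8 C, so both habitat and
#' non-habitat bands always exist and the envelope filter is exercised.
#'
#' @param config a \code{\link{world_config}}.
#' @param year a year within \code{config$years}.
#' @return list of 12 \code{\link{grid_field}}s in degrees C.
#' @export
gen_monthly_temperature <- function(config, year) {
  idx <- year_index(config, year)
  spec <- config$spec
  phi <- lat_matrix(spec) * pi / 180
  base <- 27 * cos(phi) - 3 + config$warming_rate * idx / 10
  amp <- 25 * sin(phi)^2
  peak <- ifelse(lat_matrix(spec) >= 0, 7, 1)
  lapply(seq_len(12L), function(m) {
    seas <- amp * cos(2 * pi * (m - peak) / 12)
    eps <- with_seed(derive_seed(config$seed, "temp", year, m), {
      e <- rnorm(length(base), 0, config$temp_noise_sd)
      pmin(pmax(e, -4 * config$temp_noise_sd), 4 * config$temp_noise_sd)
    })
    grid_field(base + seas + matrix(eps, spec$n_lat, spec$n_lon), spec,
               units = "degC", name = sprintf("tas_%02d", m))
  })
}

#' Generate the static natural-vegetation map
#'
#' Zonal biome belts, mirrored across the equator, covering all 15 natural
#' classes: tropical evergreen forest within 10 degrees of the equator,
#' tropical deciduous to 15, savanna to 23, then desert/shrubland,
#' temperate belts (split by longitude so every temperate class appears),
#' boreal forest, tundra and polar desert. Static over time; cropland is
#' represented by the separate areal-fraction layer, not by this map.
#'
#' @param config a \code{\link{world_config}}.
#' @return a \code{\link{landcover_map}}.
#' @export
gen_landcover <- function(config) {
  spec <- config$spec
  alat <- abs(lat_matrix(spec))
  lon <- lon_matrix(spec)
  cls <- matrix(NA_character_, spec$n_lat, spec$n_lon)
  cls[alat < 10] <- "tropical_evergreen_forest"
  cls[alat >= 10 & alat < 15] <- "tropical_deciduous_forest"
  cls[alat >= 15 & alat < 23] <- "savanna"
  band <- alat >= 23 & alat < 30
  cls[band & lon < -60] <- "desert"
  cls[band & lon >= -60 & lon < 60] <- "dense_shrubland"
  cls[band & lon >= 60] <- "open_shrubland"
  band <- alat >= 30 & alat < 40
  cls[band & lon < 0] <- "grassland"
  cls[band & lon >= 0 & lon < 90] <- "temperate_broadleaf_evergreen_forest"
  cls[band & lon >= 90] <- "temperate_deciduous_forest"
  band <- alat >= 40 & alat < 50
  cls[band & lon < 0] <- "temperate_needleleaf_evergreen_forest"
  cls[band & lon >= 0] <- "mixed_forest"
  band <- alat >= 50 & alat < 65
  cls[band & lon < 0] <- "boreal_evergreen_forest"
  cls[band & lon >= 0] <- "boreal_deciduous_forest"
  cls[alat >= 65 & alat < 75] <- "tundra"
  cls[alat >= 75] <- "polar_desert"
  landcover_map(cls, spec)
}

# cropland zonal shape: subtropical/temperate belts around |lat| = 30
cropland_shape <- function(spec) {
  alat <- abs(lat_matrix(spec))
  exp(-((alat - 30) / 12)^2)
}

#' Generate the annual cropland areal fraction
#'
#' Baseline 0.25 x a Gaussian belt centred at 30 degrees latitude, growing by
#' \code{cropland_trend} per decade (multiplicative on the belt shape),
#' clipped to [0, 1]. Deterministic: land-use reconstructions carry no
#' interannual noise here.
#'
#' @param config a \code{\link{world_config}}.
#' @param year a year within \code{config$years}.
#' @return a \code{\link{grid_field}} of fractions in [0, 1].
#' @export
gen_cropland_fraction <- function(config, year) {
  idx <- year_index(config, year)
  s <- cropland_shape(config$spec)
  f <- s * (0.25 + config$cropland_trend * idx / 10)
  grid_field(pmin(pmax(f, 0), 1), config$spec, units = "fraction",
             name = "cropland_fraction")
}

gpp_base_table <- c(
  tropical_evergreen_forest = 2500, tropical_deciduous_forest = 2000,
  savanna = 1500, temperate_broadleaf_evergreen_forest = 1300,
  temperate_needleleaf_evergreen_forest = 1100,
  temperate_deciduous_forest = 1200, mixed_forest = 1100,
  boreal_evergreen_forest = 800, boreal_deciduous_forest = 700,
  grassland = 900, dense_shrubland = 600, open_shrubland = 350,
  desert = 150, tundra = 120, polar_desert = 0)

#' Generate the annual gross primary production field
#'
#' GPP = land-cover baseline x a temperature modifier (1.5 percent per degree
#' of zonal warming relative to the first year) x the CO2-fertilization
#' multiplier, with seeded multiplicative noise, truncated at 0. The
#' tropical-forest baseline of 2000-2500 g C m-2 yr-1 places the GPP-driven
#' termite densities near the land-cover table magnitudes. Because the noise
#' stream does not depend on the fertilization path, two configs differing
#' only in fertilization give fields in exact ratio.
#'
#' @param config a \code{\link{world_config}}.
#' @param year a year within \code{config$years}.
#' @return a \code{\link{grid_field}} in g C m-2 yr-1 (polar desert exactly 0).
#' @export
gen_gpp <- function(config, year) {
  idx <- year_index(config, year)
  spec <- config$spec
  lc <- gen_landcover(config)
  base <- matrix(gpp_base_table[lc$classes], spec$n_lat, spec$n_lon)
  warm <- config$warming_rate * idx / 10
  tempmod <- pmax(0, 1 + 0.015 * warm)
  fert <- co2_multiplier(config, year)
  eps <- with_seed(derive_seed(config$seed, "gpp", year), {
    e <- rnorm(length(base), 0, config$gpp_noise_sd)
    pmin(pmax(e, -4 * config$gpp_noise_sd), 4 * config$gpp_noise_sd)
  })
  vals <- pmax(base * tempmod * fert *
                 (1 + matrix(eps, spec$n_lat, spec$n_lon)), 0)
  grid_field(vals, spec, units = "g C m-2 yr-1", name = "gpp")
}

#' Generate a soil CH4 oxidation sink field
#'
#' A smooth positive zonal shape over upland latitudes, scaled so that the
#' area-weighted global total equals \code{target_tg}. This is bookkeeping
#' input for the net upland CH4 budget; the oxidation mechanism itself is
#' upstream of this package and not modelled.
#'
#' @param config a \code{\link{world_config}}.
#' @param year a year within \code{config$years} (the synthetic sink is
#'   time-invariant; the argument keeps the driver interface uniform).
#' @param target_tg prescribed global sink total in Tg CH4 yr-1
#'   (default 31.6). Must be >= 0.
#' @return a \code{\link{grid_field}} in g m-2 yr-1.
#' @export
gen_soil_sink <- function(config, year = config$years[1], target_tg = 31.6) {
  year_index(config, year)
  if (!is.finite(target_tg) || target_tg < 0) {
    stop("target_tg must be a non-negative sink total")
  }
  spec <- config$spec
  alat <- abs(lat_matrix(spec))
  shape <- exp(-((alat - 25)^2) / 800) + 0.05
  f <- grid_field(shape, spec, units = "g m-2 yr-1", name = "soil_ch4_sink")
  raw <- area_weighted_total(f)
  grid_field(shape * (target_tg / raw), spec, units = "g m-2 yr-1",
             name = "soil_ch4_sink")
}
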