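#' Bundle one year's aligned driver inputs
#'
#' @param temperature_months list of 12 monthly (climatological) temperature
#'   fields, degrees C.
#' @param landcover a \code{\link{landcover_map}}.
#' @param cropland_fraction cropland areal fraction field in [0, 1].
#' @param gpp GPP field (g C m-2 yr-1) or NULL.
#' @param soil_sink optional soil CH4 oxidation field (g m-2 yr-1).
#' @param year calendar year the bundle represents.
#' @return object of class \code{driver_bundle}.
#' @export
driver_bundle <- function(temperature_months, landcover, cropland_fraction,
                          gpp = NULL, soil_sink = NULL, year = NA_integer_) {
  stopifnot(inherits(landcover, "landcover_map"),
            inherits(cropland_fraction, "grid_field"))
  spec <- landcover$spec
  if (length(temperature_months) != 12L) stop("12 monthly fields required")
  for (f in c(temperature_months, list(cropland_fraction),
              if (!is.null(gpp)) list(gpp),
              if (!is.null(soil_sink)) list(soil_sink))) {
    if (!inherits(f, "grid_field") || !same_spec(f$spec, spec)) {
      stop("driver grids do not match")
    }
  }
  structure(list(temperature_months = temperature_months,
                 landcover = landcover,
                 cropland_fraction = cropland_fraction,
                 gpp = gpp, soil_sink = soil_sink,
                 year = as.integer(year), spec = spec),
            class = "driver_bundle")
}

#' Build a synthetic driver bundle for one year
#'
#' Convenience wrapper chaining the synthetic generators, with the habitat
#' climatology evaluated on the trailing window.
#'
#' @param config a \code{\link{world_config}}.
#' @param year a year within \code{config$years}.
#' @param climatology_window years of trailing temperature climatology
#'   (default 20).
#' @param sink_target_tg optional global soil-sink total (Tg CH4 yr-1);
#'   NULL omits the sink layer.
#' @param cache optional environment for memoising monthly fields across
#'   years.
#' @return a \code{\link{driver_bundle}}.
#' @export
synthetic_drivers <- function(config, year, climatology_window = 20L,
                              sink_target_tg = NULL, cache = NULL) {
  driver_bundle(
    temperature_months = climatology_months(config, year,
                                            climatology_window, cache),
    landcover = gen_landcover(config),
    cropland_fraction = gen_cropland_fraction(config, year),
    gpp = gen_gpp(config, year),
    soil_sink = if (!is.null(sink_target_tg)) {
      gen_soil_sink(config, year, sink_target_tg)
    },
    year = year)
}

#' Per-cell annual termite CH4 flux
#'
#' emission = density x emission factor, summed over the natural and
#' cropland components weighted by the cropland areal fraction, converted
#' from ug m-2 h-1 to g m-2 yr-1 by 24 x 365 hours and ug -> g. Zero outside
#' habitat.
#'
#' @param rho_nat natural termite density, g m-2 (vectorised).
#' @param ef_nat natural-class emission factor, ug CH4 g-1 termite h-1.
#' @param rho_crop,ef_crop cropland density and emission factor.
#' @param f_crop cropland areal fraction in [0, 1].
#' @param in_habitat logical/0-1 habitat flag.
#' @return flux in g CH4 m-2 yr-1.
#' @examples
#' cell_flux(11, 5.9, 3.815, 3.45, 0, TRUE)  # ~0.5685 g m-2 yr-1
#' @export
cell_flux <- function(rho_nat, ef_nat, rho_crop, ef_crop, f_crop,
                      in_habitat) {
  if (any(c(rho_nat, ef_nat, rho_crop, ef_crop) < 0, na.rm = TRUE)) {
    stop("densities and emission factors must be >= 0")
  }
  if (any(f_crop < 0 | f_crop > 1, na.rm = TRUE)) {
    stop("cropland fraction outside [0, 1]")
  }
  hourly <- (1 - f_crop) * rho_nat * ef_nat + f_crop * rho_crop * ef_crop
  as.numeric(in_habitat) * hourly * HOURS_PER_YEAR * UG_TO_G
}

# per-class area-weighted emission weights: member total (Tg) is the dot
# product of the EF assignment with these, since emission is linear in EF
class_weights <- function(drivers, density_config_ = density_config(),
                          threshold = -8, regions = NULL) {
  spec <- drivers$spec
  tmin <- min_monthly_temperature(drivers$temperature_months)
  mask <- potential_habitat_mask(tmin, threshold)
  habitat <- habitat_areas(mask, drivers$cropland_fraction)
  dens <- density_field(drivers$landcover, drivers$gpp, mask, density_config_)
  biomass <- total_biomass(dens, drivers$cropland_fraction, mask)

  a <- cell_area_field(spec)
  f <- drivers$cropland_fraction$values
  m <- mask$values
  cls <- drivers$landcover$classes
  to_tg <- HOURS_PER_YEAR * UG_TO_G * KM2_TO_M2 * G_TO_TG
  nat_w <- (1 - f) * dens$values * a * m * to_tg
  crop_w <- f * lookup_density("cropland")[[1]] * a * m * to_tg
  crop_w[is.na(cls)] <- NA  # no-data cells drop out of both components
  ok <- !is.na(nat_w) & !is.na(cls)

  classes <- landcover_classes(include_cropland = TRUE)
  tally <- function(keep) {
    w <- vapply(setdiff(classes, "cropland"), function(cl) {
      sum(nat_w[ok & keep & cls == cl])
    }, numeric(1))
    c(w, cropland = sum(crop_w[!is.na(crop_w) & keep], na.rm = TRUE))
  }
  weights <- tally(TRUE)
  regional <- NULL
  if (!is.null(regions)) {
    if (!same_spec(regions$spec, spec)) stop("region mask grid mismatch")
    regional <- vapply(regions$levels,
                       function(lb) tally(regions$labels == lb),
                       numeric(length(classes)))
    rownames(regional) <- classes
  }
  list(weights = weights, regional = regional, mask = mask,
       habitat = habitat, density = dens, biomass_tg = biomass)
}

#' Run one fully specified emission estimate (one ensemble member)
#'
#' Chains habitat mask -> density -> per-cell flux -> area-weighted totals
#' for a fixed per-class emission-factor assignment.
#'
#' @param drivers a \code{\link{driver_bundle}}.
#' @param ef_assignment named EF vector over all classes (cropland included),
#'   e.g. from \code{\link{draw_ef_assignment}} or \code{\link{prescribed_ef}}.
#' @param density_config a \code{\link{density_config}}.
#' @param threshold habitat temperature threshold, degrees C.
#' @param regions optional \code{\link{region_mask}} for regional totals.
#' @return list with the flux \code{field} (g CH4 m-2 yr-1), scalar
#'   \code{total_tg}, optional named \code{regional_tg}, and the
#'   \code{habitat} result, \code{density} field and \code{biomass_tg}.
#' @export
run_member <- function(drivers, ef_assignment,
                       density_config = termiteCH4::density_config(),
                       threshold = -8, regions = NULL) {
  stopifnot(inherits(drivers, "driver_bundle"))
  classes <- landcover_classes(include_cropland = TRUE)
  if (!all(classes %in% names(ef_assignment))) {
    stop("ef_assignment must name every land-cover class incl. cropland")
  }
  cw <- class_weights(drivers, density_config, threshold, regions)
  cls <- drivers$landcover$classes
  ef_nat <- matrix(ef_assignment[cls], drivers$spec$n_lat, drivers$spec$n_lon)
  flux <- cell_flux(cw$density$values, ef_nat,
                    lookup_density("cropland")[[1]],
                    ef_assignment[["cropland"]],
                    drivers$cropland_fraction$values,
                    cw$mask$values)
  field <- grid_field(flux, drivers$spec, units = "g m-2 yr-1",
                      name = "termite_ch4_flux")
  total <- area_weighted_total(field)
  regional <- NULL
  if (!is.null(regions)) {
    regional <- vapply(regions$levels, function(lb) {
      area_weighted_total(field, regions, lb)
    }, numeric(1))
  }
  list(field = field, total_tg = total, regional_tg = regional,
       habitat = cw$habitat, density = cw$density,
       biomass_tg = cw$biomass_tg, year = drivers$year)
}

#' Monte-Carlo ensemble of global termite CH4 emissions
#'
#' Runs \code{n_members} emission estimates, each with one independent
#' per-class emission-factor assignment drawn from the dataset
#' (\code{scheme = "empirical_sample"}), or a single deterministic estimate
#' with the fixed per-class table values
#' (\code{scheme = "prescribed_per_class"}, for which the member spread is
#' exactly 0). Member totals exploit the linearity of the emission in the
#' EFs: the per-class area-weighted density sums are computed once and each
#' member is a dot product.
#'
#' @param drivers a \code{\link{driver_bundle}}.
#' @param ef_dataset an \code{ef_sample} or numeric EF vector (ignored for
#'   the prescribed scheme).
#' @param n_members ensemble size (default 1000).
#' @param seed RNG seed for the EF draws.
#' @param density_config a \code{\link{density_config}}.
#' @param threshold habitat threshold, degrees C.
#' @param regions optional \code{\link{region_mask}}.
#' @param scheme EF scheme.
#' @return object of class \code{termite_ensemble}: \code{member_totals}
#'   (Tg CH4 yr-1), \code{mean}, \code{sd}, \code{regional_means},
#'   habitat/biomass diagnostics, \code{n_members}, \code{seed}.
#' @examples
#' w <- world_config(years = 2000:2000, seed = 3)
#' d <- synthetic_drivers(w, 2000, climatology_window = 1)
#' ef <- gen_ef_sample(ef_config(n = 500, seed = 3))
#' est <- run_ensemble(d, ef, n_members = 100, seed = 3)
#' est
#' @export
run_ensemble <- function(drivers, ef_dataset = NULL, n_members = 1000L,
                         seed = 1L,
                         density_config = termiteCH4::density_config(),
                         threshold = -8, regions = NULL,
                         scheme = c("empirical_sample",
                                    "prescribed_per_class")) {
  stopifnot(inherits(drivers, "driver_bundle"))
  scheme <- match.arg(scheme)
  n_members <- as.integer(n_members)
  if (n_members < 1L) stop("n_members must be >= 1")
  cw <- class_weights(drivers, density_config, threshold, regions)
  classes <- names(cw$weights)

  if (scheme == "prescribed_per_class") {
    ef <- prescribed_ef(classes)
    totals <- rep(sum(ef * cw$weights), n_members)
    reg_members <- if (!is.null(cw$regional)) {
      matrix(rep(as.vector(ef %*% cw$regional), each = n_members),
             n_members, ncol(cw$regional),
             dimnames = list(NULL, colnames(cw$regional)))
    }
  } else {
    v <- ef_values(ef_dataset)
    if (!length(v)) stop("EF dataset must be non-empty")
    draws <- with_seed(seed, {
      matrix(v[sample.int(length(v), n_members * length(classes),
                          replace = TRUE)],
             n_members, length(classes),
             dimnames = list(NULL, classes))
    })
    totals <- as.vector(draws %*% cw$weights)
    reg_members <- if (!is.null(cw$regional)) draws %*% cw$regional
  }

  structure(
    list(member_totals = totals,
         mean = mean(totals),
         sd = if (n_members > 1L) sd(totals) else 0,
         regional_means = if (!is.null(reg_members)) colMeans(reg_members),
         regional_sds = if (!is.null(reg_members) && n_members > 1L) {
           apply(reg_members, 2L, sd)
         },
         biomass_tg = cw$biomass_tg,
         potential_area_km2 = cw$habitat$potential_area_total,
         actual_area_km2 = cw$habitat$actual_area_total,
         n_members = n_members, seed = as.integer(seed), scheme = scheme,
         year = drivers$year),
    class = "termite_ensemble")
}

#' @export
print.termite_ensemble <- function(x, ...) {
  cat(sprintf(
    "<termite_ensemble> %s%d members (%s)\n  global emission %.2f +/- %.2f Tg CH4 yr-1\n",
    if (!is.na(x$year)) sprintf("year %d, ", x$year) else "",
    x$n_members, x$scheme, x$mean, x$sd))
  cat(sprintf("  biomass %.1f Tg dw; habitat %.3g / %.3g km2 (pot/actual)\n",
              x$biomass_tg, x$potential_area_km2, x$actual_area_km2))
  if (!is.null(x$regional_means)) {
    cat("  regional means (Tg):",
        paste(sprintf("%s %.2f", names(x$regional_means), x$regional_means),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.termite_ensemble <- function(object, ...) {
  q <- stats::quantile(object$member_totals, c(0.025, 0.25, 0.5, 0.75, 0.975))
  out <- list(mean = object$mean, sd = object$sd, quantiles = q,
              n_members = object$n_members,
              regional_means = object$regional_means,
              biomass_tg = object$biomass_tg,
              potential_area_km2 = object$potential_area_km2,
              actual_area_km2 = object$actual_area_km2)
  class(out) <- "summary.termite_ensemble"
  out
}

#' @export
print.summary.termite_ensemble <- function(x, ...) {
  cat(sprintf("Global termite CH4 emission: %.2f +/- %.2f Tg yr-1 (n = %d)\n",
              x$mean, x$sd, x$n_members))
  print(round(x$quantiles, 3))
  invisible(x)
}

#' @export
plot.termite_ensemble <- function(x, breaks = 30, ...) {
  graphics::hist(x$member_totals, breaks = breaks,
                 main = "Ensemble global termite CH4 emission",
                 xlab = "Tg CH4 yr-1", col = "grey80", border = "white", ...)
  graphics::abline(v = x$mean, lwd = 2)
  invisible(x)
}

#' Fraction of the soil CH4 sink offset by termite emissions
#'
#' @param emission_total termite emission total, Tg CH4 yr-1.
#' @param sink_total soil oxidation sink total, Tg CH4 yr-1; must be > 0.
#' @return offset in percent (100 x emission / sink).
#' @examples
#' offset_fraction(14.8, 31.6)  # ~46.8
#' @export
offset_fraction <- function(emission_total, sink_total) {
  if (!is.finite(sink_total) || sink_total <= 0) {
    stop("sink_total must be positive")
  }
  100 * emission_total / sink_total
}

#' Net upland CH4 flux (termite source minus soil sink)
#'
#' @param emission termite flux field, g CH4 m-2 yr-1.
#' @param sink soil oxidation field, g CH4 m-2 yr-1 (positive = uptake).
#' @return signed \code{\link{grid_field}}: positive cells are net sources,
#'   negative net sinks.
#' @export
net_flux_field <- function(emission, sink) {
  stopifnot(inherits(emission, "grid_field"), inherits(sink, "grid_field"))
  if (!same_spec(emission$spec, sink$spec)) stop("grid mismatch")
  grid_field(emission$values - sink$values, emission$spec,
             units = "g m-2 yr-1", name = "net_ch4_flux")
}

#' Convert a CH4 flux to CO2-equivalent carbon
#'
#' Multiplies by the Global Warming Potential for the chosen horizon and
#' converts CO2 mass to carbon (12/44).
#'
#' @param tg_ch4 CH4 flux in Tg yr-1.
#' @param horizon GWP horizon in years: 20 or 100.
#' @param gwp named GWP values (defaults 79.7 and 27.0).
#' @return CO2-equivalent carbon in Tg C yr-1.
#' @examples
#' ch4_to_co2eq_carbon(0.5, 100)  # ~3.68 Tg C
#' @export
ch4_to_co2eq_carbon <- function(tg_ch4, horizon = 100,
                                gwp = c("20" = 79.7, "100" = 27.0)) {
  h <- as.character(horizon)
  if (!h %in% names(gwp)) {
    stop(sprintf("horizon must be one of: %s",
                 paste(names(gwp), collapse = ", ")))
  }
  tg_ch4 * gwp[[h]] * 12 / 44
}
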