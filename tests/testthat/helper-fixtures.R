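# Shared fixtures: coarse grids, hand-built single-class worlds, and the
# naive scalar-loop emission oracle used to cross-check the vectorized engine.

coarse_spec <- function() grid_spec(36, 72, 5)

# a driver bundle with uniform temperature, one land-cover class everywhere,
# constant cropland fraction and optional uniform GPP
uniform_drivers <- function(spec = coarse_spec(), temp = 25,
                            class = "tropical_evergreen_forest",
                            f_crop = 0, gpp = NULL, year = 2000L) {
  months <- lapply(1:12, function(m) grid_field(temp, spec, "degC"))
  driver_bundle(
    temperature_months = months,
    landcover = landcover_map(matrix(class, spec$n_lat, spec$n_lon), spec),
    cropland_fraction = grid_field(f_crop, spec, "fraction"),
    gpp = if (!is.null(gpp)) grid_field(gpp, spec, "g C m-2 yr-1"),
    year = year)
}

# independent scalar-loop oracle for the global emission total (Tg yr-1):
# recomputes everything cell by cell with plain arithmetic, including the
# spherical cell area from its closed form, sharing no code with the engine
brute_force_total <- function(drivers, ef_assignment,
                              use_gpp = TRUE, a = 1.21, b = 0.0008,
                              responsive = c("tropical_evergreen_forest",
                                             "tropical_deciduous_forest"),
                              threshold = -8) {
  spec <- drivers$spec
  tab <- landcover_table()
  rho_crop <- tab$density_g_per_m2[tab$class == "cropland"]
  ef_crop <- ef_assignment[["cropland"]]
  R <- 6371.0
  total_g <- 0
  for (i in seq_len(spec$n_lat)) {
    phi0 <- (spec$lat_origin + (i - 1) * spec$resolution) * pi / 180
    phi1 <- (spec$lat_origin + i * spec$resolution) * pi / 180
    area_m2 <- R^2 * (spec$resolution * pi / 180) *
      (sin(phi1) - sin(phi0)) * 1e6
    for (j in seq_len(spec$n_lon)) {
      tmin <- Inf
      miss <- FALSE
      for (m in 1:12) {
        v <- drivers$temperature_months[[m]]$values[i, j]
        if (is.na(v)) miss <- TRUE else tmin <- min(tmin, v)
      }
      cls <- drivers$landcover$classes[i, j]
      if (miss || is.na(cls) || tmin <= threshold) next
      rho <- tab$density_g_per_m2[tab$class == cls]
      if (use_gpp && cls %in% responsive && !is.null(drivers$gpp)) {
        g <- drivers$gpp$values[i, j]
        if (!is.na(g)) rho <- a * exp(b * g)
      }
      f <- drivers$cropland_fraction$values[i, j]
      hourly <- (1 - f) * rho * ef_assignment[[cls]] + f * rho_crop * ef_crop
      total_g <- total_g + hourly * 24 * 365 * 1e-6 * area_m2
    }
  }
  total_g * 1e-12
}

# constant EF assignment over every class
flat_ef <- function(value) {
  stats::setNames(rep(value, length(landcover_classes(TRUE))),
                  landcover_classes(TRUE))
}
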