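#' Configure the termite-density mapping
#'
#' In tropical forests, termite biomass density tracks vegetation
#' productivity through density = a * exp(b * GPP) (g dry weight m-2, with
#' GPP in g C m-2 yr-1); everywhere else the fixed per-class table value is
#' used. Setting \code{use_gpp = FALSE} gives the land-use-only variant in
#' which tropical forests also take their fixed table densities (8 and 11
#' g m-2).
#'
#' @param use_gpp apply the GPP relationship in the responsive classes.
#' @param gpp_responsive_classes classes the relationship applies to;
#'   default the two tropical forest classes. Savanna can be added as a
#'   sensitivity switch but is off by default.
#' @param a,b coefficients of the exponential relationship
#'   (defaults 1.21 g m-2 and 0.0008 per g C m-2 yr-1).
#' @return an object of class \code{density_config}.
#' @export
density_config <- function(use_gpp = TRUE,
                           gpp_responsive_classes = c(
                             "tropical_evergreen_forest",
                             "tropical_deciduous_forest"),
                           a = 1.21, b = 0.0008) {
  if (a <= 0 || b <= 0) stop("coefficients a and b must be positive")
  bad <- setdiff(gpp_responsive_classes, landcover_classes())
  if (length(bad)) {
    stop(sprintf("unknown gpp_responsive class(es): %s",
                 paste(bad, collapse = ", ")))
  }
  structure(list(use_gpp = isTRUE(use_gpp),
                 gpp_responsive_classes = gpp_responsive_classes,
                 a = a, b = b),
            class = "density_config")
}

#' Fixed per-class termite biomass density
#'
#' @param class land-cover class name(s), cropland included (vectorised).
#' @return density in g dry weight m-2.
#' @examples
#' lookup_density("tropical_evergreen_forest")  # 11
#' lookup_density("tundra")                     # 0
#' @export
lookup_density <- function(class) {
  tab <- landcover_table()
  i <- match(class, tab$class)
  if (anyNA(i)) {
    stop(sprintf("unknown land-cover class(es): %s",
                 paste(class[is.na(i)], collapse = ", ")))
  }
  stats::setNames(tab$density_g_per_m2[i], class)
}

#' GPP-driven tropical termite biomass density
#'
#' density = a * exp(b * GPP), uncapped (at GPP 3000 g C m-2 yr-1 this gives
#' about 13.3 g m-2, near the table's tropical-evergreen 11).
#'
#' @param gpp GPP in g C m-2 yr-1, finite and >= 0 (vectorised).
#' @param config a \code{\link{density_config}}.
#' @return density in g dry weight m-2.
#' @examples
#' tropical_density(0)     # 1.21
#' tropical_density(2500)  # 1.21 * e^2
#' @export
tropical_density <- function(gpp, config = density_config()) {
  if (any(!is.finite(gpp)) || any(gpp < 0)) {
    stop("gpp must be finite and >= 0")
  }
  config$a * exp(config$b * gpp)
}

#' Map natural-vegetation termite density over the grid
#'
#' Density is 0 outside the habitat mask; inside it, the GPP relationship is
#' used for the responsive classes (when \code{use_gpp}) and the fixed table
#' value otherwise. A responsive-class cell with missing GPP falls back to
#' its table value with a warning. Cropland density is applied separately by
#' the emission engine through the cropland-fraction weighting.
#'
#' @param landcover a \code{\link{landcover_map}}.
#' @param gpp_field GPP \code{\link{grid_field}} (g C m-2 yr-1); NULL is
#'   treated as all-missing GPP (table fallback, with a warning if any
#'   responsive cells exist).
#' @param habitat_mask habitat mask field.
#' @param config a \code{\link{density_config}}.
#' @return a \code{\link{grid_field}} in g m-2 (dry weight).
#' @export
density_field <- function(landcover, gpp_field, habitat_mask,
                          config = density_config()) {
  stopifnot(inherits(landcover, "landcover_map"),
            inherits(habitat_mask, "grid_field"))
  spec <- landcover$spec
  if (!same_spec(spec, habitat_mask$spec)) stop("habitat mask grid mismatch")
  cls <- landcover$classes
  tab <- landcover_table()
  dens <- matrix(tab$density_g_per_m2[match(cls, tab$class)],
                 spec$n_lat, spec$n_lon)
  if (config$use_gpp) {
    if (!is.null(gpp_field) && !same_spec(spec, gpp_field$spec)) {
      stop("GPP field grid mismatch")
    }
    g <- if (is.null(gpp_field)) {
      matrix(NA_real_, spec$n_lat, spec$n_lon)
    } else {
      gpp_field$values
    }
    resp <- !is.na(cls) & cls %in% config$gpp_responsive_classes
    miss <- resp & is.na(g)
    if (any(miss)) {
      warning(sprintf(
        "%d responsive-class cell(s) have missing GPP; using table density",
        sum(miss)))
    }
    use <- resp & !is.na(g)
    dens[use] <- tropical_density(g[use], config)
  }
  m <- habitat_mask$values
  vals <- ifelse(is.na(cls) | is.na(m), NA_real_, dens * m)
  grid_field(vals, spec, units = "g m-2", name = "termite_density")
}

#' Global termite biomass
#'
#' Area-weighted biomass over habitat cells, mixing the natural-vegetation
#' density with the cropland density by the cropland areal fraction:
#' sum of [(1-f) rho_nat + f rho_crop] x area, in Tg dry weight.
#'
#' @param density natural-density field (g m-2) from
#'   \code{\link{density_field}} (already 0 outside habitat).
#' @param cropland_fraction fraction field in [0, 1].
#' @param habitat_mask habitat mask field (restricts the cropland term).
#' @param rho_crop cropland density, g m-2 (default the table value 3.815).
#' @return total biomass in Tg dry weight.
#' @export
total_biomass <- function(density, cropland_fraction, habitat_mask,
                          rho_crop = lookup_density("cropland")[[1]]) {
  stopifnot(inherits(density, "grid_field"),
            inherits(cropland_fraction, "grid_field"))
  if (!same_spec(density$spec, cropland_fraction$spec) ||
      !same_spec(density$spec, habitat_mask$spec)) {
    stop("inputs must share one grid")
  }
  f <- cropland_fraction$values
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    stop("cropland fraction outside [0, 1]")
  }
  mix <- (1 - f) * density$values + f * rho_crop * habitat_mask$values
  fld <- grid_field(mix, density$spec, units = "g m-2", name = "biomass")
  area_weighted_total(fld)
}
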