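#' Land-cover classes and their termite parameters
#'
#' The 15 natural vegetation classes plus cropland, with the
#' Sanderson-derived per-class emission factor
#' (ug CH4 g-1 termite h-1) and termite biomass density (g dry weight m-2)
#' used throughout the package. Tundra and polar desert carry zero density
#' and so never emit regardless of the habitat mask.
#'
#' @return data frame with columns \code{class}, \code{long_name},
#'   \code{emission_factor_ug_per_g_per_h}, \code{density_g_per_m2}.
#' @examples
#' tab <- landcover_table()
#' tab[tab$class == "savanna", ]
#' @export
landcover_table <- function() {
  path <- system.file("extdata", "landcover_parameters.csv",
                      package = "termiteCH4", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Names of the natural land-cover classes
#'
#' @param include_cropland also append \code{"cropland"} (a land-use class,
#'   handled by the cropland-fraction weighting, not by the natural-vegetation
#'   map).
#' @return character vector of class names.
#' @export
landcover_classes <- function(include_cropland = FALSE) {
  cls <- landcover_table()$class
  if (include_cropland) cls else setdiff(cls, "cropland")
}

#' Per-cell categorical land-cover map
#'
#' @param classes character matrix of class names, dim (n_lat, n_lon); NA for
#'   no-data cells.
#' @param spec a \code{\link{grid_spec}}.
#' @return object of class \code{landcover_map}.
#' @export
landcover_map <- function(classes, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  classes <- as.matrix(classes)
  if (!all(dim(classes) == c(spec$n_lat, spec$n_lon))) {
    stop("classes must match the grid dimensions")
  }
  known <- landcover_classes(include_cropland = FALSE)
  bad <- setdiff(unique(classes[!is.na(classes)]), known)
  if (length(bad)) {
    stop(sprintf("unknown land-cover class(es): %s",
                 paste(bad, collapse = ", ")))
  }
  structure(list(spec = spec, classes = classes), class = "landcover_map")
}

#' @export
print.landcover_map <- function(x, ...) {
  tab <- sort(table(x$classes), decreasing = TRUE)
  cat(sprintf("<landcover_map> %d x %d, %d classes present\n",
              nrow(x$classes), ncol(x$classes), length(tab)))
  print(utils::head(tab, 5))
  invisible(x)
}
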