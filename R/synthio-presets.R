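#' Define a cortical layer for a synthetic area profile
#'
#' A layer is described by its relative thickness, the expected areal
#' density of visible cell bodies, the cell-body size distribution and the
#' staining darkness.  `cell_radius_mean_deep` allows a linear size
#' gradient across the depth of the layer (e.g. pyramidal cells growing
#' from upper to lower layer III); when `NA` the radius is constant.
#'
#' @param name Layer label (Roman numeral convention, sublayers allowed,
#'   e.g. `"IVc"`).
#' @param thickness_fraction Fraction of total cortical depth in `[0, 1]`.
#'   Fractions of all layers of an area must sum to 1.
#' @param cell_density Expected number of cell bodies per mm^2 of section.
#' @param cell_radius_mean,cell_radius_sd Mean and standard deviation of
#'   the cell-body radius in micrometres (at the top of the layer).
#' @param stain_intensity Greyscale value of the stained cell body,
#'   0 (black) to 255 (white); cells must be darker than the background.
#' @param cell_radius_mean_deep Mean radius at the bottom of the layer in
#'   micrometres, or `NA` for a constant radius.
#'
#' @return A one-row tibble.
#' @export
layer_spec <- function(name, thickness_fraction, cell_density,
                       cell_radius_mean, cell_radius_sd, stain_intensity,
                       cell_radius_mean_deep = NA_real_) {
  tibble::tibble(
    name = as.character(name),
    thickness_fraction = as.numeric(thickness_fraction),
    cell_density = as.numeric(cell_density),
    cell_radius_mean = as.numeric(cell_radius_mean),
    cell_radius_sd = as.numeric(cell_radius_sd),
    stain_intensity = as.numeric(stain_intensity),
    cell_radius_mean_deep = as.numeric(cell_radius_mean_deep)
  )
}

#' Assemble an area profile from layer specifications
#'
#' @param area_id Character identifier, unique within a phantom.
#' @param layers Tibble of [layer_spec()] rows, ordered from the pial
#'   surface downwards.
#' @param columnarity Strength of vertical cell clustering in `[0, 1]`:
#'   the point-process intensity is modulated by a vertical stripe pattern
#'   of period 50 um and relative amplitude `columnarity`.
#'
#' @return An object of class `area_profile`.
#' @export
area_profile <- function(area_id, layers, columnarity = 0) {
  prof <- structure(
    list(area_id = as.character(area_id),
         layers = layers,
         columnarity = as.numeric(columnarity)),
    class = "area_profile"
  )
  validate_area_profile(prof)
  prof
}

validate_area_profile <- function(profile) {
  ly <- profile$layers
  if (!is.data.frame(ly) || nrow(ly) < 1L)
    abort("An area profile needs at least one layer.")
  if (abs(sum(ly$thickness_fraction) - 1) > 1e-9)
    abort(sprintf("Layer thickness fractions of area '%s' must sum to 1 (got %.12f).",
                  profile$area_id, sum(ly$thickness_fraction)))
  if (any(ly$cell_density < 0) || any(ly$cell_radius_mean < 0) ||
      any(ly$cell_radius_sd < 0))
    abort("Cell densities and radii must be non-negative.")
  if (profile$columnarity < 0 || profile$columnarity > 1)
    abort("`columnarity` must lie in [0, 1].")
  invisible(profile)
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf("<area_profile '%s'>  %d layers, columnarity %.2f\n",
              x$area_id, nrow(x$layers), x$columnarity))
  print(x$layers, n = nrow(x$layers))
  invisible(x)
}

#' Built-in area presets emulating primary and secondary visual cortex
#'
#' `"hOc1-like"` carries a tripartite layer IV (IVa/IVb/IVc) whose
#' sublayer IVc has the strictly highest cell density of all layers,
#' and a cell-sparse layer V with the strictly lowest density among
#' layers II-VI.  `"hOc2-like"` has a single, thinner layer IV, pyramidal
#' cells whose size increases from upper to lower layer III, a weaker
#' V/VI density contrast, and a stronger columnar arrangement.
#'
#' The numeric densities and radii are package choices: the presets
#' encode the rank-order relations between the two areas, not measured
#' values.
#'
#' @param kind `"hOc1-like"` or `"hOc2-like"`.
#' @return An [area_profile()].
#' @export
#' @examples
#' p1 <- make_preset_profile("hOc1-like")
#' p2 <- make_preset_profile("hOc2-like")
#' p2$columnarity > p1$columnarity
make_preset_profile <- function(kind) {
  presets <- c("hOc1-like", "hOc2-like")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% presets))
    abort(sprintf("Unknown preset %s. Valid presets: %s.",
                  deparse(substitute(kind)), paste0("'", presets, "'", collapse = ", ")))
  if (kind == "hOc1-like") {
    layers <- dplyr::bind_rows(
      layer_spec("I",   0.10,   300, 2.5, 0.5, 95),
      layer_spec("II",  0.07,  6500, 3.0, 0.6, 70),
      layer_spec("III", 0.24,  4200, 4.0, 0.8, 65, cell_radius_mean_deep = 4.6),
      layer_spec("IVa", 0.05,  6500, 3.0, 0.6, 70),
      layer_spec("IVb", 0.06,  3800, 3.5, 0.7, 70),
      layer_spec("IVc", 0.12, 11000, 2.8, 0.5, 65),
      layer_spec("V",   0.12,  2000, 4.0, 0.8, 70),
      layer_spec("VI",  0.24,  6000, 3.8, 0.7, 62)
    )
    return(area_profile("hOc1-like", layers, columnarity = 0.15))
  }
  layers <- dplyr::bind_rows(
    layer_spec("I",   0.10,  300, 2.5, 0.5, 95),
    layer_spec("II",  0.08, 5500, 3.0, 0.6, 70),
    layer_spec("III", 0.30, 3200, 3.6, 0.8, 65, cell_radius_mean_deep = 5.5),
    layer_spec("IV",  0.08, 7000, 3.0, 0.6, 65),
    layer_spec("V",   0.14, 2600, 4.0, 0.8, 70),
    layer_spec("VI",  0.30, 3600, 3.8, 0.7, 62)
  )
  area_profile("hOc2-like", layers, columnarity = 0.45)
}
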