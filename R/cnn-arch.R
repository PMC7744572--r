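# Dual-branch contracting/expanding segmentation architecture:
# unit bookkeeping, patch geometry and balanced patch sampling.

#' Default dual-branch segmentation architecture
#'
#' The full-size architecture consists of 10 blocks holding 24
#' unit-bearing network layers: a high-resolution and a low-resolution
#' contracting branch of 3 blocks each (two 3x3 convolutions followed by
#' 2x2 max pooling per block) and a single expanding branch of 4 blocks
#' (an up-convolution plus two convolutions per block, with the
#' high-resolution contracting outputs joined in by skip connections).
#' Every convolution is followed by batch normalisation and a rectified
#' linear unit.  Each branch carries 864 units, 2592 per network
#' instance; network layers are numbered 1-6 (high-res contracting),
#' 7-12 (low-res contracting) and 13-24 (expanding).
#'
#' The default per-layer unit split — contracting blocks
#' (64,64), (128,128), (240,240); expanding blocks of (128), (96), (48)
#' and (16) units per layer — is a package choice constrained by the
#' per-branch total of 864.
#'
#' `scale < 1` produces a desk-scale variant: unit counts are scaled
#' (with a floor of `min_units`) and the patch edge lengths are scaled
#' accordingly, while the physical resolutions (2 and 16 um/px) are kept,
#' so the reduced model sees a smaller field of view at full detail.
#'
#' @param scale Capacity/patch scale factor (1 = full size; default
#'   desk-scale runs use 1/8 or smaller).
#' @param min_units Lower bound on units per layer in scaled variants.
#' @param hr_patch_px,hr_res_um High-resolution patch edge (px) and
#'   resolution (um/px) at full scale.
#' @param lr_patch_px,lr_res_um Low-resolution patch geometry.
#' @param n_classes Segmentation classes (area of interest, other
#'   cortex, white matter, background).
#' @return An `arch_config`: list with a per-layer `layers` tibble
#'   (`branch`, `block`, `layer_in_block`, `kind`, `units`,
#'   `network_layer`) and the patch geometry.
#' @export
default_architecture <- function(scale = 1, min_units = 8L,
                                 hr_patch_px = 2025L, hr_res_um = 2,
                                 lr_patch_px = 1123L, lr_res_um = 16,
                                 n_classes = 4L) {
  hr_units <- c(64L, 64L, 128L, 128L, 240L, 240L)
  exp_units <- rep(c(128L, 96L, 48L, 16L), each = 3L)
  contracting <- function(branch, units, nl0) tibble::tibble(
    branch = branch, block = rep(1:3, each = 2), layer_in_block = rep(1:2, 3),
    kind = "conv", units = units, network_layer = nl0 + 0:5)
  expanding <- tibble::tibble(
    branch = "exp", block = rep(1:4, each = 3), layer_in_block = rep(1:3, 4),
    kind = rep(c("upconv", "conv", "conv"), 4),
    units = exp_units, network_layer = 13:24)
  layers <- dplyr::bind_rows(contracting("hr", hr_units, 1L),
                             contracting("lr", hr_units, 7L),
                             expanding)
  if (scale != 1) {
    layers$units <- pmax(as.integer(min_units), as.integer(round(layers$units * scale)))
    hr_patch_px <- max(32L, as.integer(round(hr_patch_px * scale / 8)) * 8L)
    lr_patch_px <- max(16L, as.integer(round(lr_patch_px * scale / 4)) * 4L)
  }
  structure(list(layers = layers, scale = scale,
                 hr_patch_px = as.integer(hr_patch_px), hr_res_um = hr_res_um,
                 lr_patch_px = as.integer(lr_patch_px), lr_res_um = lr_res_um,
                 n_classes = as.integer(n_classes)),
            class = "arch_config")
}

#' Validate and describe a network architecture
#'
#' Checks the structural invariants of the dual-branch architecture
#' (block and layer counts; at full scale, 864 units per branch and 2592
#' in total) and returns an enumerated description of every layer
#' including skip-connection wiring.
#'
#' @param config An `arch_config` from [default_architecture()].
#' @return An object of class `cnn_architecture`: the validated config
#'   plus a `description` tibble and unit totals.
#' @export
build_architecture <- function(config) {
  if (!inherits(config, "arch_config")) abort("`config` must be an arch_config.")
  ly <- config$layers
  branch_tot <- tapply(as.integer(ly$units), ly$branch, sum)
  n_blocks <- sum(!duplicated(ly[, c("branch", "block")]))
  if (n_blocks != 10L) abort(sprintf("Expected 10 blocks, found %d.", n_blocks))
  if (nrow(ly) != 24L) abort(sprintf("Expected 24 network layers, found %d.", nrow(ly)))
  if (any(ly$units < 1)) abort("Every layer needs at least one unit.")
  if (config$scale == 1) {
    bad <- names(branch_tot)[branch_tot != 864]
    if (length(bad) > 0L)
      abort(sprintf("Unit allocation of branch '%s' sums to %d, expected 864.",
                    bad[1], branch_tot[[bad[1]]]))
    if (sum(ly$units) != 2592L)
      abort(sprintf("Total units %d, expected 2592.", sum(ly$units)))
  }
  desc <- dplyr::mutate(
    ly,
    skip_from = dplyr::case_when(
      branch == "exp" & block == 1 & layer_in_block == 1 ~ "hr block 3 + lr junction",
      branch == "exp" & layer_in_block == 2 & block > 1 ~
        paste0("hr block ", 5 - block, " skip"),
      TRUE ~ NA_character_))
  structure(list(config = config, description = desc,
                 units_per_branch = lapply(as.list(branch_tot), as.integer),
                 total_units = as.integer(sum(ly$units))),
            class = "cnn_architecture")
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf("<cnn_architecture>  scale %.4g; units hr/lr/exp = %d/%d/%d (total %d)\n",
              x$config$scale, x$units_per_branch$hr, x$units_per_branch$lr,
              x$units_per_branch$exp, x$total_units))
  cat(sprintf("  hr patch %d px @ %g um/px (%.2f mm), lr patch %d px @ %g um/px (%.2f mm)\n",
              x$config$hr_patch_px, x$config$hr_res_um,
              field_of_view(x$config$hr_patch_px, x$config$hr_res_um),
              x$config$lr_patch_px, x$config$lr_res_um,
              field_of_view(x$config$lr_patch_px, x$config$lr_res_um)))
  invisible(x)
}

#' Field of view of a patch
#'
#' @param patch_px Patch edge length in pixels.
#' @param resolution_um_per_px Micrometres per pixel.
#' @return Extent in millimetres, rounded to 2 decimals.
#' @export
#' @examples
#' field_of_view(2025, 2)   # 4.05
#' field_of_view(1123, 16)  # 17.97
field_of_view <- function(patch_px, resolution_um_per_px) {
  if (any(patch_px <= 0) || any(resolution_um_per_px <= 0))
    abort("`patch_px` and `resolution_um_per_px` must be positive.")
  round(patch_px * resolution_um_per_px / 1000, 2)
}

# Four-class ground truth: 1 = area of interest, 2 = other cortex,
# 3 = white matter, 4 = background.
phantom_class_map <- function(phantom, aoi = 1L) {
  al <- phantom$area_labels
  wm_code <- phantom$areas$code[phantom$areas$name == "WM"]
  cm <- matrix(4L, nrow(al), ncol(al))
  cortex <- al != 0L & al != wm_code
  cm[cortex] <- 2L
  cm[al == aoi] <- 1L
  cm[al == wm_code] <- 3L
  cm
}

#' Sample balanced training patches from a phantom
#'
#' Draws exactly `n_per_class` patch centres from each of the four
#' classes (area of interest, other cortex, white matter, background),
#' restricted to centres whose high-resolution patch lies fully inside
#' the image.  Deterministic given `seed`.
#'
#' @param phantom A [render_phantom()] result.
#' @param n_per_class Patches per class.
#' @param seed Integer seed.
#' @param arch An `arch_config` (patch geometry).
#' @param aoi Area code treated as the area of interest.
#' @return A tibble of class `patch_samples` with `class`, `row`, `col`
#'   (patch centres, 1-based pixels); attributes `arch` and `aoi`.
#' @export
sample_patches <- function(phantom, n_per_class, seed, arch, aoi = 1L) {
  cm <- phantom_class_map(phantom, aoi)
  half <- arch$hr_patch_px %/% 2
  nr <- nrow(cm); nc <- ncol(cm)
  ok <- matrix(FALSE, nr, nc)
  if (nr < arch$hr_patch_px || nc < arch$hr_patch_px)
    abort("Phantom is smaller than one high-resolution patch.")
  ok[(half + 1):(nr - half), (half + 1):(nc - half)] <- TRUE
  class_names <- c("area_of_interest", "other_cortex", "white_matter", "background")
  out <- withr::with_seed(as.integer(seed), {
    purrr::map(1:4, function(k) {
      idx <- which(cm == k & ok)
      if (length(idx) == 0L)
        abort(sprintf("Class '%s' is absent from the usable part of the phantom.",
                      class_names[k]))
      pick <- sample(idx, n_per_class, replace = length(idx) < n_per_class)
      tibble::tibble(class = class_names[k], class_id = k,
                     row = ((pick - 1L) %% nr) + 1L,
                     col = ((pick - 1L) %/% nr) + 1L)
    })
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("patch_samples", class(res))
  attr(res, "arch") <- arch
  attr(res, "aoi") <- aoi
  res
}
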