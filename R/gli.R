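#' Binarize cell bodies in a histology-style image
#'
#' Cells stain dark on a light background, so the foreground is every
#' pixel *strictly darker* than the threshold.  When `threshold` is `NULL`
#' it is chosen by Otsu's criterion on the 256-level histogram; the value
#' actually used is always attached to the result (attribute
#' `"threshold"`) so the binarization is reproducible.
#'
#' @param image Integer/numeric matrix of greyscale values in `[0, 255]`,
#'   or a [render_phantom()] result (its `$image` is used).
#' @param threshold Greyscale cut in `[0, 255]`, or `NULL` for Otsu.
#' @return Logical matrix of the same dimensions (`TRUE` = cell body),
#'   with attribute `threshold`.
#' @export
binarize_cells <- function(image, threshold = NULL) {
  if (inherits(image, "cortical_phantom")) image <- image$image
  if (!is.matrix(image) || length(image) == 0L)
    abort("`image` must be a non-empty greyscale matrix.")
  if (is.null(threshold)) {
    threshold <- 255 * EBImage::otsu(EBImage::as.Image(t(image) / 255),
                                     range = c(0, 1), levels = 256)
  }
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 255)
    abort("`threshold` must be a single value in [0, 255].")
  mask <- image < threshold
  attr(mask, "threshold") <- threshold
  mask
}

#' Compute the grey level index image
#'
#' The grey level index (GLI) is the volume fraction of cell bodies in
#' small square measuring fields (default 20 x 20 um): the fraction of
#' foreground pixels in each field.  Trailing partial fields at the right
#' and bottom image edge are discarded so that every field has equal
#' area, as the volume-fraction definition requires.
#'
#' @param mask Logical (or 0/1) matrix from [binarize_cells()].
#' @param field_size_um Measuring-field edge length in micrometres.
#' @param resolution_um_per_px Micrometres per pixel of the source image.
#'   `field_size_um / resolution_um_per_px` must be a positive integer.
#' @return An object of class `gli_image`: list with `values` (matrix of
#'   fractions in `[0, 1]`), `field_size_um`, `resolution_um_per_px` and
#'   the source image dimensions.
#' @export
compute_gli <- function(mask, field_size_um = 20, resolution_um_per_px) {
  if (!is.matrix(mask) || length(mask) == 0L)
    abort("`mask` must be a non-empty binary matrix.")
  stopifnot_scalar(field_size_um, "field_size_um")
  stopifnot_scalar(resolution_um_per_px, "resolution_um_per_px")
  fpx <- field_size_um / resolution_um_per_px
  if (fpx <= 0 || abs(fpx - round(fpx)) > 1e-9)
    abort(sprintf(paste0("field_size_um / resolution (= %.4f px) must be a ",
                         "positive integer; resample the image so that the ",
                         "measuring field is a whole number of pixels."), fpx))
  fpx <- as.integer(round(fpx))
  if (nrow(mask) < fpx || ncol(mask) < fpx)
    abort("Image is smaller than a single measuring field.")
  values <- block_mean(matrix(as.numeric(mask), nrow(mask), ncol(mask)), fpx)
  structure(list(values = values, field_size_um = field_size_um,
                 resolution_um_per_px = resolution_um_per_px,
                 field_px = fpx,
                 source_dim = dim(mask)),
            class = "gli_image")
}

#' @export
print.gli_image <- function(x, ...) {
  cat(sprintf("<gli_image>  %d x %d fields of %g um (%d px); mean GLI %.3f\n",
              nrow(x$values), ncol(x$values), x$field_size_um, x$field_px,
              mean(x$values)))
  invisible(x)
}
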