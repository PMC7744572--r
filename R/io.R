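# Plain-file interchange: TIFF images, JSON sidecars, CSV tables.

#' Write a phantom to disk
#'
#' The image is written as 8-bit TIFF, the masks as 16-bit TIFFs,
#' contours / border positions / lookup tables as JSON, and the render
#' configuration as a flat key-value file.
#'
#' @param phantom A [render_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(phantom$image / 255, file.path(dir, "image.tif"),
                  bits.per.sample = 8)
  tiff::writeTIFF(matrix(as.numeric(phantom$cell_mask), nrow(phantom$cell_mask)) ,
                  file.path(dir, "cell_mask.tif"), bits.per.sample = 8)
  tiff::writeTIFF(phantom$layer_labels / 65535, file.path(dir, "layer_labels.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(phantom$area_labels / 65535, file.path(dir, "area_labels.tif"),
                  bits.per.sample = 16)
  jsonlite::write_json(
    list(outer_contour = phantom$outer_contour,
         inner_contour = phantom$inner_contour,
         true_border = phantom$true_border,
         layers = phantom$layers, areas = phantom$areas),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  cfg <- phantom$config
  writeLines(paste0(names(cfg), " = ", unlist(lapply(cfg, as.character))),
             file.path(dir, "render_config.txt"))
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir Directory written by [write_phantom()].
#' @return A list with the image, masks and ground-truth tables (the
#'   same fields as a `cortical_phantom`, minus the geometry closure).
#' @export
read_phantom <- function(dir) {
  rd <- function(f, scale) {
    m <- tiff::readTIFF(file.path(dir, f))
    matrix(as.integer(round(m * scale)), nrow(m), ncol(m))
  }
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  list(image = rd("image.tif", 255),
       cell_mask = rd("cell_mask.tif", 255) > 0,
       layer_labels = rd("layer_labels.tif", 65535),
       area_labels = rd("area_labels.tif", 65535),
       outer_contour = tibble::as_tibble(gt$outer_contour),
       inner_contour = tibble::as_tibble(gt$inner_contour),
       true_border = tibble::as_tibble(gt$true_border),
       layers = tibble::as_tibble(gt$layers),
       areas = tibble::as_tibble(gt$areas))
}

#' Write / read a GLI image (32-bit float TIFF plus JSON metadata)
#'
#' @param gli A [compute_gli()] result.
#' @param path Output TIFF path; a `.json` sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_gli <- function(gli, path) {
  tiff::writeTIFF(gli$values, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(field_size_um = gli$field_size_um,
                            resolution_um_per_px = gli$resolution_um_per_px,
                            field_px = gli$field_px,
                            source_dim = gli$source_dim),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gli
#' @export
read_gli <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(values = tiff::readTIFF(path),
                 field_size_um = meta$field_size_um,
                 resolution_um_per_px = meta$resolution_um_per_px,
                 field_px = meta$field_px,
                 source_dim = meta$source_dim),
            class = "gli_image")
}

#' Write profiles as a wide CSV (one row per traverse, p000...)
#'
#' @param profiles A [sample_profiles()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  m <- profile_matrix(profiles)
  colnames(m) <- sprintf("p%03d", seq_len(ncol(m)) - 1L)
  utils::write.csv(data.frame(traverse = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Persist the machine-readable part of a pipeline report
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    schema = report$config$schema,
    seed = report$config$seed,
    threshold_used = report$threshold_used,
    n_traverses = report$n_traverses,
    contour_length_um = report$contour_length_um,
    confirmed_borders = report$borders$confirmed,
    window_maxima = report$borders$maxima,
    agreement_truth = report$agreement_truth,
    dice_aoi = report$dice_aoi,
    characteristic_per_layer = if (!is.null(report$characteristic))
      as.list(table(report$characteristic$network_layer[report$characteristic$characteristic])),
    levels = if (!is.null(report$levels))
      report$levels[, c("map", "network_layer", "score_cell", "score_layer",
                        "score_area", "level")],
    parameters = report$config[c("synth", "gli", "traverses", "borders")])
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  write_profiles_csv(report$profiles, file.path(dir, "profiles.csv"))
  invisible(dir)
}
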