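# End-to-end orchestration: phantom -> GLI -> traverses -> features ->
# borders, optionally followed by CNN training and activation analysis.

#' Assemble a pipeline configuration
#'
#' All stage parameters in one serializable list.  A single global seed
#' fans out to per-stage seeds by fixed offsets, so each stage is
#' independently reproducible.
#'
#' @param seed Global integer seed.
#' @param presets Area preset names placed along the ribbon.
#' @param width_px,height_px,resolution_um,cortical_thickness_um,geometry,noise_sd
#'   Phantom rendering parameters (see [render_config()]).
#' @param field_size_um GLI measuring-field edge.
#' @param threshold Binarization threshold or `NULL` for Otsu.
#' @param spacing_um Traverse spacing along the outer contour.
#' @param n_points Depth samples per profile.
#' @param solve_spacing_um Grid spacing of the Laplace solve.
#' @param tol Laplace residual tolerance.
#' @param window_sizes,confirm_fraction,alpha,shrinkage Border detection
#'   parameters (see [find_borders()]).
#' @param cnn Logical: run the CNN stage (training, activation
#'   extraction, MI, feature levels).
#' @param cnn_scale Desk-scale factor for [default_architecture()].
#' @param cnn_epochs,cnn_n_per_class,cnn_lr Training parameters.
#' @param cnn_window_px Activation-analysis window edge.
#' @param arch Optional explicit `arch_config` (otherwise built from
#'   `cnn_scale`).
#' @param out_dir Optional output directory for report artifacts.
#' @return A list of class `cortexmap_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            presets = c("hOc1-like", "hOc2-like"),
                            width_px = 1600L, height_px = 1200L,
                            resolution_um = 2, cortical_thickness_um = 2000,
                            geometry = "flat", noise_sd = 6,
                            field_size_um = 20, threshold = NULL,
                            spacing_um = 40, n_points = 100L,
                            solve_spacing_um = 20, tol = 1e-4,
                            window_sizes = 12:24, confirm_fraction = 0.8,
                            alpha = 0.05, shrinkage = 0,
                            cnn = FALSE, cnn_scale = 1 / 32,
                            cnn_epochs = 6L, cnn_n_per_class = 32L,
                            cnn_lr = 1e-3, cnn_window_px = 384L,
                            arch = NULL, out_dir = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    synth = list(presets = presets, width_px = width_px, height_px = height_px,
                 resolution_um = resolution_um,
                 cortical_thickness_um = cortical_thickness_um,
                 geometry = geometry, noise_sd = noise_sd),
    gli = list(field_size_um = field_size_um, threshold = threshold),
    traverses = list(spacing_um = spacing_um, n_points = n_points,
                     solve_spacing_um = solve_spacing_um, tol = tol),
    borders = list(window_sizes = window_sizes,
                   confirm_fraction = confirm_fraction,
                   alpha = alpha, shrinkage = shrinkage),
    cnn = list(enabled = isTRUE(cnn), scale = cnn_scale, epochs = cnn_epochs,
               n_per_class = cnn_n_per_class, lr = cnn_lr,
               window_px = cnn_window_px, arch = arch),
    out_dir = out_dir,
    schema = "cortexmap-report-1")
  class(cfg) <- "cortexmap_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return A tibble of violations (`field`, `constraint`); empty when
#'   the configuration satisfies all module invariants.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, constraint)
    v[[length(v) + 1]] <<- tibble::tibble(field = field, constraint = constraint)
  s <- config$synth
  if (s$resolution_um <= 0) bad("synth.resolution_um", "must be positive")
  if (config$gli$field_size_um <= 0) bad("gli.field_size_um", "must be positive")
  else {
    fpx <- config$gli$field_size_um / s$resolution_um
    if (abs(fpx - round(fpx)) > 1e-9)
      bad("gli.field_size_um", "must be an integer number of pixels")
  }
  if (config$traverses$spacing_um <= 0) bad("traverses.spacing_um", "must be positive")
  if (config$traverses$n_points < 3) bad("traverses.n_points", "must be at least 3")
  b <- config$borders
  if (any(b$window_sizes < 2)) bad("borders.window_sizes", "window sizes must be >= 2")
  if (b$confirm_fraction <= 0 || b$confirm_fraction > 1)
    bad("borders.confirm_fraction", "must lie in (0, 1]")
  if (b$alpha <= 0 || b$alpha >= 1) bad("borders.alpha", "must lie in (0, 1)")
  arch <- config$cnn$arch
  if (!is.null(arch)) {
    tot <- tapply(arch$layers$units, arch$layers$branch, sum)
    if (arch$scale == 1) {
      for (br in names(tot)) if (tot[[br]] != 864)
        bad(paste0("cnn.arch.", br),
            sprintf("branch '%s' units sum to %d, expected 864", br, tot[[br]]))
    }
    if (any(arch$layers$units < 1)) bad("cnn.arch", "every layer needs >= 1 unit")
  }
  needed <- s$cortical_thickness_um + 360  # margins above and below
  if (needed > s$height_px * s$resolution_um)
    bad("synth.cortical_thickness_um", "cortex does not fit the image height")
  if (length(v) == 0)
    tibble::tibble(field = character(), constraint = character())
  else dplyr::bind_rows(v)
}

# Preset list with unique area ids (duplicated presets, e.g. in a
# null configuration with two identical areas, get an index suffix).
preset_profiles <- function(presets) {
  profs <- purrr::map(presets, make_preset_profile)
  if (anyDuplicated(presets)) {
    for (i in seq_along(profs))
      profs[[i]]$area_id <- paste0(profs[[i]]$area_id, "#", i)
  }
  profs
}

# Coarse Laplace domain and scaled contours for a phantom.
phantom_laplace_field <- function(phantom, solve_spacing_um, tol = 1e-4) {
  res <- phantom$config$resolution_um
  k <- solve_spacing_um / res
  if (abs(k - round(k)) > 1e-9)
    abort("`solve_spacing_um` must be an integer number of pixels.")
  k <- as.integer(round(k))
  nrf <- nrow(phantom$area_labels); ncf <- ncol(phantom$area_labels)
  nr <- nrf %/% k; nc <- ncf %/% k
  ri <- pmin(round((seq_len(nr) - 0.5) * k + 0.5), nrf)
  ci <- pmin(round((seq_len(nc) - 0.5) * k + 0.5), ncf)
  al <- phantom$area_labels[ri, ci]
  ll <- phantom$layer_labels[ri, ci]
  wm_code <- phantom$areas$code[phantom$areas$name == "WM"]
  l1_codes <- phantom$layers$code[phantom$layers$name == "I"]
  domain <- al != 0L & al != wm_code & !(ll %in% l1_codes)
  scale_contour <- function(ct) dplyr::mutate(ct, x = (x + 0.5) / k - 0.5,
                                              y = (y + 0.5) / k - 0.5)
  field <- solve_laplace(domain, scale_contour(phantom$outer_contour),
                         scale_contour(phantom$inner_contour), tol = tol)
  attr(field, "spacing_um") <- k * res
  field
}

# Ground-truth border positions on the traverse index axis.
true_border_positions <- function(phantom, seed_arc_um) {
  if (nrow(phantom$true_border) == 0) return(numeric(0))
  stats::approx(seed_arc_um, seq_along(seed_arc_um),
                phantom$true_border$u_um, rule = 2)$y
}

#' Run the full analysis pipeline on a synthetic phantom
#'
#' Executes phantom synthesis, GLI computation, Laplace traverses,
#' profile features and border detection; when `config$cnn$enabled`,
#' additionally trains the desk-scale segmenter on companion phantoms,
#' evaluates it on the main phantom, and runs the activation analysis
#' (mutual information, characteristic filters, feature levels, CNN
#' border estimate).
#'
#' @param config A [pipeline_config()].
#' @return An object of class `cortexmap_report`.
#' @export
run_pipeline <- function(config) {
  viol <- validate_config(config)
  if (nrow(viol) > 0)
    abort(paste0("Invalid configuration: ",
                 paste(viol$field, viol$constraint, sep = ": ", collapse = "; ")))
  s <- config$synth
  stage <- "synth"
  report <- tryCatch({
    profiles_areas <- preset_profiles(s$presets)
    rc <- render_config(resolution_um = s$resolution_um, width_px = s$width_px,
                        height_px = s$height_px,
                        cortical_thickness_um = s$cortical_thickness_um,
                        geometry = s$geometry, noise_sd = s$noise_sd,
                        seed = config$seed)
    phantom <- render_phantom(profiles_areas, rc)

    stage <- "gli"
    mask <- binarize_cells(phantom$image, config$gli$threshold)
    gli <- compute_gli(mask, config$gli$field_size_um, s$resolution_um)

    stage <- "traverses"
    field <- phantom_laplace_field(phantom, config$traverses$solve_spacing_um,
                                   config$traverses$tol)
    spacing_um <- attr(field, "spacing_um")
    contour_um <- polyline_point(field$outer, 0)$total * spacing_um
    n_trav <- max(2L, floor(contour_um / config$traverses$spacing_um))
    trv <- trace_traverses(field, n_trav)

    stage <- "profiles"
    prof <- sample_profiles(gli, trv, config$traverses$n_points,
                            traverse_resolution_um = spacing_um)

    stage <- "features"
    feats <- profile_features(prof)

    stage <- "borders"
    borders <- find_borders(feats, config$borders$window_sizes,
                            config$borders$confirm_fraction,
                            config$borders$alpha, config$borders$shrinkage)
    seed_arc_um <- attr(prof, "seed_arc_um")
    truth_pos <- true_border_positions(phantom, seed_arc_um)
    agreement <- border_agreement(borders$confirmed$position, truth_pos,
                                  seed_arc_um)
    out <- list(config = config, phantom = phantom, gli = gli, field = field,
                traverses = trv, profiles = prof, features = feats,
                borders = borders, truth_positions = truth_pos,
                agreement_truth = agreement,
                threshold_used = attr(mask, "threshold"),
                n_traverses = length(seed_arc_um),
                contour_length_um = contour_um)

    if (config$cnn$enabled) {
      stage <- "cnn"
      out <- c(out, run_cnn_stage(config, phantom, borders, seed_arc_um))
    }
    out
  }, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          parent = e, class = "cortexmap_stage_error")
  })
  class(report) <- "cortexmap_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

run_cnn_stage <- function(config, phantom, borders, seed_arc_um) {
  arch <- config$cnn$arch %||% default_architecture(scale = config$cnn$scale)
  s <- config$synth
  train_cfg <- render_config(
    resolution_um = s$resolution_um, width_px = s$width_px,
    height_px = s$height_px, cortical_thickness_um = s$cortical_thickness_um,
    geometry = s$geometry, noise_sd = s$noise_sd, seed = config$seed + 101L)
  train_ph <- render_phantom(preset_profiles(s$presets), train_cfg)
  seg <- train_segmenter(train_ph, arch, aoi = 1L,
                         n_per_class = config$cnn$n_per_class,
                         epochs = config$cnn$epochs, lr = config$cnn$lr,
                         seed = config$seed + 2000L)
  pred <- predict(seg, phantom)
  cmap <- phantom_class_map(phantom, aoi = 1L)
  cortex <- cmap <= 2L
  dice <- dice_score(pred, cmap, class = 1L, within = cortex)

  aa <- analyse_activations(seg, phantom, window_px = config$cnn$window_px)

  cnn_pos <- cnn_border_positions(pred, phantom, seed_arc_um)
  agree_gli <- border_agreement(borders$confirmed$position, cnn_pos,
                                seed_arc_um)
  list(segmenter = seg, dice_aoi = dice,
       activation_stack_meta = aa$stack$window,
       mi = aa$mi, characteristic = aa$characteristic, levels = aa$levels,
       cnn_border_positions = cnn_pos, agreement_gli_cnn = agree_gli)
}

# Mid-depth point above/below the first true border (or image centre).
analysis_center <- function(phantom) {
  if (nrow(phantom$true_border) == 0)
    return(c(nrow(phantom$image) %/% 2L, ncol(phantom$image) %/% 2L))
  tb <- phantom$true_border[1, ]
  geom <- phantom$geometry
  xy <- geom$xy_from_uv(tb$u_um, geom$T * 0.5)
  res <- phantom$config$resolution_um
  c(as.integer(round(xy$y / res)), as.integer(round(xy$x / res)))
}

# Border positions implied by the predicted segmentation: transitions of
# the majority class along mid-depth points of the traverse seeds.
cnn_border_positions <- function(pred, phantom, seed_arc_um) {
  geom <- phantom$geometry
  res <- phantom$config$resolution_um
  depths <- geom$T * c(0.3, 0.5, 0.7)
  votes <- vapply(seed_arc_um, function(u) {
    xy <- geom$xy_from_uv(rep(u, length(depths)), depths)
    r <- pmin(pmax(round(xy$y / res), 1), nrow(pred))
    c2 <- pmin(pmax(round(xy$x / res), 1), ncol(pred))
    cls <- pred[cbind(r, c2)]
    mean(cls == 1L) >= 0.5
  }, logical(1))
  which(diff(votes) != 0) + 1L
}

#' @export
print.cortexmap_report <- function(x, ...) {
  cat("<cortexmap_report>\n")
  cat(sprintf("  %d traverses over %.2f mm of cortex; binarization threshold %.1f\n",
              x$n_traverses, x$contour_length_um / 1000, x$threshold_used))
  nb <- nrow(x$borders$confirmed)
  cat(sprintf("  confirmed GLI borders: %d", nb))
  if (nb > 0)
    cat(sprintf(" at position(s) %s", paste(x$borders$confirmed$position, collapse = ", ")))
  cat("\n")
  if (nrow(x$agreement_truth) > 0 && any(x$agreement_truth$matched))
    cat(sprintf("  distance to true border: %s um\n",
                paste(round(x$agreement_truth$distance_um[x$agreement_truth$matched]),
                      collapse = ", ")))
  if (!is.null(x$dice_aoi)) {
    cat(sprintf("  CNN: held-out area Dice %.3f; %d/%d characteristic maps; levels: %s\n",
                x$dice_aoi, sum(x$characteristic$characteristic),
                nrow(x$characteristic),
                paste(names(table(x$levels$level)), table(x$levels$level),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `cortexmap_report`.
#' @param ... Unused.
#' @export
glance.cortexmap_report <- function(x, ...) {
  tibble::tibble(
    n_traverses = x$n_traverses,
    n_confirmed_borders = nrow(x$borders$confirmed),
    border_error_um = if (any(x$agreement_truth$matched))
      min(x$agreement_truth$distance_um, na.rm = TRUE) else NA_real_,
    threshold = x$threshold_used,
    dice_aoi = x$dice_aoi %||% NA_real_,
    seed = x$config$seed)
}
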