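#' Rendering configuration for a synthetic cortical phantom
#'
#' @param resolution_um Micrometres per pixel (default 2, matching
#'   high-resolution histology patches).
#' @param width_px,height_px Image size in pixels.
#' @param cortical_thickness_um Cortical depth from the pial surface to
#'   the grey/white matter boundary, in micrometres.
#' @param geometry `"flat"` (rectangular ribbon) or `"arc"` (annulus
#'   sector bulging downwards).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise in
#'   greyscale units (applied after rendering, then clipped to `[0, 255]`).
#' @param seed Integer seed fixing all randomness of the phantom.
#' @param pia_margin_um Background band above the pial surface.
#' @param wm_band_um Thickness of the rendered white-matter band below
#'   the cortex.
#' @param background Greyscale value of unstained tissue and empty
#'   background (must be `>= 200`; cells are darker).
#' @param wm_cell_density Areal density (per mm^2) of small faint glial
#'   cell bodies rendered in the white-matter band, giving it a texture
#'   distinct from the empty background.
#' @param arc_radius_um Pial radius of curvature for the `"arc"` geometry.
#'
#' @return A list of class `render_config`.
#' @export
render_config <- function(resolution_um = 2, width_px = 1600, height_px = 1200,
                          cortical_thickness_um = 2000,
                          geometry = c("flat", "arc"), noise_sd = 6, seed = 1L,
                          pia_margin_um = 80, wm_band_um = 280,
                          background = 242, wm_cell_density = 800,
                          arc_radius_um = 6000) {
  geometry <- match.arg(geometry)
  stopifnot_scalar(resolution_um, "resolution_um")
  if (resolution_um <= 0) abort("`resolution_um` must be positive.")
  if (background < 200) abort("`background` must be >= 200 (cells stain dark on a light background).")
  cfg <- list(resolution_um = resolution_um, width_px = as.integer(width_px),
              height_px = as.integer(height_px),
              cortical_thickness_um = cortical_thickness_um,
              geometry = geometry, noise_sd = noise_sd, seed = as.integer(seed),
              pia_margin_um = pia_margin_um, wm_band_um = wm_band_um,
              background = background, wm_cell_density = wm_cell_density,
              arc_radius_um = arc_radius_um)
  class(cfg) <- "render_config"
  cfg
}

# Geometry bookkeeping shared by rendering and contour construction.
# u: arc-length coordinate along the layer I/II contour (um, from 0)
# v: depth below the pial surface (um)
phantom_geometry <- function(config, frac_I) {
  res <- config$resolution_um
  w_um <- config$width_px * res
  h_um <- config$height_px * res
  T <- config$cortical_thickness_um
  if (config$geometry == "flat") {
    needed <- config$pia_margin_um + T + config$wm_band_um
    if (needed > h_um)
      abort(sprintf(paste0("Cortical thickness does not fit the image: ",
                           "need %.0f um of height, have %.0f um."), needed, h_um),
            class = "cortexmap_geometry_error")
    list(kind = "flat", u_max = w_um, frac_I = frac_I, T = T,
         pia = config$pia_margin_um,
         uv_from_xy = function(x_um, y_um) {
           list(u = x_um, v = y_um - config$pia_margin_um)
         },
         xy_from_uv = function(u, v) {
           list(x = u, y = v + config$pia_margin_um)
         },
         depth_angle = function(u) rep(pi / 2, length(u)))
  } else {
    r_pia <- config$arc_radius_um
    r_ref <- r_pia + frac_I * T
    theta_half <- (0.96 * w_um / 2) / r_ref
    cx <- w_um / 2
    cy <- config$pia_margin_um - r_pia * cos(theta_half)
    sagitta <- r_pia * (1 - cos(theta_half))
    needed <- config$pia_margin_um + sagitta + T + config$wm_band_um
    if (needed > h_um)
      abort(sprintf(paste0("Cortical thickness does not fit the image: ",
                           "need %.0f um of height, have %.0f um."), needed, h_um),
            class = "cortexmap_geometry_error")
    list(kind = "arc", u_max = 2 * theta_half * r_ref, frac_I = frac_I, T = T,
         r_pia = r_pia, r_ref = r_ref, theta_half = theta_half, cx = cx, cy = cy,
         uv_from_xy = function(x_um, y_um) {
           dx <- x_um - cx
           dy <- y_um - cy
           r <- sqrt(dx * dx + dy * dy)
           theta <- atan2(dx, dy)
           list(u = (theta + theta_half) * r_ref, v = r - r_pia)
         },
         xy_from_uv = function(u, v) {
           theta <- u / r_ref - theta_half
           r <- r_pia + v
           list(x = cx + r * sin(theta), y = cy + r * cos(theta))
         },
         depth_angle = function(u) {
           theta <- u / r_ref - theta_half
           atan2(cos(theta), sin(theta))
         })
  }
}

# Poisson point process for one layer of one area, with vertical-stripe
# (columnar) intensity modulation and a per-layer seed so that changing
# one layer leaves the others untouched.  The candidate stream is
# prefix-stable: increasing the density extends, never reshuffles, the
# drawn cells (count drawn by inverse-CDF from a single uniform).
sample_layer_cells <- function(u0, u1, v0, v1, density, columnarity,
                               radius_top, radius_deep, radius_sd, layer_seed,
                               column_period_um = 50) {
  area_mm2 <- (u1 - u0) * (v1 - v0) / 1e6
  lam <- density * area_mm2
  if (lam <= 0) {
    return(tibble::tibble(u = numeric(), v = numeric(), radius = numeric(),
                          aspect = numeric(), angle_jitter = numeric()))
  }
  withr::with_seed(layer_seed, {
    u_cnt <- runif(1)
    n_cand <- qpois(u_cnt, lam * (1 + columnarity))
    if (n_cand == 0L) {
      return(tibble::tibble(u = numeric(), v = numeric(), radius = numeric(),
                            aspect = numeric(), angle_jitter = numeric()))
    }
    u <- runif(n_cand, u0, u1)
    v <- runif(n_cand, v0, v1)
    acc <- runif(n_cand) <
      (1 + columnarity * cos(2 * pi * u / column_period_um)) / (1 + columnarity)
    rd <- if (is.na(radius_deep)) radius_top else radius_deep
    mean_r <- radius_top + (rd - radius_top) * (v - v0) / max(v1 - v0, 1e-9)
    radius <- pmax(rnorm(n_cand, mean_r, radius_sd), 0.8)
    aspect <- runif(n_cand, 1, 1.6)
    angle_jitter <- rnorm(n_cand, 0, 0.25)
    tibble::tibble(u = u[acc], v = v[acc], radius = radius[acc],
                   aspect = aspect[acc], angle_jitter = angle_jitter[acc])
  })
}

# Draw filled ellipses into the image (in place via returned matrices).
# Cells are area-preserving ellipses: semi-axes r*sqrt(a), r/sqrt(a),
# oriented along the local depth direction plus jitter, clipped to tissue.
draw_cells <- function(image, cell_mask, cells, intensity, tissue_ok, res) {
  nr <- nrow(image); nc <- ncol(image)
  if (nrow(cells) == 0L) return(list(image = image, cell_mask = cell_mask))
  xs <- cells$x_um / res - 0.5
  ys <- cells$y_um / res - 0.5
  r1 <- cells$radius * sqrt(cells$aspect) / res
  r2 <- cells$radius / sqrt(cells$aspect) / res
  phi <- cells$angle + cells$angle_jitter
  for (k in seq_len(nrow(cells))) {
    e <- r1[k] + 1
    c0 <- max(1L, as.integer(floor(xs[k] - e)) + 1L)
    c1 <- min(nc, as.integer(ceiling(xs[k] + e)) + 1L)
    rr0 <- max(1L, as.integer(floor(ys[k] - e)) + 1L)
    rr1 <- min(nr, as.integer(ceiling(ys[k] + e)) + 1L)
    if (c0 > c1 || rr0 > rr1) next
    dx <- ((c0:c1) - 1) - xs[k]
    dy <- ((rr0:rr1) - 1) - ys[k]
    ca <- cos(phi[k]); sa <- sin(phi[k])
    # rotated coordinates: major axis along depth direction
    A <- outer(dy * sa, dx * ca, "+") / r1[k]      # along-axis
    B <- outer(dy * ca, -dx * sa, "+") / r2[k]     # across-axis
    inside <- (A * A + B * B) <= 1
    if (!any(inside)) next
    sub_ok <- tissue_ok[rr0:rr1, c0:c1, drop = FALSE]
    sel <- inside & sub_ok
    if (!any(sel)) next
    img_sub <- image[rr0:rr1, c0:c1, drop = FALSE]
    msk_sub <- cell_mask[rr0:rr1, c0:c1, drop = FALSE]
    img_sub[sel] <- intensity
    msk_sub[sel] <- TRUE
    image[rr0:rr1, c0:c1] <- img_sub
    cell_mask[rr0:rr1, c0:c1] <- msk_sub
  }
  list(image = image, cell_mask = cell_mask)
}

#' Render a synthetic cortical ribbon phantom
#'
#' Places cell bodies by an inhomogeneous Poisson point process with
#' per-layer density (optionally modulated by a columnar stripe pattern),
#' draws them as filled ellipses at the layer's stain intensity on a light
#' background, adds Gaussian pixel noise, and returns the image together
#' with full ground truth: cell mask, per-pixel layer and area labels, the
#' layer I/II and grey/white matter contours, and the arc-length positions
#' of the area borders on the outer contour.
#'
#' The phantom is fully deterministic given `config$seed`; each
#' (area, layer) combination draws from its own derived seed, so editing
#' one layer's parameters leaves all other layers' cells unchanged.
#'
#' @param profiles A single [area_profile()] or a list of them, placed
#'   side by side along the cortical ribbon (equal arc-length extents).
#' @param config A [render_config()].
#'
#' @return An object of class `cortical_phantom` with elements `image`
#'   (integer matrix, 0-255), `cell_mask` (logical matrix), `layer_labels`
#'   and `area_labels` (integer matrices), `layers` and `areas` (lookup
#'   tibbles), `outer_contour`, `inner_contour` (tibbles with `u`, `x`,
#'   `y`; pixel coordinates are 0-based, pixel-centre convention),
#'   `true_border` (tibble with `u_um`, `x`, `y`), and `config`.
#' @export
#' @examples
#' cfg <- render_config(width_px = 300, height_px = 260,
#'                      cortical_thickness_um = 360, seed = 7)
#' ph <- render_phantom(list(make_preset_profile("hOc1-like"),
#'                           make_preset_profile("hOc2-like")), cfg)
#' mean(ph$cell_mask)
render_phantom <- function(profiles, config) {
  if (inherits(profiles, "area_profile")) profiles <- list(profiles)
  if (length(profiles) < 1L) abort("Need at least one area profile.")
  purrr::walk(profiles, validate_area_profile)
  if (anyDuplicated(purrr::map_chr(profiles, "area_id")))
    abort("Area ids must be unique within a phantom.")
  if (!inherits(config, "render_config")) abort("`config` must be a render_config().")

  res <- config$resolution_um
  nr <- config$height_px; nc <- config$width_px
  T <- config$cortical_thickness_um
  n_area <- length(profiles)
  frac_I1 <- profiles[[1]]$layers$thickness_fraction[1]
  geom <- phantom_geometry(config, frac_I1)

  # per-pixel physical coordinates (pixel centres)
  x_um <- matrix((seq_len(nc) - 0.5) * res, nr, nc, byrow = TRUE)
  y_um <- matrix((seq_len(nr) - 0.5) * res, nr, nc)
  uv <- geom$uv_from_xy(x_um, y_um)
  u <- uv$u; v <- uv$v

  u_max <- geom$u_max
  in_u <- u >= 0 & u <= u_max
  area_breaks <- seq(0, u_max, length.out = n_area + 1)

  wm_code <- n_area + 1L
  area_labels <- matrix(0L, nr, nc)
  cortex <- in_u & v >= 0 & v <= T
  a_idx <- pmin(pmax(findInterval(u[cortex], area_breaks,
                                  rightmost.closed = TRUE), 1L), n_area)
  area_labels[cortex] <- a_idx
  wm <- in_u & v > T & v <= T + config$wm_band_um
  area_labels[wm] <- wm_code

  # layer lookup across areas (+ a white-matter row)
  layer_rows <- purrr::imap(profiles, function(p, i) {
    dplyr::mutate(p$layers, area_id = p$area_id, area_code = i)
  })
  layers <- dplyr::bind_rows(layer_rows)
  layers$code <- seq_len(nrow(layers))
  layers <- dplyr::bind_rows(
    layers,
    tibble::tibble(name = "WM", thickness_fraction = NA_real_,
                   cell_density = config$wm_cell_density,
                   cell_radius_mean = 1.8, cell_radius_sd = 0.3,
                   stain_intensity = 120, cell_radius_mean_deep = NA_real_,
                   area_id = "WM", area_code = wm_code,
                   code = nrow(layers) + 1L))
  wm_layer_code <- layers$code[layers$name == "WM"]

  layer_labels <- matrix(0L, nr, nc)
  for (i in seq_len(n_area)) {
    ly <- profiles[[i]]$layers
    sel <- cortex & area_labels == i
    cum <- cumsum(ly$thickness_fraction)
    li <- pmin(findInterval(v[sel] / T, c(0, head(cum, -1)),
                            rightmost.closed = FALSE), nrow(ly))
    codes <- layers$code[layers$area_code == i]
    layer_labels[sel] <- codes[li]
  }
  layer_labels[wm] <- wm_layer_code

  tissue_ok <- area_labels != 0L
  image <- matrix(config$background, nr, nc)
  cell_mask <- matrix(FALSE, nr, nc)

  # cells, drawn area by area, layer by layer (later cells overwrite)
  for (i in seq_len(n_area)) {
    p <- profiles[[i]]
    ly <- p$layers
    cum <- c(0, cumsum(ly$thickness_fraction))
    for (j in seq_len(nrow(ly))) {
      cells <- sample_layer_cells(
        area_breaks[i], area_breaks[i + 1], cum[j] * T, cum[j + 1] * T,
        ly$cell_density[j], p$columnarity,
        ly$cell_radius_mean[j], ly$cell_radius_mean_deep[j],
        ly$cell_radius_sd[j],
        layer_seed = config$seed + 1009L * i + 31L * j)
      if (nrow(cells) > 0L) {
        xy <- geom$xy_from_uv(cells$u, cells$v)
        cells$x_um <- xy$x; cells$y_um <- xy$y
        cells$angle <- geom$depth_angle(cells$u)
        drawn <- draw_cells(image, cell_mask, cells, ly$stain_intensity[j],
                            tissue_ok, res)
        image <- drawn$image; cell_mask <- drawn$cell_mask
      }
    }
  }
  # white-matter glia
  wm_cells <- sample_layer_cells(0, u_max, T, T + config$wm_band_um,
                                 config$wm_cell_density, 0, 1.8, NA, 0.3,
                                 layer_seed = config$seed + 900007L)
  if (nrow(wm_cells) > 0L) {
    xy <- geom$xy_from_uv(wm_cells$u, wm_cells$v)
    wm_cells$x_um <- xy$x; wm_cells$y_um <- xy$y
    wm_cells$angle <- geom$depth_angle(wm_cells$u)
    drawn <- draw_cells(image, cell_mask, wm_cells, 120, tissue_ok, res)
    image <- drawn$image; cell_mask <- drawn$cell_mask
  }

  if (config$noise_sd > 0) {
    image <- withr::with_seed(config$seed + 424243L,
                              image + rnorm(nr * nc, 0, config$noise_sd))
  }
  image <- matrix(as.integer(round(pmin(pmax(image, 0), 255))), nr, nc)

  # contours (sampled every ~2 px of arc length)
  du <- 2 * res
  ug <- seq(0, u_max, by = du)
  frac_I_of_u <- function(uu) {
    ai <- pmin(pmax(findInterval(uu, area_breaks, rightmost.closed = TRUE), 1L), n_area)
    purrr::map_dbl(ai, ~ profiles[[.x]]$layers$thickness_fraction[1])
  }
  contour_tbl <- function(v_of_u) {
    xy <- geom$xy_from_uv(ug, v_of_u)
    tibble::tibble(u = ug, x = xy$x / res - 0.5, y = xy$y / res - 0.5)
  }
  outer_contour <- contour_tbl(frac_I_of_u(ug) * T)
  inner_contour <- contour_tbl(rep(T, length(ug)))

  tb <- if (n_area > 1) {
    ub <- area_breaks[2:n_area]
    xy <- geom$xy_from_uv(ub, frac_I_of_u(ub) * T)
    tibble::tibble(border = seq_along(ub), u_um = ub,
                   x = xy$x / res - 0.5, y = xy$y / res - 0.5)
  } else {
    tibble::tibble(border = integer(), u_um = numeric(),
                   x = numeric(), y = numeric())
  }

  structure(list(
    image = image, cell_mask = cell_mask,
    layer_labels = layer_labels, area_labels = area_labels,
    layers = layers,
    areas = tibble::tibble(
      code = c(0L, seq_len(n_area), wm_code),
      name = c("background", purrr::map_chr(profiles, "area_id"), "WM")),
    outer_contour = outer_contour, inner_contour = inner_contour,
    true_border = tb, profiles = profiles, config = config,
    geometry = geom
  ), class = "cortical_phantom")
}

#' @export
print.cortical_phantom <- function(x, ...) {
  cat(sprintf("<cortical_phantom>  %d x %d px at %g um/px (%s geometry)\n",
              nrow(x$image), ncol(x$image), x$config$resolution_um,
              x$config$geometry))
  cat(sprintf("  areas: %s | cortical thickness %g um | %d area border(s)\n",
              paste(setdiff(x$areas$name, c("background", "WM")), collapse = ", "),
              x$config$cortical_thickness_um, nrow(x$true_border)))
  cat(sprintf("  cell pixels: %.1f%%\n", 100 * mean(x$cell_mask)))
  invisible(x)
}
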