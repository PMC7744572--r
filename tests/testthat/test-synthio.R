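test_that("presets encode the stated laminar rank-order relations", {
  p1 <- make_preset_profile("hOc1-like")
  p2 <- make_preset_profile("hOc2-like")
  l1 <- p1$layers
  d_ivc <- l1$cell_density[l1$name == "IVc"]
  expect_true(all(d_ivc > l1$cell_density[l1$name != "IVc"]))
  mid <- l1$name %in% c("II", "III", "IVa", "IVb", "IVc", "VI")
  expect_true(all(l1$cell_density[l1$name == "V"] < l1$cell_density[mid]))
  # hOc2: exactly one undivided layer IV, thinner than hOc1's IV complex
  expect_identical(sum(grepl("^IV", p2$layers$name)), 1L)
  expect_identical(p2$layers$name[grepl("^IV", p2$layers$name)], "IV")
  iv1 <- sum(l1$thickness_fraction[grepl("^IV", l1$name)])
  expect_lt(p2$layers$thickness_fraction[p2$layers$name == "IV"], iv1)
  # pyramidal size gradient in hOc2 layer III; stronger columnarity
  l2_III <- p2$layers[p2$layers$name == "III", ]
  expect_gt(l2_III$cell_radius_mean_deep, l2_III$cell_radius_mean)
  expect_gt(p2$columnarity, p1$columnarity)
})

test_that("unknown presets and invalid layer tables are rejected", {
  expect_error(make_preset_profile("hOc5-like"), "Valid presets")
  bad <- dplyr::bind_rows(layer_spec("I", 0.5, 100, 3, 0.5, 70),
                          layer_spec("II", 0.4, 100, 3, 0.5, 70))
  expect_error(area_profile("x", bad), "sum to 1")
  neg <- dplyr::bind_rows(layer_spec("I", 1, -5, 3, 0.5, 70))
  expect_error(area_profile("x", neg), "non-negative")
})

test_that("zero densities and zero noise give a uniform background image", {
  layers <- dplyr::bind_rows(layer_spec("I", 0.3, 0, 3, 0.5, 70),
                             layer_spec("II", 0.7, 0, 3, 0.5, 70))
  cfg <- render_config(width_px = 200, height_px = 400,
                       cortical_thickness_um = 300, noise_sd = 0, seed = 1,
                       wm_cell_density = 0)
  ph <- render_phantom(area_profile("empty", layers), cfg)
  expect_true(all(ph$image == cfg$background))
  expect_false(any(ph$cell_mask))
})

test_that("layer point process follows the Poisson count oracle", {
  # density d over a region of area A mm^2 -> count within 4*sqrt(dA) of dA
  for (seed in 1:5) {
    cells <- cortexmap:::sample_layer_cells(
      0, 2000, 0, 500, density = 2000, columnarity = 0.3,
      radius_top = 3, radius_deep = NA, radius_sd = 0.5,
      layer_seed = seed)
    lam <- 2000 * (2000 * 500) / 1e6
    expect_lt(abs(nrow(cells) - lam), 4 * sqrt(lam))
  }
})

test_that("rendering is bit-identical for identical seeds", {
  ph1 <- small_phantom(seed = 9, width_px = 400, height_px = 500,
                       cortical_thickness_um = 600)
  ph2 <- small_phantom(seed = 9, width_px = 400, height_px = 500,
                       cortical_thickness_um = 600)
  expect_identical(ph1$image, ph2$image)
  expect_identical(ph1$cell_mask, ph2$cell_mask)
  expect_identical(ph1$layer_labels, ph2$layer_labels)
  ph3 <- small_phantom(seed = 10, width_px = 400, height_px = 500,
                       cortical_thickness_um = 600)
  expect_false(identical(ph1$image, ph3$image))
})

test_that("raising one layer's density does not shrink its foreground", {
  base <- make_preset_profile("hOc1-like")
  denser <- base
  denser$layers$cell_density[denser$layers$name == "V"] <-
    denser$layers$cell_density[denser$layers$name == "V"] * 1.6
  cfg <- render_config(width_px = 500, height_px = 700,
                       cortical_thickness_um = 1000, noise_sd = 0, seed = 4)
  ph_a <- render_phantom(base, cfg)
  ph_b <- render_phantom(denser, cfg)
  code_v <- ph_a$layers$code[ph_a$layers$name == "V"]
  frac <- function(ph) mean(ph$cell_mask[ph$layer_labels == code_v])
  expect_gte(frac(ph_b), frac(ph_a))
  # other layers are driven by their own seeds and stay untouched
  code_ii <- ph_a$layers$code[ph_a$layers$name == "II"]
  expect_identical(ph_a$cell_mask[ph_a$layer_labels == code_ii],
                   ph_b$cell_mask[ph_b$layer_labels == code_ii])
})

test_that("per-layer foreground fractions track the intended densities", {
  ph <- small_phantom(seed = 2, noise_sd = 0,
                      presets = "hOc1-like", width_px = 600)
  ly <- ph$layers[ph$layers$area_id == "hOc1-like", ]
  measured <- vapply(ly$code, function(code)
    mean(ph$cell_mask[ph$layer_labels == code]), numeric(1))
  expected <- ly$cell_density * pi * ly$cell_radius_mean^2
  expect_gt(cor(measured, expected, method = "spearman"), 0.9)
  expect_identical(which.max(measured), which(ly$name == "IVc"))
})

test_that("masks, contours and borders are mutually consistent", {
  for (geom in c("flat", "arc")) {
    ph <- small_phantom(seed = 5, geometry = geom,
                        height_px = if (geom == "arc") 800 else 700)
    expect_true(all(ph$layer_labels[ph$cell_mask] != 0L))
    expect_true(all(ph$image >= 0 & ph$image <= 255))
    # every cortical pixel lies between the contours (field of depth)
    wm_code <- ph$areas$code[ph$areas$name == "WM"]
    cortex <- ph$area_labels != 0L & ph$area_labels != wm_code
    res <- ph$config$resolution_um
    x_um <- matrix((col(ph$image) - 0.5) * res, nrow(ph$image))
    y_um <- matrix((row(ph$image) - 0.5) * res, nrow(ph$image))
    v <- ph$geometry$uv_from_xy(x_um, y_um)$v
    expect_true(all(v[cortex] >= -res & v[cortex] <= ph$geometry$T + res))
    # one recorded border, on the outer contour between the two areas
    expect_identical(nrow(ph$true_border), 1L)
    expect_equal(ph$true_border$u_um, ph$geometry$u_max / 2, tolerance = 1e-9)
  }
})

test_that("a cortex thicker than the image raises a geometry error", {
  expect_error(
    render_phantom(make_preset_profile("hOc1-like"),
                   render_config(width_px = 200, height_px = 200,
                                 cortical_thickness_um = 2000)),
    class = "cortexmap_geometry_error")
})

test_that("phantoms round-trip through the TIFF/JSON writers", {
  ph <- small_phantom(seed = 3, width_px = 300, height_px = 500,
                      cortical_thickness_um = 600)
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  back <- read_phantom(dir)
  expect_identical(back$image, ph$image)
  expect_identical(back$cell_mask, ph$cell_mask)
  expect_identical(back$layer_labels, ph$layer_labels)
  expect_equal(back$true_border$u_um, ph$true_border$u_um)
})
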