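test_that("binarization keeps strictly-darker pixels only", {
  expect_false(any(binarize_cells(matrix(255, 4, 4), 128)))
  expect_true(all(binarize_cells(matrix(0, 4, 4), 128)))
  # threshold itself is background under the strictly-darker convention
  expect_false(any(binarize_cells(matrix(128, 4, 4), 128)))
  expect_error(binarize_cells(matrix(numeric(), 0, 0), 100), "non-empty")
  expect_error(binarize_cells(matrix(10, 2, 2), 300), "0, 255")
})

test_that("noise-free phantom binarizes exactly to its cell mask", {
  ph <- small_phantom(seed = 6, noise_sd = 0, width_px = 400, height_px = 600,
                      cortical_thickness_um = 800)
  for (thr in c(130, 180, 240)) {
    expect_identical(unname(binarize_cells(ph$image, thr) > 0),
                     unname(ph$cell_mask > 0),
                     info = paste("threshold", thr))
  }
})

test_that("the default threshold is chosen by Otsu and logged", {
  ph <- small_phantom(seed = 6, width_px = 400, height_px = 600,
                      cortical_thickness_um = 800)
  mask <- binarize_cells(ph$image)
  thr <- attr(mask, "threshold")
  expect_true(is.numeric(thr) && thr > 100 && thr < 242)
  expect_identical(as.vector(mask), as.vector(ph$image < thr))
  expect_identical(dim(mask), dim(ph$image))
})

test_that("GLI fields are exact foreground fractions", {
  expect_true(all(compute_gli(matrix(TRUE, 20, 30), 20, 2)$values == 1))
  m <- matrix(FALSE, 10, 10)
  m[sample(100, 37)] <- TRUE
  expect_equal(compute_gli(m, 20, 2)$values[1, 1], 0.37)
})

test_that("GLI matches a per-field recount oracle and conserves mass", {
  withr::with_seed(8, {
    mask <- matrix(runif(73 * 91) < 0.3, 73, 91)
  })
  gli <- compute_gli(mask, 10, 2)   # 5 px fields
  expect_identical(dim(gli$values), c(73L %/% 5L, 91L %/% 5L))
  for (i in seq_len(nrow(gli$values))) for (j in seq_len(ncol(gli$values))) {
    block <- mask[(i - 1) * 5 + 1:5, (j - 1) * 5 + 1:5]
    expect_equal(gli$values[i, j], sum(block) / 25)
  }
  cropped <- mask[1:70, 1:90]
  expect_equal(mean(gli$values), mean(cropped))
})

test_that("permuting pixels within one field leaves its value unchanged", {
  withr::with_seed(9, mask <- matrix(runif(40 * 40) < 0.4, 40, 40))
  g1 <- compute_gli(mask, 20, 2)
  perm <- mask
  blk <- perm[11:20, 21:30]
  perm[11:20, 21:30] <- matrix(sample(blk), 10, 10)
  g2 <- compute_gli(perm, 20, 2)
  expect_equal(g1$values[2, 3], g2$values[2, 3])
})

test_that("non-integer measuring fields are rejected with advice", {
  expect_error(compute_gli(matrix(TRUE, 30, 30), 20, 3), "resample")
})

test_that("GLI images round-trip through float TIFF", {
  withr::with_seed(10, mask <- matrix(runif(60 * 40) < 0.2, 60, 40))
  gli <- compute_gli(mask, 20, 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_gli(gli, path)
  back <- read_gli(path)
  expect_equal(back$values, gli$values, tolerance = 1e-7)
  expect_equal(back$field_size_um, 20)
})
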