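# Traverse tracing and profile sampling.

test_that("flat-cortex traverses are vertical with the cortical length", {
  field <- flat_fixture()
  trv <- trace_traverses(field, 8)
  for (d in split(trv, trv$traverse)) {
    expect_lt(max(abs(d$x - d$x[1])), 0.5)
    h <- max(d$s)
    expect_lt(abs(h - 50) / 50, 0.01)
    expect_lt(abs(d$y[1] - 5), 1)
    expect_lt(abs(d$y[nrow(d)] - 55), 1)
  }
})

test_that("annulus traverses are radial within one pixel", {
  fx <- annulus_fixture()
  trv <- trace_traverses(fx$field, 10)
  for (d in split(trv, trv$traverse)) {
    th0 <- atan2(d$y[1], d$x[1])
    # distance of every point from the seed's ray
    off <- abs(d$x * sin(th0) - d$y * cos(th0))
    expect_lt(max(off), 1)
    expect_lt(abs(max(d$s) - (fx$r1 - fx$r0)) / (fx$r1 - fx$r0), 0.05)
  }
  # streamline ordering is preserved at the inner contour (no crossing)
  ends <- dplyr::summarise(dplyr::group_by(trv, traverse),
                           th = atan2(y[dplyr::n()], x[dplyr::n()]))
  expect_true(all(diff(ends$th) > 0))
})

test_that("profiles sample the GLI by bilinear interpolation", {
  ramp <- structure(list(values = matrix(seq(0, 1, length.out = 5), 5, 3),
                         field_size_um = 20, resolution_um_per_px = 2,
                         field_px = 10, source_dim = c(50L, 30L)),
                    class = "gli_image")
  trv <- tibble::tibble(traverse = 1L, step = 1:5, x = 1, y = 0:4, s = 0:4)
  prof <- sample_profiles(ramp, trv, n_points = 5, traverse_resolution_um = 20)
  expect_equal(prof$value, c(0, 0.25, 0.5, 0.75, 1))

  const <- ramp
  const$values <- matrix(0.37, 5, 3)
  expect_equal(sample_profiles(const, trv, 5, 20)$value, rep(0.37, 5))
})

test_that("profile values match an independent interpolation oracle", {
  withr::with_seed(4, raw <- matrix(runif(30 * 30), 30, 30))
  smooth <- cortexmap:::gaussian_smooth(raw, 2)
  gli <- structure(list(values = smooth, field_size_um = 20,
                        resolution_um_per_px = 2, field_px = 10,
                        source_dim = c(300L, 300L)), class = "gli_image")
  # diagonal traverse at constant speed
  t <- seq(0, 1, length.out = 40)
  trv <- tibble::tibble(traverse = 1L, step = seq_along(t),
                        x = 3 + 20 * t, y = 25 - 18 * t,
                        s = t * sqrt(20^2 + 18^2))
  prof <- sample_profiles(gli, trv, n_points = 11, traverse_resolution_um = 20)
  tt <- seq(0, 1, length.out = 11)
  ox <- 3 + 20 * tt
  oy <- 25 - 18 * tt
  oracle <- vapply(seq_along(tt), function(i) {
    x0 <- floor(ox[i]); y0 <- floor(oy[i])
    fx <- ox[i] - x0; fy <- oy[i] - y0
    (1 - fx) * (1 - fy) * smooth[y0 + 1, x0 + 1] +
      fx * (1 - fy) * smooth[y0 + 1, x0 + 2] +
      (1 - fx) * fy * smooth[y0 + 2, x0 + 1] +
      fx * fy * smooth[y0 + 2, x0 + 2]
  }, numeric(1))
  expect_equal(prof$value, oracle, tolerance = 1e-6)
})

test_that("the reversed traverse yields the reversed profile", {
  withr::with_seed(5, vals <- cortexmap:::gaussian_smooth(matrix(runif(400), 20), 1.5))
  gli <- structure(list(values = vals, field_size_um = 20,
                        resolution_um_per_px = 2, field_px = 10,
                        source_dim = c(200L, 200L)), class = "gli_image")
  trv <- tibble::tibble(traverse = 1L, step = 1:15, x = seq(2, 16, 1),
                        y = seq(3, 10, 0.5), s = seq(0, 14, 1) * sqrt(1.25))
  rev_trv <- tibble::tibble(traverse = 1L, step = 1:15, x = rev(trv$x),
                            y = rev(trv$y), s = trv$s)
  p1 <- sample_profiles(gli, trv, 9, 20)$value
  p2 <- sample_profiles(gli, rev_trv, 9, 20)$value
  expect_equal(p1, rev(p2), tolerance = 1e-9)
})

test_that("traverses leaving the GLI grid raise an error", {
  gli <- structure(list(values = matrix(0.5, 5, 5), field_size_um = 20,
                        resolution_um_per_px = 2, field_px = 10,
                        source_dim = c(50L, 50L)), class = "gli_image")
  trv <- tibble::tibble(traverse = 1L, step = 1:3, x = c(1, 2, 40),
                        y = c(1, 1, 1), s = 0:2)
  expect_error(sample_profiles(gli, trv, 3, 20), "exits the GLI grid")
})

test_that("a failing streamline names its seed", {
  # flat field but a tiny step budget
  field <- flat_fixture()
  expect_error(trace_traverses(field, 3, max_steps = 5), "seed 1")
})
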