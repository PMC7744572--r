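test_that("activation normalization uses the smallest positive value", {
  out <- normalize_activation(matrix(c(0, 0.2, 0.6, 1.0), 2))
  expect_equal(as.vector(out), c(0, 0, 0.5, 1))
  expect_false(attr(out, "degenerate"))
  expect_equal(attr(out, "lower_bound"), 0.2)

  z <- normalize_activation(matrix(0, 3, 3))
  expect_true(all(z == 0))
  expect_true(attr(z, "degenerate"))
  cst <- normalize_activation(matrix(2, 3, 3))
  expect_true(all(cst == 0) && attr(cst, "degenerate"))

  withr::with_seed(1, m <- matrix(rexp(100), 10))
  nm <- normalize_activation(m)
  expect_equal(min(nm), 0)
  expect_equal(max(nm), 1)
  expect_error(normalize_activation(matrix(c(1, NaN), 1)), "non-finite")
})

test_that("the joint histogram is an exact counting table", {
  expect_equal(joint_histogram(matrix(0, 2, 2), matrix(0, 2, 2))[1, 1], 1)
  withr::with_seed(2, {
    x <- matrix(runif(40 * 40), 40)
    y <- matrix(runif(40 * 40), 40)
  })
  J <- joint_histogram(x, y)
  expect_equal(sum(J), 1, tolerance = 1e-12)
  # brute-force per-pixel count
  oracle <- matrix(0, 256, 256)
  for (k in seq_along(x)) {
    i <- min(floor(x[k] * 256), 255) + 1
    j <- min(floor(y[k] * 256), 255) + 1
    oracle[i, j] <- oracle[i, j] + 1
  }
  expect_identical(J, oracle / length(x))
  # marginalisation identity: row sums are x's own histogram
  hx <- tabulate(pmin(floor(as.vector(x) * 256), 255) + 1, 256) / length(x)
  expect_equal(rowSums(J), hx)
  expect_error(joint_histogram(x, y[1:10]), "same number")
})

test_that("mutual information satisfies its identities", {
  withr::with_seed(3, x <- matrix(runif(300 * 300), 300))
  expect_equal(mutual_information(x, x), entropy_bits(x), tolerance = 1e-10)
  # constructed binary pair with joint mass (1/2, 0, 0, 1/2) carries 1 bit
  a <- matrix(rep(c(0, 1), each = 500), 1000)
  expect_equal(mutual_information(a, a), 1)
  b <- 1 - a
  expect_equal(mutual_information(a, b), 1)
  # independent uniform-noise maps share almost nothing (finite-sample bias)
  withr::with_seed(4, {
    u <- matrix(runif(1e6), 1000)
    v <- matrix(runif(1e6), 1000)
  })
  expect_lt(mutual_information(u, v), 0.05)
  expect_gte(mutual_information(u, v), 0)
})

test_that("blurring one map of a correlated pair does not raise MI", {
  withr::with_seed(5, x <- cortexmap:::gaussian_smooth(matrix(runif(200 * 200), 200), 2))
  x <- (x - min(x)) / (max(x) - min(x))
  withr::with_seed(6, noise <- matrix(runif(200 * 200, 0, 0.2), 200))
  y <- (x + noise) / 1.2
  xb <- cortexmap:::gaussian_smooth(x, 8)
  expect_lte(mutual_information(xb, y), mutual_information(x, y) * 1.02)
})

test_that("the pairwise MI matrix is symmetric with entropies on the diagonal", {
  withr::with_seed(7, maps <- lapply(1:3, function(i) matrix(runif(900), 30)))
  maps[[4]] <- maps[[2]]           # duplicate
  maps[[5]] <- matrix(0, 30, 30)   # degenerate
  mi <- pairwise_mi(maps)
  M <- mi$values
  expect_identical(M, t(M))
  expect_true(all(M >= -1e-12))
  expect_identical(mi$degenerate, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_true(all(M[5, ] == 0))
  expect_equal(M[2, c(1, 3)], M[4, c(1, 3)])
  # off-diagonal entries equal one-at-a-time recomputation
  n1 <- normalize_activation(maps[[1]])
  n3 <- normalize_activation(maps[[3]])
  expect_equal(M[1, 3], mutual_information(n1, n3), tolerance = 1e-12)
  expect_equal(M[1, 1], entropy_bits(normalize_activation(maps[[1]])),
               tolerance = 1e-12)
  # maps 2 and 4 are identical, so only 4 distinct positive pair values
  expect_identical(length(unique(M[upper.tri(M)][M[upper.tri(M)] > 0])), 4L)
})

test_that("characteristic filters need three same-layer partners in the top twelve", {
  # synthetic MI structure: 20 maps, layers of 5; map 1 highly similar to
  # 5 same-layer-ish partners, map 6 similar to only 2
  m <- 20
  prov <- tibble::tibble(map = 1:m, network_layer = rep(1:4, each = 5))
  withr::with_seed(42, V <- matrix(runif(m * m, 0.01, 0.1), m, m))
  V <- (V + t(V)) / 2
  put <- function(i, j, v) V[i, j] <<- V[j, i] <<- v
  for (j in 2:5) put(1, j, 0.9)            # 4 same-layer partners for map 1
  for (j in c(7, 8)) put(6, j, 0.9)        # only 2 strong for map 6 ...
  for (j in c(9, 10)) put(6, j, 0.001)     # ... its siblings stay out of reach
  mi <- structure(list(values = V, provenance = prov,
                       degenerate = rep(FALSE, m), bins = 256L,
                       unit = "bits", reference_dim = c(10L, 10L)),
                  class = "mi_matrix")
  ch <- characteristic_filters(mi, k = 12, min_same_layer = 3)
  expect_true(ch$characteristic[1])
  expect_identical(ch$n_same_layer[1], 4L)
  expect_false(ch$characteristic[6])
  expect_error(characteristic_filters(mi, k = 20), "smaller")
})

test_that("identical maps give the tie-break-derived same-layer counts", {
  withr::with_seed(8, base <- matrix(runif(400), 20))
  maps <- lapply(1:15, function(i) base)
  mi <- pairwise_mi(maps)
  mi$provenance$network_layer <- rep(1:3, each = 5)
  ch <- characteristic_filters(mi, k = 12, min_same_layer = 3)
  # all MI values tie, so the compilation is the 12 lowest map indices:
  # derive the expected same-layer count independently
  for (i in 1:15) {
    partners <- setdiff(1:15, i)[1:12]
    expected <- sum(mi$provenance$network_layer[partners] ==
                      mi$provenance$network_layer[i])
    expect_identical(ch$n_same_layer[i], as.integer(expected))
    expect_true(ch$tie_at_k[i])
  }
  # units of the first layer retain all their (units - 1) siblings
  expect_true(all(ch$n_same_layer[1:5] == 4L))
})

test_that("constructed maps are assigned their feature level", {
  ph <- small_phantom(seed = 15, width_px = 500, height_px = 600,
                      cortical_thickness_um = 800, noise_sd = 0)
  w <- list(row = 300L, col = 250L, px = 256L, res_um = 2)
  crop <- function(m) m[(w$row - 128):(w$row + 127), (w$col - 128):(w$col + 127)]
  cellf <- cortexmap:::gaussian_smooth(crop(ph$cell_mask * 1), 5)
  cellf <- cellf / max(cellf)
  ivc_code <- ph$layers$code[ph$layers$name == "IVc"]
  layer_map <- (crop(ph$layer_labels) == ivc_code) * 1
  withr::with_seed(16, area_map <- pmin(pmax(
    (crop(ph$area_labels) == 1) + rnorm(256^2, 0, 0.05), 0), 1))
  stack <- structure(list(
    maps = list(cellf, layer_map, area_map),
    provenance = tibble::tibble(map = 1:3, instance = "cnn1", branch = "hr",
                                block = 1L, layer_in_block = 1L,
                                network_layer = c(1L, 5L, 13L), unit = 1:3,
                                nrow = 256L, ncol = 256L),
    window = w), class = "activation_stack")
  lev <- assign_levels(stack, ph)
  expect_identical(lev$level, c("first", "second", "third"))
  expect_gt(lev$score_cell[1], 0.9)
  expect_equal(lev$score_layer[2], 1)
  expect_gt(lev$score_area[3], 0.9)
})
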