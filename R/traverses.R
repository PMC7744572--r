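# Cortical traverses: streamlines of the Laplace field, and GLI profile
# sampling along them.

# Fill NA cells with the value of the nearest (4-neighbour) valid cell so
# that gradients can be interpolated right up to the domain boundary.
fill_nearest <- function(m, max_pass = 200L) {
  for (i in seq_len(max_pass)) {
    na <- is.na(m)
    if (!any(na)) break
    cand <- (shift_m(!na, 1, 0, FALSE) + shift_m(!na, -1, 0, FALSE) +
               shift_m(!na, 0, 1, FALSE) + shift_m(!na, 0, -1, FALSE))
    m0 <- m; m0[na] <- 0
    s <- shift_m(m0, 1, 0) + shift_m(m0, -1, 0) +
      shift_m(m0, 0, 1) + shift_m(m0, 0, -1)
    fillable <- na & cand > 0
    m[fillable] <- s[fillable] / cand[fillable]
  }
  m[is.na(m)] <- 0
  m
}

# Points at given arc-length positions along a polyline.
polyline_point <- function(contour, s_target) {
  seg <- sqrt(diff(contour$x)^2 + diff(contour$y)^2)
  s <- c(0, cumsum(seg))
  list(x = stats::approx(s, contour$x, s_target, rule = 2)$y,
       y = stats::approx(s, contour$y, s_target, rule = 2)$y,
       total = s[length(s)])
}

#' Trace cortical traverses through a Laplace field
#'
#' Seeds `n_traverses` points at equidistant arc-length positions along
#' the outer (layer I/II) contour and integrates each along the gradient
#' of the field (4th-order Runge-Kutta on the normalised gradient, fixed
#' step) until it reaches the inner (grey/white matter) contour, i.e.
#' until the field value exceeds `stop_level`.
#'
#' @param field A [solve_laplace()] result.
#' @param n_traverses Number of traverses.
#' @param step Integration step in grid pixels.
#' @param stop_level Field value at which a traverse is considered to
#'   have reached the inner contour.
#' @param max_steps Step budget per traverse; exceeding it raises an
#'   error naming the offending seed.
#' @return A tibble of class `cortical_traverses` with columns
#'   `traverse`, `step`, `x`, `y` (0-based pixel-centre grid coordinates)
#'   and `s` (arc length in grid pixels).  Attributes: `seed_arc`
#'   (arc-length of each seed along the outer contour, in grid pixels)
#'   and `contour_length`.
#' @export
trace_traverses <- function(field, n_traverses, step = 0.25,
                            stop_level = 0.999, max_steps = NULL) {
  if (!inherits(field, "laplace_field")) abort("`field` must be a laplace_field.")
  if (n_traverses < 1L) abort("Need at least one traverse.")
  vals <- fill_nearest(field$values)
  nr <- nrow(vals); nc <- ncol(vals)
  gx <- (cbind(vals[, -1], vals[, nc]) - cbind(vals[, 1], vals[, -nc])) / 2
  gy <- (rbind(vals[-1, ], vals[nr, ]) - rbind(vals[1, ], vals[-nr, ])) / 2

  sd_tot <- polyline_point(field$outer, 0)$total
  seed_arc <- (seq_len(n_traverses) - 0.5) / n_traverses * sd_tot
  seed <- polyline_point(field$outer, seed_arc)

  max_steps <- max_steps %||% as.integer(ceiling(20 * max(nr, nc) / step))
  dirn <- function(x, y) {
    dx <- bilinear_interp(gx, x, y)
    dy <- bilinear_interp(gy, x, y)
    nrm <- sqrt(dx * dx + dy * dy)
    bad <- nrm < 1e-12
    nrm[bad] <- 1
    dx[bad] <- 0; dy[bad] <- 0
    list(x = dx / nrm, y = dy / nrm)
  }

  n <- n_traverses
  X <- matrix(NA_real_, max_steps + 1L, n)
  Y <- matrix(NA_real_, max_steps + 1L, n)
  X[1, ] <- seed$x; Y[1, ] <- seed$y
  alive <- rep(TRUE, n)
  n_pts <- rep(1L, n)
  x <- seed$x; y <- seed$y
  for (k in seq_len(max_steps)) {
    if (!any(alive)) break
    xa <- x[alive]; ya <- y[alive]
    k1 <- dirn(xa, ya)
    k2 <- dirn(xa + step / 2 * k1$x, ya + step / 2 * k1$y)
    k3 <- dirn(xa + step / 2 * k2$x, ya + step / 2 * k2$y)
    k4 <- dirn(xa + step * k3$x, ya + step * k3$y)
    xa <- xa + step / 6 * (k1$x + 2 * k2$x + 2 * k3$x + k4$x)
    ya <- ya + step / 6 * (k1$y + 2 * k2$y + 2 * k3$y + k4$y)
    x[alive] <- xa; y[alive] <- ya
    idx <- which(alive)
    X[cbind(n_pts[idx] + 1L, idx)] <- xa
    Y[cbind(n_pts[idx] + 1L, idx)] <- ya
    n_pts[idx] <- n_pts[idx] + 1L
    done <- bilinear_interp(vals, xa, ya) >= stop_level
    alive[idx[done]] <- FALSE
  }
  if (any(alive))
    abort(sprintf("Traverse from seed %d did not reach the inner contour within %d steps.",
                  which(alive)[1], max_steps))

  step_len <- step
  out <- purrr::map(seq_len(n), function(i) {
    m <- n_pts[i]
    tibble::tibble(traverse = i, step = seq_len(m),
                   x = X[seq_len(m), i], y = Y[seq_len(m), i],
                   s = (seq_len(m) - 1) * step_len)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("cortical_traverses", class(res))
  attr(res, "seed_arc") <- seed_arc
  attr(res, "contour_length") <- sd_tot
  attr(res, "grid_dim") <- c(nr, nc)
  res
}

#' Sample GLI profiles along traverses
#'
#' Bilinearly interpolates the GLI image at `n_points` equidistant
#' arc-length positions along each traverse, yielding one profile per
#' traverse over relative cortical depth `x` in `[0, 1]`.
#'
#' @param gli A [compute_gli()] result.
#' @param traverses A [trace_traverses()] result.
#' @param n_points Number of equidistant depth samples per profile.
#' @param traverse_resolution_um Physical size (um) of one grid pixel of
#'   the coordinate system the traverses were traced in (the Laplace
#'   grid spacing).
#' @return A tibble of class `gli_profiles` with columns `traverse`,
#'   `point` (0-based), `depth` in `[0, 1]` and `value`; attribute
#'   `seed_arc_um` gives each traverse's position (um of arc length)
#'   along the outer contour.
#' @export
sample_profiles <- function(gli, traverses, n_points = 100,
                            traverse_resolution_um) {
  if (!inherits(gli, "gli_image")) abort("`gli` must be a gli_image.")
  if (n_points < 3L) abort("`n_points` must be at least 3.")
  stopifnot_scalar(traverse_resolution_um, "traverse_resolution_um")
  f_um <- gli$field_size_um
  gnr <- nrow(gli$values); gnc <- ncol(gli$values)

  gx_all <- (traverses$x + 0.5) * traverse_resolution_um / f_um - 0.5
  gy_all <- (traverses$y + 0.5) * traverse_resolution_um / f_um - 0.5
  if (any(gx_all < -0.5 - 1e-9) || any(gx_all > gnc - 0.5 + 1e-9) ||
      any(gy_all < -0.5 - 1e-9) || any(gy_all > gnr - 0.5 + 1e-9))
    abort("Traverse exits the GLI grid; enlarge the GLI image or move the seeds.")

  tr <- dplyr::mutate(traverses, .gx = gx_all, .gy = gy_all)
  pieces <- lapply(split(tr, tr$traverse), function(d) {
    s_t <- seq(0, max(d$s), length.out = n_points)
    if (nrow(d) < 2L) abort("A traverse needs at least two points.")
    px <- stats::approx(d$s, d$.gx, s_t, rule = 2)$y
    py <- stats::approx(d$s, d$.gy, s_t, rule = 2)$y
    tibble::tibble(traverse = d$traverse[1], point = seq_len(n_points) - 1L,
                   depth = (seq_len(n_points) - 1) / (n_points - 1),
                   value = bilinear_interp(gli$values, px, py))
  })
  res <- dplyr::bind_rows(pieces)
  class(res) <- c("gli_profiles", class(res))
  attr(res, "n_points") <- n_points
  sa <- attr(traverses, "seed_arc")
  if (!is.null(sa)) attr(res, "seed_arc_um") <- sa * traverse_resolution_um
  res
}

#' Arrange profiles as a traverse-by-depth matrix
#'
#' @param profiles A [sample_profiles()] result (long tibble).
#' @return Numeric matrix, one row per traverse.
#' @export
profile_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(profiles[, c("traverse", "point", "value")],
                             names_from = "point", values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$traverse
  m
}
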