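# Laplace field between the cortical boundaries.

rasterize_polyline <- function(contour, nr, nc) {
  x <- contour$x; y <- contour$y
  if (length(x) == 1L) {
    px <- cbind(round(y) + 1, round(x) + 1)
  } else {
    seg <- sqrt(diff(x)^2 + diff(y)^2)
    s <- c(0, cumsum(seg))
    t <- seq(0, s[length(s)], by = 0.3)
    px <- cbind(round(stats::approx(s, y, t)$y) + 1,
                round(stats::approx(s, x, t)$y) + 1)
  }
  keep <- px[, 1] >= 1 & px[, 1] <= nr & px[, 2] >= 1 & px[, 2] <= nc
  unique(px[keep, , drop = FALSE])
}

shift_m <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

neighbour_sum <- function(u, act) {
  ua <- u * act
  s <- shift_m(ua, 1, 0) + shift_m(ua, -1, 0) +
    shift_m(ua, 0, 1) + shift_m(ua, 0, -1)
  s
}

#' Solve the Laplace equation between two cortical contours
#'
#' Computes a harmonic scalar field on the pixel grid of `domain` with
#' Dirichlet values 0 on the outer (layer I/II) contour and 1 on the
#' inner (grey/white matter) contour, using red-black successive
#' over-relaxation.  Pixels of the domain that touch the image border or
#' non-domain pixels get mirror (zero-flux) conditions, so the field's
#' isolines run parallel to the open lateral edges.
#'
#' @param domain Logical matrix: `TRUE` on the cortical ribbon to solve
#'   over (the contours must run through or alongside it).
#' @param outer,inner Contour polylines: data frames with `x`, `y` in
#'   0-based pixel-centre coordinates of `domain`.
#' @param tol Convergence tolerance on the maximum absolute residual
#'   `|mean(available neighbours) - u|` over free pixels.
#' @param max_iter Sweep cap (default scales with the grid size).
#' @param omega Over-relaxation factor; default is the classical optimum
#'   for a square grid of the given size.
#' @return An object of class `laplace_field`: `values` (matrix, `NA`
#'   outside the solved region), masks, achieved `residual`, `iterations`,
#'   and the two contours (used later for traverse seeding).
#' @export
solve_laplace <- function(domain, outer, inner, tol = 1e-4,
                          max_iter = NULL, omega = NULL) {
  if (!is.matrix(domain) || !is.logical(domain))
    abort("`domain` must be a logical matrix.")
  nr <- nrow(domain); nc <- ncol(domain)
  f0 <- matrix(FALSE, nr, nc)
  f1 <- matrix(FALSE, nr, nc)
  f0[rasterize_polyline(outer, nr, nc)] <- TRUE
  f1[rasterize_polyline(inner, nr, nc)] <- TRUE
  f1 <- f1 & !f0
  free <- domain & !f0 & !f1
  act <- free | f0 | f1
  if (!any(f0) || !any(f1))
    abort("Contours do not intersect the grid.")
  if (!any(free)) abort("No free pixels between the contours.")

  # connectivity: every free pixel must be reachable from the outer band
  reach <- f0
  repeat {
    grown <- (reach | shift_m(reach, 1, 0, FALSE) | shift_m(reach, -1, 0, FALSE) |
                shift_m(reach, 0, 1, FALSE) | shift_m(reach, 0, -1, FALSE)) & act
    if (identical(grown, reach)) break
    reach <- grown
  }
  if (any(free & !reach))
    abort("Disconnected domain: some cortical pixels cannot be reached from the outer contour.")

  cnt <- shift_m(act * 1, 1, 0) + shift_m(act * 1, -1, 0) +
    shift_m(act * 1, 0, 1) + shift_m(act * 1, 0, -1)
  cnt[cnt == 0] <- 1

  omega <- omega %||% (2 / (1 + sin(pi / (max(nr, nc) + 1))))
  max_iter <- max_iter %||% (60L * max(nr, nc) + 1000L)

  u <- matrix(0, nr, nc)
  u[free] <- 0.5
  u[f1] <- 1
  rb <- (outer(seq_len(nr), seq_len(nc), "+") %% 2) == 0
  red <- free & rb
  black <- free & !rb

  residual <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    navg <- neighbour_sum(u, act) / cnt
    u[red] <- u[red] + omega * (navg[red] - u[red])
    navg <- neighbour_sum(u, act) / cnt
    u[black] <- u[black] + omega * (navg[black] - u[black])
    navg <- neighbour_sum(u, act) / cnt
    residual <- max(abs(navg[free] - u[free]))
    if (residual < tol) break
  }
  if (residual >= tol)
    warn(sprintf("Laplace solver stopped at residual %.3g after %d sweeps (tol %.3g).",
                 residual, it, tol))
  vals <- u
  vals[!act] <- NA_real_
  vals <- pmin(pmax(vals, 0), 1)
  structure(list(values = vals, free = free, fixed_outer = f0, fixed_inner = f1,
                 residual = residual, iterations = it, omega = omega,
                 outer = tibble::as_tibble(outer[, c("x", "y")]),
                 inner = tibble::as_tibble(inner[, c("x", "y")])),
            class = "laplace_field")
}

#' @export
print.laplace_field <- function(x, ...) {
  cat(sprintf("<laplace_field>  %d x %d grid; residual %.2e after %d sweeps\n",
              nrow(x$values), ncol(x$values), x$residual, x$iterations))
  invisible(x)
}
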