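# Closed-form Laplace fixtures shared by the solver and traverse tests.

flat_fixture <- function(tol = 1e-7) {
  domain <- matrix(FALSE, 70, 50)
  domain[6:56, ] <- TRUE
  outer <- tibble::tibble(x = c(0, 49), y = c(5, 5))
  inner <- tibble::tibble(x = c(0, 49), y = c(55, 55))
  solve_laplace(domain, outer, inner, tol = tol)
}

annulus_fixture <- function(r0 = 100, r1 = 220, tol = 1e-6) {
  n <- 240
  x <- matrix(0:(n - 1), n, n, byrow = TRUE)
  y <- matrix(0:(n - 1), n, n)
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  a0 <- 15 * pi / 180; a1 <- 75 * pi / 180
  domain <- r >= r0 - 1 & r <= r1 + 1 & th >= a0 & th <= a1
  arc <- function(rr) {
    t <- seq(a0, a1, length.out = 400)
    tibble::tibble(x = rr * cos(t), y = rr * sin(t))
  }
  list(field = solve_laplace(domain, arc(r0), arc(r1), tol = tol),
       r0 = r0, r1 = r1)
}
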