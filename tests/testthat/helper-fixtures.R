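# Shared fixtures and independent oracles, all built in code.

# Small two-area phantom for unit tests (fast to render).
small_phantom <- function(seed = 1, noise_sd = 6, geometry = "flat",
                          presets = c("hOc1-like", "hOc2-like"),
                          width_px = 800, height_px = 700,
                          cortical_thickness_um = 1000) {
  profs <- lapply(presets, make_preset_profile)
  if (anyDuplicated(presets)) {
    for (i in seq_along(profs)) profs[[i]]$area_id <- paste0(profs[[i]]$area_id, "#", i)
  }
  render_phantom(profs, render_config(
    width_px = width_px, height_px = height_px,
    cortical_thickness_um = cortical_thickness_um,
    geometry = geometry, noise_sd = noise_sd, seed = seed))
}

# "Easy" training pair: strong overall density contrast, no pixel noise.
easy_profiles <- function() {
  a <- make_preset_profile("hOc1-like")
  b <- make_preset_profile("hOc2-like")
  b$layers$cell_density <- b$layers$cell_density * 0.35
  list(a, b)
}

easy_phantom <- function(seed) {
  render_phantom(easy_profiles(),
                 render_config(width_px = 1200, height_px = 800,
                               cortical_thickness_um = 1200,
                               noise_sd = 0, seed = seed))
}

# Brute-force frequency-distribution moment oracle (independent of the
# package implementation; plain loops on purpose).
oracle_features <- function(y) {
  n <- length(y)
  xs <- seq(0, 1, length.out = n)
  dist5 <- function(vals) {
    tot <- 0
    for (v in vals) tot <- tot + v
    mu <- 0
    for (i in seq_len(n)) mu <- mu + vals[i] / tot * xs[i]
    m2 <- m3 <- m4 <- 0
    for (i in seq_len(n)) {
      w <- vals[i] / tot
      m2 <- m2 + w * (xs[i] - mu)^2
      m3 <- m3 + w * (xs[i] - mu)^3
      m4 <- m4 + w * (xs[i] - mu)^4
    }
    c(tot / n, mu, sqrt(m2), m3 / m2^1.5, m4 / m2^2)
  }
  dx <- 1 / (n - 1)
  d <- numeric(n)
  d[1] <- abs(y[2] - y[1]) / dx
  for (i in 2:(n - 1)) d[i] <- abs(y[i + 1] - y[i - 1]) / (2 * dx)
  d[n] <- abs(y[n] - y[n - 1]) / dx
  c(dist5(y), dist5(d))
}

# Two-block Mahalanobis oracle.
oracle_d2 <- function(L, R) {
  b <- nrow(L)
  S <- ((b - 1) * cov(L) + (b - 1) * cov(R)) / (2 * b - 2)
  dm <- colMeans(L) - colMeans(R)
  drop(t(dm) %*% solve(S) %*% dm)
}

# Gaussian feature sequence with mean steps at given positions.
step_sequence <- function(n, p = 10, steps = integer(), magnitudes = 1,
                          seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    mags <- rep_len(magnitudes, length(steps))
    for (k in seq_along(steps)) {
      X[steps[k]:n, seq_len(min(4, p))] <-
        X[steps[k]:n, seq_len(min(4, p))] + mags[k]
    }
    X
  })
}

# Tiny architecture for engine tests.
tiny_arch <- function(hr_px = 24L, lr_px = 16L) {
  arch <- default_architecture(scale = 1 / 64, min_units = 2)
  arch$hr_patch_px <- hr_px
  arch$lr_patch_px <- lr_px
  arch
}
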