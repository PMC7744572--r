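# 10-component shape feature vectors of mean GLI profiles.

#' Pointwise mean of a set of GLI profiles
#'
#' @param profiles A [sample_profiles()] tibble, a numeric matrix (one
#'   row per profile), or a list of equal-length numeric vectors.
#' @return Numeric vector: the pointwise arithmetic mean profile.
#' @export
mean_profile <- function(profiles) {
  if (inherits(profiles, "gli_profiles") || is.data.frame(profiles))
    profiles <- profile_matrix(profiles)
  if (is.list(profiles) && !is.matrix(profiles)) {
    lens <- lengths(profiles)
    if (length(unique(lens)) != 1L) abort("Profiles have mismatching lengths.")
    profiles <- do.call(rbind, profiles)
  }
  if (!is.matrix(profiles) || nrow(profiles) < 1L)
    abort("Need at least one profile.")
  colMeans(profiles)
}

# Frequency-distribution statistics of a non-negative trace over [0, 1].
dist_stats <- function(y, prefix) {
  n <- length(y)
  x <- seq(0, 1, length.out = n)
  tot <- sum(y)
  if (tot <= 0) {
    # degenerate trace (e.g. derivative of a constant profile): the depth
    # distribution is undefined; report a centred, zero-spread convention
    out <- c(0, 0.5, 0, 0, 0)
  } else {
    w <- y / tot
    mu <- sum(w * x)
    m2 <- sum(w * (x - mu)^2)
    m3 <- sum(w * (x - mu)^3)
    m4 <- sum(w * (x - mu)^4)
    out <- c(mean(y), mu, sqrt(m2),
             if (m2 > 0) m3 / m2^1.5 else 0,
             if (m2 > 0) m4 / m2^2 else 0)
  }
  setNames(out, paste0(prefix, c("meany", "mean", "sd", "skew", "kurt")))
}

#' Shape feature vector of a GLI profile
#'
#' Treats the profile as a frequency distribution over relative cortical
#' depth `x` in `[0, 1]` and computes the mean amplitude together with
#' four central-moment statistics (centroid, standard deviation,
#' skewness, kurtosis), then the same five statistics on the absolute
#' differential quotient of the profile (central differences in the
#' interior, one-sided at the ends).  Kurtosis is the raw ratio
#' `m4 / m2^2`, not excess-corrected.
#'
#' @param profile Numeric vector of `>= 3` non-negative amplitudes with
#'   positive sum.
#' @return Named numeric vector of length 10: `meany`, `mean`, `sd`,
#'   `skew`, `kurt`, `d.meany`, `d.mean`, `d.sd`, `d.skew`, `d.kurt`
#'   (`mean` is the centroid of the depth distribution; the `d.` block
#'   describes the absolute differential quotient).
#' @export
feature_vector <- function(profile) {
  y <- as.numeric(profile)
  n <- length(y)
  if (n < 3L) abort("A profile needs at least 3 points.")
  if (any(!is.finite(y))) abort("Profile contains non-finite values.")
  if (sum(y) <= 0)
    abort("All-zero profile: its frequency distribution over depth is undefined.")
  dx <- 1 / (n - 1)
  d <- c(abs(y[2] - y[1]) / dx,
         abs(y[3:n] - y[1:(n - 2)]) / (2 * dx),
         abs(y[n] - y[n - 1]) / dx)
  c(dist_stats(y, ""), dist_stats(d, "d."))
}

#' Feature vectors for an ordered sequence of profiles
#'
#' Applies [feature_vector()] to every profile, preserving the traverse
#' order, so the result can feed the sliding-window border detection.
#'
#' @param profiles A [sample_profiles()] tibble or numeric matrix (one
#'   row per profile).
#' @return A tibble with a `traverse` column and the 10 feature columns.
#' @export
profile_features <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  feats <- t(apply(m, 1, feature_vector))
  out <- tibble::as_tibble(feats)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  out <- dplyr::bind_cols(tibble::tibble(traverse = as.integer(ids)), out)
  if (!is.null(attr(profiles, "seed_arc_um")))
    attr(out, "seed_arc_um") <- attr(profiles, "seed_arc_um")
  out
}

feature_cols <- c("meany", "mean", "sd", "skew", "kurt",
                  "d.meany", "d.mean", "d.sd", "d.skew", "d.kurt")
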