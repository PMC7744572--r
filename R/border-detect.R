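# Sliding-window Mahalanobis border detection with Hotelling T2
# significance and multi-window confirmation.

features_to_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  if (is.data.frame(features)) {
    cols <- intersect(feature_cols, names(features))
    if (length(cols) == 0L)
      cols <- names(features)[vapply(features, is.numeric, TRUE) &
                                names(features) != "traverse"]
    return(as.matrix(features[, cols, drop = FALSE]))
  }
  abort("`features` must be a matrix or a profile_features() tibble.")
}

#' Sliding-window Mahalanobis distance along a feature-vector sequence
#'
#' At each position `i` the `b` feature vectors to the left are compared
#' with the `b` vectors starting at `i`: `D^2 = (m_L - m_R)' S^-1
#' (m_L - m_R)` with `S` the pooled within-block covariance.  Position
#' `i` labels the first profile of the right block, i.e. the putative
#' first profile of a new area.  Significance uses Hotelling's T2
#' (`T2 = b/2 * D^2`) converted to an F statistic with `(p, 2b - p - 1)`
#' degrees of freedom, Bonferroni-corrected over the tested positions.
#'
#' @param features Ordered feature vectors: a [profile_features()] tibble
#'   or an `n x p` matrix.
#' @param b Block (window) size; the sequence must hold at least `2 b`
#'   vectors and `2 b` must exceed `p + 1` for the F test to exist.
#' @param alpha Familywise significance level after Bonferroni.
#' @param shrinkage Optional shrinkage weight `lambda` in `[0, 1]`
#'   blending the pooled covariance towards a scaled identity
#'   (`(1 - lambda) S + lambda mean(diag(S)) I`), for short sequences.
#' @return A tibble of class `distance_function`: `position`, `d2`,
#'   `statistic` (F), `p_value`, `p_adj`, `significant`; attributes `b`,
#'   `alpha`, `p_dim`.
#' @export
sliding_distance <- function(features, b, alpha = 0.05, shrinkage = 0) {
  X <- features_to_matrix(features)
  n <- nrow(X); p <- ncol(X)
  if (b < 2L) abort("`b` must be at least 2.")
  if (n < 2 * b) abort(sprintf("Sequence of length %d is too short for window size %d.", n, b))
  if (2 * b - p - 1 <= 0)
    abort(sprintf("Window size %d too small for %d features (need 2b > p + 1).", b, p))
  positions <- (b + 1):(n - b + 1)
  d2 <- numeric(length(positions))
  for (k in seq_along(positions)) {
    i <- positions[k]
    L <- X[(i - b):(i - 1), , drop = FALSE]
    R <- X[i:(i + b - 1), , drop = FALSE]
    S <- ((b - 1) * cov(L) + (b - 1) * cov(R)) / (2 * b - 2)
    if (shrinkage > 0)
      S <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(p)
    dm <- colMeans(L) - colMeans(R)
    Si <- tryCatch(solve(S, dm), error = function(e)
      abort(paste0("Singular pooled covariance at position ", i,
                   "; consider the `shrinkage` option.")))
    d2[k] <- sum(dm * Si)
  }
  t2 <- (b / 2) * d2
  fstat <- t2 * (2 * b - p - 1) / ((2 * b - 2) * p)
  pv <- pf(fstat, p, 2 * b - p - 1, lower.tail = FALSE)
  padj <- pmin(1, pv * length(positions))
  out <- tibble::tibble(position = positions, d2 = d2, statistic = fstat,
                        p_value = pv, p_adj = padj,
                        significant = padj < alpha)
  class(out) <- c("distance_function", class(out))
  attr(out, "b") <- b
  attr(out, "alpha") <- alpha
  attr(out, "p_dim") <- p
  out
}

#' Confirm borders across multiple window sizes
#'
#' For every window size the significant global maximum of the distance
#' function is located (ties broken toward the lower index and flagged).
#' A position is a confirmed border when it is the significant global
#' maximum, up to +-1 position, for at least `confirm_fraction` of the
#' window sizes.
#'
#' @inheritParams sliding_distance
#' @param window_sizes Integer vector of window sizes (all must be valid
#'   for the sequence length).
#' @param confirm_fraction Required fraction of window sizes supporting a
#'   position.
#' @return An object of class `border_result` with `confirmed` (tibble:
#'   `position`, `support`, `fraction`), `maxima` (per-window global
#'   maxima), and the detection parameters.  Use [tidy()] / [glance()].
#' @export
find_borders <- function(features, window_sizes = 12:24,
                         confirm_fraction = 0.8, alpha = 0.05,
                         shrinkage = 0) {
  if (length(window_sizes) == 0L) abort("`window_sizes` must not be empty.")
  X <- features_to_matrix(features)
  n <- nrow(X)
  p <- ncol(X)
  ws <- sort(unique(as.integer(window_sizes)))
  if (any(2 * ws > n))
    abort(sprintf("Window size %d is too large for %d profiles.",
                  max(ws), n))
  maxima_all <- list()
  confirmed <- list()

  # One confirmed border claims its segment; the flanking sub-segments
  # are then searched independently, so several well-separated borders
  # can each be the (significant) global maximum of their own segment.
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    wv <- ws[2 * ws <= len & 2 * ws > p + 1]
    if (length(wv) == 0L) return(invisible())
    seg <- X[lo:hi, , drop = FALSE]
    maxima <- dplyr::bind_rows(purrr::map(wv, function(b) {
      dfun <- sliding_distance(seg, b, alpha = alpha, shrinkage = shrinkage)
      imax <- which(dfun$d2 == max(dfun$d2))
      tibble::tibble(b = b, position = lo - 1L + dfun$position[imax[1]],
                     d2 = dfun$d2[imax[1]],
                     significant = dfun$significant[imax[1]],
                     tie = length(imax) > 1L, lo = lo, hi = hi)
    }))
    maxima_all[[length(maxima_all) + 1L]] <<- maxima
    sig <- maxima$position[maxima$significant]
    if (length(sig) == 0L) return(invisible())
    support <- vapply(lo:hi, function(i) sum(abs(sig - i) <= 1), integer(1))
    best <- lo:hi
    best <- best[which.max(support)]
    nsup <- max(support)
    if (nsup < confirm_fraction * length(wv)) return(invisible())
    confirmed[[length(confirmed) + 1L]] <<- tibble::tibble(
      position = best, support = nsup, n_windows = length(wv),
      fraction = nsup / length(wv))
    recurse(lo, best - 1L)
    recurse(best, hi)
  }
  recurse(1L, n)

  confirmed <- if (length(confirmed) > 0)
    dplyr::arrange(dplyr::bind_rows(confirmed), .data$position)
  else tibble::tibble(position = integer(), support = integer(),
                      n_windows = integer(), fraction = numeric())
  structure(list(confirmed = confirmed, maxima = dplyr::bind_rows(maxima_all),
                 window_sizes = ws,
                 confirm_fraction = confirm_fraction, alpha = alpha,
                 n_profiles = n),
            class = "border_result")
}

#' @export
print.border_result <- function(x, ...) {
  cat(sprintf("<border_result>  %d profile positions, windows %s, alpha %.3g\n",
              x$n_profiles, paste(range(x$window_sizes), collapse = ".."),
              x$alpha))
  if (nrow(x$confirmed) == 0) {
    cat("  no confirmed borders\n")
  } else {
    cat(sprintf("  confirmed border at position %d (support %d/%d windows)\n",
                x$confirmed$position, x$confirmed$support,
                length(x$window_sizes)))
  }
  invisible(x)
}

#' @rdname find_borders
#' @param x A `border_result`.
#' @param ... Unused.
#' @export
tidy.border_result <- function(x, ...) x$confirmed

#' @rdname find_borders
#' @export
glance.border_result <- function(x, ...) {
  tibble::tibble(n_confirmed = nrow(x$confirmed),
                 n_windows = length(x$window_sizes),
                 confirm_fraction = x$confirm_fraction,
                 alpha = x$alpha, n_profiles = x$n_profiles)
}

#' Arc-length agreement between two sets of border positions
#'
#' Greedily matches each border of `a` to the nearest border of `b`
#' (closest pairs first); the distance is reported along the outer
#' contour in micrometres.  Unmatched borders on either side are
#' reported as misses.
#'
#' @param a,b Border positions as profile indices (e.g.
#'   `tidy(result)$position`).
#' @param arc_positions_um Arc-length position (um) of each profile index
#'   along the outer contour (attribute `seed_arc_um` of
#'   [sample_profiles()]), or a scalar profile spacing in um.
#' @return A tibble with `a_position`, `b_position`, `distance_um`,
#'   `matched`.
#' @export
border_agreement <- function(a, b, arc_positions_um) {
  pos_um <- function(p) {
    if (length(arc_positions_um) == 1L) return(p * arc_positions_um)
    stats::approx(seq_along(arc_positions_um), arc_positions_um, p, rule = 2)$y
  }
  au <- pos_um(a); bu <- pos_um(b)
  res <- tibble::tibble(a_position = numeric(), b_position = numeric(),
                        distance_um = numeric(), matched = logical())
  ai <- seq_along(au); bi <- seq_along(bu)
  while (length(ai) > 0L && length(bi) > 0L) {
    d <- abs(outer(au[ai], bu[bi], "-"))
    k <- arrayInd(which.min(d), dim(d))
    res <- dplyr::bind_rows(res, tibble::tibble(
      a_position = a[ai[k[1]]], b_position = b[bi[k[2]]],
      distance_um = d[k], matched = TRUE))
    ai <- ai[-k[1]]; bi <- bi[-k[2]]
  }
  for (i in ai) res <- dplyr::bind_rows(res, tibble::tibble(
    a_position = a[i], b_position = NA_real_, distance_um = NA_real_,
    matched = FALSE))
  for (j in bi) res <- dplyr::bind_rows(res, tibble::tibble(
    a_position = NA_real_, b_position = b[j], distance_um = NA_real_,
    matched = FALSE))
  res
}
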