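# Internal numeric helpers shared across modules.

# Bilinear interpolation on a matrix.  Coordinates are 0-based,
# pixel-centre convention: (x, y) = (0, 0) is the centre of m[1, 1],
# x runs along columns, y along rows.  Values are clamped to the grid
# edge (constant extrapolation over at most half a pixel).
bilinear_interp <- function(m, x, y) {
  nr <- nrow(m)
  nc <- ncol(m)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2L)
  y0 <- pmin(floor(y), nr - 2L)
  x0 <- pmax(x0, 0L)
  y0 <- pmax(y0, 0L)
  fx <- x - x0
  fy <- y - y0
  i00 <- (x0) * nr + y0 + 1
  v00 <- m[i00]
  v10 <- m[i00 + nr]      # x0+1, y0
  v01 <- m[i00 + 1]       # x0,   y0+1
  v11 <- m[i00 + nr + 1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

# Nearest-neighbour resample of a matrix to target dimensions, assuming
# both cover the same physical extent.
resample_nearest <- function(m, nr, nc) {
  ri <- pmin(pmax(ceiling((seq_len(nr) - 0.5) * nrow(m) / nr), 1L), nrow(m))
  ci <- pmin(pmax(ceiling((seq_len(nc) - 0.5) * ncol(m) / nc), 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Block mean over k x k pixel blocks (trailing partial blocks dropped).
block_mean <- function(m, k) {
  nr <- (nrow(m) %/% k) * k
  nc <- (ncol(m) %/% k) * k
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- array(m, c(k, nr %/% k, nc))
  s <- colSums(a)                       # (nr/k) x nc
  a2 <- array(t(s), c(k, nc %/% k, nr %/% k))
  t(colSums(a2)) / (k * k)
}

# Gaussian smoothing in pixels (EBImage expects image in [0, 1]-ish but
# gblur is linear, so scaling is irrelevant).
gaussian_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  img <- EBImage::as.Image(t(m))
  t(EBImage::imageData(EBImage::gblur(img, sigma = sigma_px)))
}

# Rank-based area under the ROC curve of `values` for `positive`.
auc_rank <- function(values, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(values)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic sub-sampling: at most n elements, evenly strided.
stride_sample <- function(idx, n) {
  if (length(idx) <= n) return(idx)
  idx[round(seq(1, length(idx), length.out = n))]
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, name) {
  if (!is_scalar_number(x)) abort(paste0("`", name, "` must be a single finite number."))
  invisible(x)
}
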