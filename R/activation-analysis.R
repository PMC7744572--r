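# Mutual-information similarity of filter activations, characteristic
# filters and cytoarchitectonic feature-level assignment.

#' Normalize a filter activation map to the unit interval
#'
#' The smallest value strictly greater than zero serves as the lower
#' bound `a` and the maximum as `M`: values `<= a` map to 0, all others
#' to `(v - a) / (M - a)`.  All-zero or constant maps come back as
#' all-zero with attribute `degenerate = TRUE`.
#'
#' @param map Numeric matrix of non-negative activations.
#' @return Matrix in `[0, 1]` with attributes `lower_bound` and
#'   `degenerate`.
#' @export
normalize_activation <- function(map) {
  if (any(!is.finite(map))) abort("Activation map contains non-finite values.")
  pos <- map[map > 0]
  if (length(pos) == 0L || max(map) <= min(pos)) {
    out <- map * 0
    attr(out, "lower_bound") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  a <- min(pos)
  M <- max(map)
  out <- (map - a) / (M - a)
  out[map <= a] <- 0
  attr(out, "lower_bound") <- a
  attr(out, "degenerate") <- FALSE
  out
}

bin_index <- function(v, bins) {
  v <- as.vector(v)
  if (any(v < -1e-9) || any(v > 1 + 1e-9))
    abort("Values must lie in [0, 1]; normalize the maps first.")
  pmin(as.integer(floor(pmin(pmax(v, 0), 1) * bins)), bins - 1L)
}

#' Joint histogram of two normalized maps
#'
#' Bins both maps into `bins` equal-width bins over `[0, 1]`
#' (`[i/bins, (i+1)/bins)`, top bin closed) and returns the joint
#' probability table: entry `(i, j)` is the fraction of positions with
#' `x` in bin `i` and `y` in bin `j`.
#'
#' @param x,y Numeric matrices/vectors of equal length with values in
#'   `[0, 1]` (resample to a common reference resolution first).
#' @param bins Number of bins (256, with bin edges at `i/256`).
#' @return `bins x bins` matrix summing to 1.
#' @export
joint_histogram <- function(x, y, bins = 256L) {
  if (length(x) != length(y))
    abort("`x` and `y` must have the same number of positions; resample to the reference resolution first.")
  ix <- bin_index(x, bins)
  iy <- bin_index(y, bins)
  tab <- tabulate(ix + bins * iy + 1L, nbins = bins * bins)
  matrix(tab, bins, bins) / length(ix)
}

#' Mutual information of two normalized maps, in bits
#'
#' `MI = sum_ij p_ij log2(p_ij / (p_i. p_.j))` over the joint histogram,
#' with the convention `0 log 0 = 0`.
#'
#' @inheritParams joint_histogram
#' @return Mutual information in bits (non-negative up to rounding).
#' @export
mutual_information <- function(x, y, bins = 256L) {
  P <- joint_histogram(x, y, bins)
  px <- rowSums(P)
  py <- colSums(P)
  nz <- which(P > 0)
  i <- ((nz - 1L) %% bins) + 1L
  j <- ((nz - 1L) %/% bins) + 1L
  sum(P[nz] * log2(P[nz] / (px[i] * py[j])))
}

#' Shannon entropy of a normalized map, in bits
#'
#' @inheritParams joint_histogram
#' @export
entropy_bits <- function(x, bins = 256L) {
  p <- tabulate(bin_index(x, bins) + 1L, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Pairwise mutual-information matrix of an activation stack
#'
#' Normalizes every map ([normalize_activation()]), resamples all maps
#' to a common reference resolution by nearest neighbour, and computes
#' the mutual information of every unordered pair.  The diagonal holds
#' each map's entropy.  Degenerate (constant) maps get zero rows and are
#' flagged.
#'
#' @param stack An [extract_activations()] stack (or plain list of
#'   matrices).
#' @param bins Histogram bins.
#' @param reference_dim Target `c(rows, cols)`; defaults to the largest
#'   map in the stack (the input-image resolution).
#' @return An object of class `mi_matrix`: symmetric `matrix`, the map
#'   `provenance`, `degenerate` flags and metadata (`bins`,
#'   `unit = "bits"`).
#' @export
pairwise_mi <- function(stack, bins = 256L, reference_dim = NULL) {
  maps <- if (inherits(stack, "activation_stack")) stack$maps else stack
  prov <- if (inherits(stack, "activation_stack")) stack$provenance else
    tibble::tibble(map = seq_along(maps))
  m <- length(maps)
  if (m < 2L) abort("Need at least two maps.")
  if (is.null(reference_dim)) {
    areas <- vapply(maps, length, numeric(1))
    reference_dim <- dim(maps[[which.max(areas)]])
  }
  idx <- vector("list", m)
  marg <- vector("list", m)
  degenerate <- logical(m)
  for (i in seq_len(m)) {
    nm <- normalize_activation(maps[[i]])
    degenerate[i] <- attr(nm, "degenerate")
    r <- resample_nearest(nm, reference_dim[1], reference_dim[2])
    idx[[i]] <- bin_index(r, bins)
    marg[[i]] <- tabulate(idx[[i]] + 1L, nbins = bins) / length(idx[[i]])
  }
  N <- reference_dim[1] * reference_dim[2]
  M <- matrix(0, m, m)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  for (i in seq_len(m)) {
    if (degenerate[i]) next
    M[i, i] <- ent(marg[[i]])
    if (i == m) break
    for (j in (i + 1):m) {
      if (degenerate[j]) next
      tab <- tabulate(idx[[i]] + bins * idx[[j]] + 1L, nbins = bins * bins)
      nz <- which(tab > 0L)
      p <- tab[nz] / N
      bi <- ((nz - 1L) %% bins) + 1L
      bj <- ((nz - 1L) %/% bins) + 1L
      mi <- sum(p * log2(p / (marg[[i]][bi] * marg[[j]][bj])))
      M[i, j] <- mi
      M[j, i] <- mi
    }
  }
  structure(list(values = M, provenance = prov, degenerate = degenerate,
                 bins = bins, unit = "bits", reference_dim = reference_dim),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf("<mi_matrix>  %d x %d maps, %d bins, %s; %d degenerate map(s)\n",
              nrow(x$values), ncol(x$values), x$bins, x$unit,
              sum(x$degenerate)))
  invisible(x)
}

#' @rdname pairwise_mi
#' @param x An `mi_matrix`.
#' @param ... Unused.
#' @export
tidy.mi_matrix <- function(x, ...) {
  m <- nrow(x$values)
  pairs <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(map_a = pairs[, 1], map_b = pairs[, 2],
                 mi_bits = x$values[pairs])
}

#' Identify characteristic filter activations
#'
#' For every map, the `k` partners with the highest mutual information
#' (self excluded, ties at rank `k` broken toward the lower map index)
#' form its compilation; the map is characteristic for its network layer
#' when at least `min_same_layer` of the partners come from the same
#' network layer (of the same network instance).
#'
#' @param mi A [pairwise_mi()] result whose provenance carries
#'   `network_layer` (and optionally `instance`).
#' @param k Compilation size.
#' @param min_same_layer Required same-layer partners.
#' @return A tibble of class `characteristic_set`: `map`,
#'   `network_layer`, `n_same_layer`, `characteristic`, `tie_at_k`, and
#'   a `partners` list-column.
#' @export
characteristic_filters <- function(mi, k = 12L, min_same_layer = 3L) {
  if (!inherits(mi, "mi_matrix")) abort("`mi` must be a pairwise_mi() result.")
  prov <- mi$provenance
  if (!"network_layer" %in% names(prov))
    abort("Provenance lacks `network_layer`; extract maps with provenance.")
  m <- nrow(mi$values)
  if (k >= m) abort(sprintf("k = %d must be smaller than the number of maps (%d).", k, m))
  inst <- if ("instance" %in% names(prov)) prov$instance else rep("cnn1", m)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    cand <- setdiff(which(inst == inst[i]), i)
    v <- mi$values[i, cand]
    ord <- order(-v, cand)
    top <- cand[ord[seq_len(min(k, length(cand)))]]
    tie_at_k <- length(cand) > k && v[ord[k]] == v[ord[k + 1]]
    nsl <- sum(prov$network_layer[top] == prov$network_layer[i])
    rows[[i]] <- tibble::tibble(
      map = i, instance = inst[i], network_layer = prov$network_layer[i],
      n_same_layer = nsl, characteristic = nsl >= min_same_layer,
      tie_at_k = tie_at_k, partners = list(top))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("characteristic_set", class(out))
  attr(out, "k") <- k
  attr(out, "min_same_layer") <- min_same_layer
  out
}

#' Full activation analysis of a trained segmenter on a phantom
#'
#' Convenience wrapper chaining [extract_activations()],
#' [pairwise_mi()], [characteristic_filters()] and [assign_levels()].
#' Similarity and the characteristic criterion are evaluated on an
#' analysis window (by default centred mid-depth on the first true
#' border); characteristic maps of the superficial network layers
#' (<= 12) are level-scored on that window, while deeper-layer maps —
#' whose resolution is too coarse for a local read-out — are scored on
#' the whole section.
#'
#' @param segmenter A [train_segmenter()] model.
#' @param phantom The phantom to analyse (ground truth required).
#' @param center Window centre `c(row, col)`; default mid-depth at the
#'   first true border.
#' @param window_px Analysis window edge in pixels.
#' @param branches Branches whose units are analysed.
#' @param thresholds,aoi Passed to [assign_levels()].
#' @return A list with `stack` (window activations), `mi`,
#'   `characteristic` and `levels`.
#' @export
analyse_activations <- function(segmenter, phantom, center = NULL,
                                window_px = 384L,
                                branches = c("hr", "exp"),
                                thresholds = c(cell = 0.5, layer = 0.85,
                                               area = 0.85),
                                aoi = 1L) {
  center <- center %||% analysis_center(phantom)
  stack <- extract_activations(segmenter, phantom, center = center,
                               window_px = window_px, branches = branches)
  mi <- pairwise_mi(stack)
  ch <- characteristic_filters(mi)
  ch_ids <- ch$map[ch$characteristic]
  shallow_ids <- ch_ids[ch$network_layer[ch_ids] <= 12]
  deep_ids <- ch_ids[ch$network_layer[ch_ids] > 12]
  levels <- list()
  if (length(shallow_ids) > 0)
    levels$shallow <- assign_levels(stack, phantom, which_maps = shallow_ids,
                                    thresholds = thresholds, aoi = aoi)
  if (length(deep_ids) > 0) {
    img <- phantom$image
    # deep layers live in the expanding branch; extracting only that
    # branch keeps the whole-section stack small
    section <- extract_activations(
      segmenter, phantom,
      center = c(nrow(img) %/% 2L, ncol(img) %/% 2L),
      window_px = max(dim(img)), branches = "exp")
    wk <- paste(stack$provenance$network_layer, stack$provenance$unit)
    sk <- paste(section$provenance$network_layer, section$provenance$unit)
    sec_ids <- match(wk[deep_ids], sk)
    lev_deep <- assign_levels(section, phantom, which_maps = sec_ids,
                              thresholds = thresholds, aoi = aoi)
    lev_deep$map <- deep_ids
    levels$deep <- lev_deep
  }
  levels <- dplyr::arrange(dplyr::bind_rows(levels), .data$map)
  class(levels) <- c("level_assignment", class(levels))
  attr(levels, "thresholds") <- thresholds
  list(stack = stack, mi = mi, characteristic = ch, levels = levels)
}

#' Assign cytoarchitectonic feature levels to activation maps
#'
#' Scores every map against the phantom's ground truth in the analysed
#' window: `score_cell` is the absolute Spearman correlation with the
#' locally smoothed cell-body density (cellular, fine-scale structure);
#' `score_layer` is the best two-class ranking separation (area under
#' the ROC curve, folded so 0.5 is chance) of the map for one cortical
#' layer against the rest of the cortex; `score_area` is the same for
#' the area of interest against the rest of the tissue.  The winning
#' score, when above its threshold, assigns the map to the first
#' (cellular), second (laminar) or third (areal) feature level.
#'
#' This is a quantitative proxy for expert visual categorisation, not a
#' claim of equivalence to it.
#'
#' @param stack An [extract_activations()] stack (with window geometry).
#' @param phantom The phantom the activations were computed on.
#' @param which_maps Map ids to score (default: all; typically the
#'   characteristic maps).
#' @param thresholds Named vector with elements `cell`, `layer`, `area`.
#' @param aoi Area code of the area of interest.
#' @param sigma_um Gaussian smoothing bandwidth for the cell-density
#'   field and the cellular score.
#' @param sigma_area_um Smoothing bandwidth for the areal score: the
#'   area separation is judged on local mean activation at the GLI
#'   measuring-field scale, because normalized activations are sparse
#'   (many exact zeros) and pixel-level ranking would be dominated by
#'   ties rather than by regional selectivity.
#' @param max_px Pixel budget per score (evenly strided subsample).
#' @return A tibble of class `level_assignment` with the three scores,
#'   the best-separated layer and the assigned `level` (`"first"`,
#'   `"second"`, `"third"` or `"unassigned"`).
#' @export
assign_levels <- function(stack, phantom, which_maps = NULL,
                          thresholds = c(cell = 0.5, layer = 0.85, area = 0.85),
                          aoi = 1L, sigma_um = 10, sigma_area_um = 20,
                          max_px = 20000L) {
  if (!inherits(stack, "activation_stack"))
    abort("`stack` must be an activation_stack.")
  if (!inherits(phantom, "cortical_phantom"))
    abort("`phantom` must be a cortical_phantom (ground-truth masks are required).")
  w <- stack$window
  which_maps <- which_maps %||% stack$provenance$map
  res <- phantom$config$resolution_um
  crop_i <- function(m) extract_window(m, w$row, w$col, w$px, 0L)
  al <- crop_i(phantom$area_labels)
  ll <- crop_i(phantom$layer_labels)
  cm <- crop_i(matrix(as.numeric(phantom$cell_mask),
                      nrow(phantom$cell_mask), ncol(phantom$cell_mask)))
  wm_code <- phantom$areas$code[phantom$areas$name == "WM"]
  cortex <- al != 0L & al != wm_code
  tissue <- al != 0L
  cellf <- gaussian_smooth(cm, sigma_um / res)
  i_cortex <- stride_sample(which(cortex), max_px)
  i_tissue <- stride_sample(which(tissue), max_px)
  layer_codes <- sort(unique(ll[cortex]))
  layer_names <- setNames(phantom$layers$name, phantom$layers$code)
  auc_fold <- function(v, pos) {
    a <- auc_rank(v, pos)
    if (is.na(a)) NA_real_ else max(a, 1 - a)
  }
  rows <- lapply(which_maps, function(mid) {
    mp <- resample_nearest(stack$maps[[mid]], w$px, w$px)
    # local mean activation vs local cell density, both at the same scale
    mps <- gaussian_smooth(mp, sigma_um / res)
    vc <- mps[i_cortex]
    score_cell <- if (sd(vc) == 0 || sd(cellf[i_cortex]) == 0) 0 else
      abs(cor(vc, cellf[i_cortex], method = "spearman"))
    vc <- mp[i_cortex]
    aucs <- vapply(layer_codes, function(code)
      auc_fold(vc, ll[i_cortex] == code), numeric(1))
    score_layer <- if (all(is.na(aucs))) 0 else max(aucs, na.rm = TRUE)
    best_layer <- if (score_layer > 0)
      layer_names[[as.character(layer_codes[which.max(aucs)])]] else NA_character_
    mpa <- gaussian_smooth(mp, sigma_area_um / res)
    score_area <- auc_fold(mpa[i_tissue], al[i_tissue] == aoi)
    score_area <- if (is.na(score_area)) 0 else score_area
    scores <- c(first = score_cell, second = score_layer, third = score_area)
    win <- which.max(scores)
    thr <- thresholds[c("cell", "layer", "area")][win]
    prov <- stack$provenance[stack$provenance$map == mid, ]
    tibble::tibble(map = mid, instance = prov$instance,
                   branch = prov$branch, network_layer = prov$network_layer,
                   unit = prov$unit,
                   score_cell = score_cell, score_layer = score_layer,
                   best_layer = best_layer, score_area = score_area,
                   level = if (scores[win] > thr) names(scores)[win] else "unassigned")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("level_assignment", class(out))
  attr(out, "thresholds") <- thresholds
  out
}
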