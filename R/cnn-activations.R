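# Filter-activation extraction: one post-ReLU 2D map per network unit.

#' Extract per-unit filter activation maps
#'
#' Runs the network in inference mode on a (window of a) section image
#' and records the post-ReLU output of every unit of the requested
#' branches: one 2D activation map per unit, at the native resolution of
#' its network layer, with full provenance (branch, block, network
#' layer, unit index).
#'
#' @param object A [train_segmenter()] model, or a raw model built by
#'   the engine (e.g. an untrained full-size instance).
#' @param image Greyscale matrix or a [render_phantom()] result.
#' @param center Patch centre `c(row, col)` (1-based pixels); default is
#'   the image centre.
#' @param window_px Edge length of the analysed square window (rounded
#'   up to a multiple of 8); default covers the image short side.
#' @param branches Branches to record: any of `"hr"`, `"lr"`, `"exp"`.
#'   The default follows the convention of analysing the
#'   high-resolution contracting and expanding branches.
#' @param instance Label for this network instance in the provenance.
#' @param background Background greyscale value used for padding and
#'   input scaling (taken from the segmenter when available).
#' @return An object of class `activation_stack`: `maps` (list of
#'   matrices, all values >= 0), `provenance` tibble and the analysed
#'   window geometry.
#' @export
extract_activations <- function(object, image, center = NULL, window_px = NULL,
                                branches = c("hr", "exp"), instance = "cnn1",
                                background = NULL) {
  if (inherits(object, "cortex_segmenter")) {
    model <- object$model
    background <- background %||% object$background
  } else {
    model <- object
    background <- background %||% 242
  }
  arch <- model$arch
  if (inherits(image, "cortical_phantom")) {
    background <- image$config$background
    image <- image$image
  }
  if (!all(branches %in% c("hr", "lr", "exp")))
    abort("`branches` must be a subset of c('hr', 'lr', 'exp').")
  center <- center %||% c(nrow(image) %/% 2L, ncol(image) %/% 2L)
  window_px <- window_px %||% min(dim(image))
  window_px <- as.integer(ceiling(window_px / 8) * 8)
  if (window_px < 16L)
    abort("Analysis window is smaller than the minimum valid network input.")
  io <- make_inputs(image, center[1], center[2], window_px, arch, background)
  fwd <- model_forward(model, io$xhr, io$xlr, training = FALSE, keep_acts = TRUE)

  ly <- arch$layers
  ids <- layer_ids(arch)
  keep <- ly$branch %in% branches
  ord <- order(ly$network_layer[keep])
  sel <- which(keep)[ord]
  maps <- list()
  prov <- vector("list", length(sel))
  for (si in seq_along(sel)) {
    i <- sel[si]
    A <- fwd$acts[[ids[i]]]
    d <- dim(A)
    unit_maps <- lapply(seq_len(d[3]), function(u) A[, , u])
    maps <- c(maps, unit_maps)
    prov[[si]] <- tibble::tibble(
      instance = instance, branch = ly$branch[i], block = ly$block[i],
      layer_in_block = ly$layer_in_block[i],
      network_layer = ly$network_layer[i],
      unit = seq_len(d[3]), nrow = d[1], ncol = d[2])
  }
  prov <- dplyr::bind_rows(prov)
  prov$map <- seq_len(nrow(prov))
  structure(list(maps = maps, provenance = prov,
                 window = list(row = center[1], col = center[2],
                               px = window_px, res_um = arch$hr_res_um)),
            class = "activation_stack")
}

#' @export
print.activation_stack <- function(x, ...) {
  cat(sprintf("<activation_stack>  %d maps from %d network layers (%s), window %d px\n",
              length(x$maps), length(unique(x$provenance$network_layer)),
              paste(unique(x$provenance$branch), collapse = "/"),
              x$window$px))
  invisible(x)
}

#' Concatenate activation stacks from several network instances
#'
#' @param ... `activation_stack` objects over the same window.
#' @return A single `activation_stack`; map ids are renumbered.
#' @export
bind_stacks <- function(...) {
  stacks <- list(...)
  maps <- do.call(c, lapply(stacks, `[[`, "maps"))
  prov <- dplyr::bind_rows(lapply(stacks, `[[`, "provenance"))
  prov$map <- seq_len(nrow(prov))
  structure(list(maps = maps, provenance = prov, window = stacks[[1]]$window),
            class = "activation_stack")
}
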