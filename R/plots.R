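# ggplot2 visualisations for the main result types.

raster_tibble <- function(m, max_dim = 400L) {
  k <- max(1L, ceiling(max(dim(m)) / max_dim))
  rs <- seq(1L, nrow(m), by = k)
  cs <- seq(1L, ncol(m), by = k)
  sub <- m[rs, cs, drop = FALSE]
  tibble::tibble(x = rep(cs - 1L, each = length(rs)),
                 y = rep(rs - 1L, times = length(cs)),
                 value = as.vector(sub))
}

#' @describeIn render_phantom Plot the phantom image with contours and
#'   the true border positions.
#' @param object A `cortical_phantom`.
#' @param ... Unused.
#' @export
autoplot.cortical_phantom <- function(object, ...) {
  df <- raster_tibble(object$image)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_path(data = object$outer_contour, colour = "gold") +
    ggplot2::geom_path(data = object$inner_contour, colour = "steelblue") +
    ggplot2::geom_point(data = object$true_border, colour = "red", size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Synthetic cortical phantom",
                  subtitle = "gold: layer I/II contour; blue: GM/WM contour; red: true border") +
    ggplot2::theme_minimal()
}

#' @describeIn compute_gli Plot the GLI image.
#' @param object A `gli_image`.
#' @param ... Unused.
#' @export
autoplot.gli_image <- function(object, ...) {
  df <- raster_tibble(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "GLI") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Grey level index (%g um fields)",
                                  object$field_size_um)) +
    ggplot2::theme_minimal()
}

#' @describeIn sliding_distance Plot the distance function with
#'   significant positions highlighted.
#' @param object A `distance_function`.
#' @param ... Unused.
#' @export
autoplot.distance_function <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$d2)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red")) +
    ggplot2::labs(x = "profile position", y = expression(D^2),
                  title = sprintf("Mahalanobis distance (window size %d)",
                                  attr(object, "b"))) +
    ggplot2::theme_minimal()
}

#' @describeIn find_borders Plot per-window significant maxima and
#'   confirmed borders.
#' @param object A `border_result`.
#' @export
autoplot.border_result <- function(object, ...) {
  ggplot2::ggplot(object$maxima,
                  ggplot2::aes(x = .data$position, y = .data$b)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red")) +
    ggplot2::geom_vline(xintercept = object$confirmed$position,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "profile position", y = "window size",
                  title = "Global distance maxima across window sizes",
                  subtitle = "dashed: confirmed borders") +
    ggplot2::theme_minimal()
}

#' @describeIn pairwise_mi Heatmap of the mutual-information matrix
#'   (lightness-ordered colour map).
#' @param object An `mi_matrix`.
#' @export
autoplot.mi_matrix <- function(object, ...) {
  m <- object$values
  df <- tibble::tibble(a = rep(seq_len(nrow(m)), ncol(m)),
                       b = rep(seq_len(ncol(m)), each = nrow(m)),
                       mi = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$mi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "MI (bits)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "map", y = "map",
                  title = "Pairwise mutual information of filter activations") +
    ggplot2::theme_minimal()
}

#' @describeIn assign_levels Scores of every scored map by network
#'   layer, coloured by assigned level.
#' @param object A `level_assignment`.
#' @export
autoplot.level_assignment <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("score_cell", "score_layer", "score_area"),
                              names_to = "score", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$network_layer, y = .data$value,
                                     colour = .data$level)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::facet_wrap(~score, ncol = 1) +
    ggplot2::labs(x = "network layer", y = "score",
                  title = "Cytoarchitectonic feature-level scores") +
    ggplot2::theme_minimal()
}

#' Compilation sheet: a map and its highest-MI partners
#'
#' Displays a reference filter activation together with its top-`k`
#' mutual-information partners, using a colour map that emphasises
#' lightness changes over changes in hue.
#'
#' @param stack An [extract_activations()] stack.
#' @param mi The matching [pairwise_mi()] result.
#' @param map Reference map id.
#' @param k Number of partners.
#' @param max_dim Downsampling cap per panel.
#' @return A ggplot object.
#' @export
plot_compilation <- function(stack, mi, map, k = 12L, max_dim = 128L) {
  v <- mi$values[map, ]
  v[map] <- -Inf
  partners <- order(-v, seq_along(v))[seq_len(k)]
  ids <- c(map, partners)
  dfs <- purrr::imap(ids, function(id, pos) {
    nm <- normalize_activation(stack$maps[[id]])
    df <- raster_tibble(nm, max_dim)
    df$panel <- sprintf("%s#%d (L%d)%s", if (pos == 1) "ref " else "",
                        id, stack$provenance$network_layer[id],
                        if (pos == 1) "" else sprintf(" MI %.2f", mi$values[map, id]))
    df$ord <- pos
    df
  })
  df <- dplyr::bind_rows(dfs)
  df$panel <- stats::reorder(df$panel, df$ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 7))
}
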