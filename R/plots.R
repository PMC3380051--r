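# ggplot2 views of the result objects.

#' @export
autoplot.cpnn <- function(object, ...) {
  stopifnot(object$trained)
  df <- tibble::tibble(epoch = seq_along(object$quantization_error),
                       qe = object$quantization_error)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$qe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Quantization error",
                  title = "CPNN training convergence")
}

#' Map of per-neuron TM output weights
#'
#' @param model A trained `cpnn`.
#' @return A ggplot tile map of the Kohonen grid colored by the TM
#'   output weight.
#' @export
plot_tm_map <- function(model) {
  df <- tidy(model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$TM)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column", y = "Row", fill = "TM weight",
                  title = "Kohonen map TM response")
}

#' @export
autoplot.rama_histogram <- function(object, ...) {
  bw <- attr(object, "bin_width")
  df <- dplyr::filter(tibble::as_tibble(object), .data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi_lo + bw / 2,
                                   y = .data$psi_lo + bw / 2,
                                   fill = .data$count)) +
    ggplot2::geom_tile(width = bw, height = bw) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = expression(phi ~ "(deg)"), y = expression(psi ~ "(deg)"),
                  fill = "Count", title = "Ramachandran histogram")
}

#' @export
autoplot.rdf_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r_mid, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "r (Å)", y = "g(r)",
                  title = "Radial distribution function")
}

#' @export
autoplot.helical_wheel <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$xx <- cos(df$azimuth * pi / 180)
  df$yy <- sin(df$azimuth * pi / 180)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$xx, y = .data$yy,
                                   color = .data$weight)) +
    ggplot2::geom_point(size = 5) +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$aa, .data$resno)),
                       vjust = -1.2, size = 3, color = "black") +
    ggplot2::scale_color_gradient2(low = "steelblue", mid = "grey85",
                                   high = "orange", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(color = "Hydropathy", title = "Helical wheel")
}
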