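# ggplot2 views of the result types.

#' @export
#' @rdname total_outflow
#' @param object An `outflow_series`.
#' @param ... Unused.
autoplot.outflow_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$outflow,
                                       colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time relative to event (s)",
                  y = expression(Q[j]^2 * (t)),
                  colour = "node",
                  title = "Normalized total information outflow") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname integrate_band
#' @param object A `band_adtf`.
autoplot.band_adtf <- function(object, ...) {
  df <- generics::tidy(object)
  df$edge <- paste(df$source, "→", df$sink)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$edge,
                                   fill = .data$theta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time relative to event (s)", y = "directed edge",
                  fill = expression(theta),
                  title = sprintf("Band-integrated ADTF (%g–%g Hz)",
                                  object$band[1], object$band[2])) +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname key_node_trajectory
#' @param object A `key_node_trajectory`.
autoplot.key_node_trajectory <- function(object, ...) {
  df <- object$trajectory
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$key_node,
                                   size = .data$degree)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time relative to event (s)", y = "key node",
                  size = "degree", title = "Key-node trajectory") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname classify_edge_dynamics
#' @param object An `edge_dynamics` tibble.
autoplot.edge_dynamics <- function(object, ...) {
  df <- dplyr::filter(object, .data$class != "unchanged")
  df$edge <- paste(df$source, "→", df$sink)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$edge, colour = .data$class)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$onset_s, xend = .data$offset_s,
                                       yend = .data$edge), linewidth = 2) +
    ggplot2::scale_colour_manual(values = c(enhanced = "#c0392b",
                                            weakened = "#27ae60")) +
    ggplot2::labs(x = "time relative to event (s)", y = "directed edge",
                  colour = NULL,
                  title = "Enhanced and weakened connections") +
    ggplot2::theme_minimal()
}
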