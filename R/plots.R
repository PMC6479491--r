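#' @exportS3Method ggplot2::autoplot
autoplot.rin_rmsd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "RMSD (Å)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.rin_rmsf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$residue_index + 1, .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue", y = "RMSF (Å)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.rin_sasa <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$sasa)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = expression(SASA ~ (nm^2)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.rin_occupancy <- function(object, ...) {
  df <- dplyr::mutate(object, label = factor(.data$label, levels = .data$label))
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$occupancy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "H-bond occupancy") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.essential_dynamics <- function(object, n = 20, ...) {
  df <- head(tidy(object), n)
  ggplot2::ggplot(df, ggplot2::aes(.data$component)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$eigenvalue)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$eigenvalue)) +
    ggplot2::labs(x = "eigenvector index", y = expression(eigenvalue ~ (nm^2)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.projection_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pc1, .data$pc2, colour = .data$time)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "PC1 (nm)", y = "PC2 (nm)", colour = "time (ps)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.free_energy_surface <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pc_a, .data$pc_b, fill = .data$delta_g)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", direction = -1) +
    ggplot2::labs(
      x = sprintf("PC%d (nm)", object$pc_pair[1]),
      y = sprintf("PC%d (nm)", object$pc_pair[2]),
      fill = expression(Delta * G ~ (kJ / mol))
    )
}

#' @exportS3Method ggplot2::autoplot
autoplot.centrality_table <- function(object,
                                      metric = c("betweenness", "closeness", "degree_norm"),
                                      ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(.data$node, .data[[metric]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue node", y = metric)
}

#' @exportS3Method ggplot2::autoplot
autoplot.centrality_diff <- function(object, ...) {
  th <- attr(object, "thresholds")
  df <- dplyr::mutate(object, label = factor(.data$label, levels = .data$label))
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$delta_cb, fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = th, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression("|" * Delta * C[B] * "|")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
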