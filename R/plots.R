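# Plot methods (ggplot2 is suggested, not required).

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}

#' Plot distance statistics as a mean-distance heat map
#'
#' @param object A `distance_stats`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.distance_stats <- function(object, ...) {
  need_ggplot2()
  ggplot2::ggplot(object, ggplot2::aes(x = .data$i, y = .data$j,
                                       fill = .data$mu)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean distance (nm)") +
    ggplot2::labs(x = "residue i", y = "residue j",
                  title = "Calpha pair distance means") +
    ggplot2::theme_minimal()
}

#' Plot per-epoch training losses
#'
#' @param object A `train_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.train_run <- function(object, ...) {
  need_ggplot2()
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$protein)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "distance-distribution loss") +
    ggplot2::theme_minimal()
}
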