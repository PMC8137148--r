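#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot population curves of a trajectory
#'
#' `type = "counts"` draws normalised cell counts over time per cell type
#' (the standard readout of competition kinetics); `type = "density"` the
#' mean local density.
#'
#' @param object a `cc_trajectory`.
#' @param type `"counts"` or `"density"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cc_trajectory <- function(object, type = c("counts", "density"), ...) {
  type <- match.arg(type)
  ps <- population_summary(object)
  ps <- ps[ps$n_cells > 0 | ps$frame == 0, ]
  if (type == "counts") {
    ggplot2::ggplot(ps, ggplot2::aes(.data$time_h, .data$norm_count,
                                     colour = .data$type)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)", y = "normalised cell count",
                    colour = NULL)
  } else {
    ggplot2::ggplot(ps, ggplot2::aes(.data$time_h, .data$mean_rho,
                                     colour = .data$type)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)",
                    y = expression(local~density~(mu*m^-2)), colour = NULL)
  }
}

#' Raster view of a lattice state
#'
#' Winners green, losers red, free space black; one tile per pixel.
#'
#' @param x a `cc_state` or label matrix.
#' @param types for a matrix, integer id-to-type map.
#' @return a ggplot.
#' @export
plot_snapshot <- function(x, types = NULL) {
  labels <- if (inherits(x, "cc_state")) x$labels else x
  if (is.null(types) && inherits(x, "cc_state")) types <- x$typ
  ty <- matrix(0L, nrow(labels), ncol(labels))
  ty[labels > 0L] <- if (is.null(types)) 1L else types[labels[labels > 0L]]
  px <- if (inherits(x, "cc_state")) x$pixel_size else 1
  d <- tibble(
    x = rep(seq_len(ncol(labels)) - 0.5, each = nrow(labels)) * px,
    y = rep(seq_len(nrow(labels)) - 0.5, times = ncol(labels)) * px,
    type = factor(c("free", "winner", "loser")[as.vector(ty) + 1L],
                  levels = c("free", "winner", "loser")))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$type)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(free = "black", winner = "#2ca02c",
                                          loser = "#d62728")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = NULL)
}

#' Plot a parameter sweep
#'
#' Loser survival fraction (or another outcome column) against the swept
#' parameter value, with across-replicate mean and standard deviation.
#'
#' @param object a [parameter_sweep()] result.
#' @param outcome column to plot.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cc_sweep <- function(object, outcome = "survival_fraction", ...) {
  d <- dplyr::summarise(dplyr::group_by(as_tibble(object), .data$value),
                        mean = mean(.data[[outcome]], na.rm = TRUE),
                        sd = stats::sd(.data[[outcome]], na.rm = TRUE),
                        .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = unique(object$parameter), y = outcome)
}
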