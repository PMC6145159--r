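map_to_df <- function(m, name) {
  tibble(row = rep(seq_len(nrow(m)), ncol(m)),
         col = rep(seq_len(ncol(m)), each = nrow(m)),
         value = as.vector(m), map = name)
}

#' Plot the maps of a material image
#'
#' Raster panels of the tissue and bone coefficient maps.
#'
#' @param object A [material_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.material_image <- function(object, ...) {
  df <- rbind(map_to_df(object$x1, "tissue (x1)"),
              map_to_df(object$x2, "bone (x2)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~map) +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "coef")
}

#' Plot a dual-energy image pair
#'
#' @param object A [dual_energy_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dual_energy_image <- function(object, ...) {
  df <- rbind(map_to_df(object$mu_L, "low energy"),
              map_to_df(object$mu_H, "high energy"))
  df$map <- factor(df$map, levels = c("low energy", "high energy"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~map) +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mu (1/cm)")
}

#' Plot experiment metrics
#'
#' Bias and SD per method, material and noise condition.
#'
#' @param object A `dect_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dect_experiment <- function(object, ...) {
  m <- object$metrics
  long <- rbind(
    tibble(method = m$method, material = m$material, noise = m$noise,
           metric = "bias", value = m$bias),
    tibble(method = m$method, material = m$material, noise = m$noise,
           metric = "sd", value = m$sd))
  ggplot2::ggplot(long, ggplot2::aes(.data$method, .data$value,
                                     fill = .data$noise)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(metric ~ material, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "coefficient units", fill = "noise")
}

#' Plot a training-loss history
#'
#' @param network A trained `fcn_network`.
#' @return A ggplot object of mean per-sample loss against epoch.
#' @export
plot_training_history <- function(network) {
  if (is.null(network$history)) stop("network has no training history",
                                     call. = FALSE)
  ggplot2::ggplot(network$history,
                  ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean loss (coefficient^2)")
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
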