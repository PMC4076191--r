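# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a landscape layer
#'
#' @param object a [landscape_grid()].
#' @param layer layer name (`"cover_type"`, `"lichen"`, `"cover"`,
#'   `"edge"`, `"altitude"`).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.landscape_grid <- function(object, layer = "cover_type", ...) {
  m <- object[[layer]]
  df <- tidyr::expand_grid(
    row = seq_len(object$nrows), col = seq_len(object$ncols)
  )
  ctr <- cell_center(object, df$row, df$col)
  df$x <- ctr[, 1]
  df$y <- ctr[, 2]
  df$value <- m[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = layer) +
    ggplot2::theme_minimal()
  if (layer == "cover_type") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value)))
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c()
  }
}

#' Plot tracks over an optional landscape
#'
#' @param tracks a track tibble (`id`, `x`, `y`).
#' @param grid optional [landscape_grid()] drawn underneath.
#' @param layer background layer name.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, grid = NULL, layer = "cover_type") {
  p <- if (is.null(grid)) {
    ggplot2::ggplot() +
      ggplot2::theme_minimal() +
      ggplot2::coord_equal()
  } else {
    autoplot.landscape_grid(grid, layer)
  }
  p +
    ggplot2::geom_path(
      data = tracks,
      ggplot2::aes(.data$x, .data$y, colour = .data$id),
      linewidth = 0.4
    ) +
    ggplot2::labs(colour = "individual")
}

#' Coefficient plot for an SSF fit
#'
#' Forest plot of the fitted coefficients with 95% intervals (robust when a
#' sandwich covariance is attached).
#'
#' @param object an [fit_clogit()] object.
#' @param ... passed to [tidy.ssf_fit()].
#' @return A ggplot.
#' @export
autoplot.ssf_fit <- function(object, ...) {
  td <- tidy(object, ...)
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high)
    ) +
    ggplot2::labs(x = "coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' Rank-bin frequency plot for a cross-validation result
#'
#' @param object an [kfold_cv()] object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ssf_cv <- function(object, ...) {
  df <- tibble::tibble(
    bin = seq_len(object$n_bins),
    freq = object$bin_freq
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$freq)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "rank bin (1 = lowest score)", y = "mean frequency per repetition",
      subtitle = sprintf(
        "r_s = %.2f (null %.2f)", object$mean_rs, object$null_mean_rs
      )
    ) +
    ggplot2::theme_minimal()
}

#' Per-class coefficient distributions of a scenario contrast
#'
#' Boxplots of the per-run RSF coefficients by landcover class and scenario,
#' starred where the rank test rejects at the 5% level.
#'
#' @param object a [scenario_contrast()] object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scenario_contrast <- function(object, ...) {
  sig <- object$beta_tests$class[
    !object$beta_tests$excluded & object$beta_tests$p_value < 0.05
  ]
  df <- object$beta
  df$label <- ifelse(df$class %in% sig,
    paste0(df$class, "*"), as.character(df$class)
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$label, .data$beta, fill = .data$scenario)
  ) +
    ggplot2::geom_boxplot(position = "dodge") +
    ggplot2::labs(x = "landcover class", y = "RSF coefficient") +
    ggplot2::theme_minimal()
}
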