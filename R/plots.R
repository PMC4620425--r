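#' Feature-overlay rendering
#'
#' Renders the superposition of selected features over a grayscale version
#' of a tongue image: each spec brightens its center partition by a fixed
#' increment (overlapping centers accumulate, clipped at 255) while the
#' border partitions are darkened by `border_decrement` (0 by default, i.e.
#' left fixed). Regions repeatedly covered by selected centers therefore
#' stand out as the brightest areas.
#'
#' @param image Background tongue image (used in grayscale).
#' @param specs Spec tibble of the selected features (may be empty).
#' @param increment Brightness added per overlapping center.
#' @param border_decrement Brightness subtracted per overlapping border.
#' @return A tongue image array.
#' @export
overlay_features <- function(image, specs, increment = 40,
                             border_decrement = 0) {
  image <- as_tongue_image(unclass(image))
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  if (nrow(specs) == 0) {
    warn("No specs to overlay; returning the grayscale background.")
  } else {
    fits <- specs$x >= 1 & specs$y >= 1 &
      specs$x + specs$w + 2 * specs$t - 1 <= TONGUE_WIDTH &
      specs$y + specs$h + 2 * specs$t - 1 <= TONGUE_HEIGHT
    if (any(!fits)) {
      warn(sprintf("%d out-of-frame spec(s) skipped.", sum(!fits)))
      specs <- specs[fits, , drop = FALSE]
    }
    for (i in seq_len(nrow(specs))) {
      x <- specs$x[i]; y <- specs$y[i]
      w <- specs$w[i]; h <- specs$h[i]; t <- specs$t[i]
      if (border_decrement != 0) {
        gray[y:(y + h + 2 * t - 1), x:(x + w + 2 * t - 1)] <-
          gray[y:(y + h + 2 * t - 1), x:(x + w + 2 * t - 1)] -
          border_decrement
      }
      ctr_r <- (y + t):(y + t + h - 1)
      ctr_c <- (x + t):(x + t + w - 1)
      gray[ctr_r, ctr_c] <- gray[ctr_r, ctr_c] + increment +
        if (border_decrement != 0) border_decrement else 0
    }
  }
  gray <- pmin(pmax(gray, 0), 255)
  as_tongue_image(array(rep(gray, 3), dim = c(dim(gray), 3)))
}

#' ROC curve plot
#'
#' @param x A [roc_points()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)",
                                  roc_trapezoid(x))) +
    ggplot2::theme_minimal()
}

#' Boosting-diagnostics plot
#'
#' Per-round selection strength `|a - 0.5|` and remaining example count.
#'
#' @param x A `roc_boost` fit.
#' @param ... Unused.
#' @return A ggplot (two facets).
#' @export
autoplot.roc_boost <- function(x, ...) {
  if (nrow(x$rounds) == 0) abort("Fit has no rounds to plot.")
  long <- tidyr::pivot_longer(
    dplyr::select(x$rounds, "round", "strength", "n_remaining_after"),
    -"round", names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, c("strength", "n_remaining_after"),
                        c("selection strength |a - 0.5|",
                          "examples remaining"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$round, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Boosting round", y = NULL,
                  title = sprintf("ROC-Boosting (%d rounds, stop: %s)",
                                  nrow(x$rounds), x$stop_reason)) +
    ggplot2::theme_minimal()
}

#' Raster plot of a tongue image
#'
#' @param image A tongue image array.
#' @return A ggplot using `geom_raster`.
#' @export
plot_tongue <- function(image) {
  image <- as_tongue_image(unclass(image))
  df <- tidyr::expand_grid(x = seq_len(TONGUE_WIDTH),
                           y = seq_len(TONGUE_HEIGHT))
  df$fill <- grDevices::rgb(as.vector(image[, , 1]) / 255,
                            as.vector(image[, , 2]) / 255,
                            as.vector(image[, , 3]) / 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
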