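#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an empirical variogram
#'
#' Semivariance against lag midpoint, with point size showing the pair count
#' and, optionally, a fitted exponential model curve.
#'
#' @param object An `empirical_variogram`.
#' @param fit Optional `variogram_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.empirical_variogram <- function(object, fit = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_area(name = "pairs") +
    ggplot2::labs(
      x = "lag distance (km)",
      y = expression(gamma(h) ~ "(µg/L)"^2),
      title = paste0("Empirical variogram (", attr(object, "estimator"), ")")
    ) +
    ggplot2::expand_limits(y = 0) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    hs <- seq(1e-6, max(df$lag), length.out = 200)
    line <- tibble::tibble(lag = hs, gamma = predict(fit$model, hs))
    p <- p + ggplot2::geom_line(data = line, colour = "firebrick")
  }
  p
}

#' Plot a fitted variogram with its empirical estimates
#'
#' @param object A `variogram_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variogram_fit <- function(object, ...) {
  emp <- new_empirical_variogram(object$emp, estimator = object$estimator,
                                 bins = NULL)
  autoplot(emp, fit = object)
}

#' Histogram of kriging cross-validation errors
#'
#' The distribution of leave-one-out prediction errors with the Tukey outer
#' fences marked; under a valid model the errors look Gaussian with no mass
#' beyond the fences.
#'
#' @param object A `cv_report`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_report <- function(object, bins = 30, ...) {
  fences <- tukey_fences(object$sites$error)
  ggplot2::ggplot(object$sites, ggplot2::aes(x = .data$error)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = fences$outer, linetype = "dashed") +
    ggplot2::labs(x = "cross-validation error (µg/L)", y = "count",
                  title = sprintf("LOO cross-validation errors (median SSPE %.3f)",
                                  object$median_sspe)) +
    ggplot2::theme_minimal()
}

#' Map a probability-of-deficiency surface
#'
#' Tile map of per-node probabilities (or their calibrated phrases) on the
#' prediction grid.
#'
#' @param object A `probability_surface`.
#' @param what `"probability"` for a continuous fill or `"phrase"` for the
#'   calibrated-phrase classes.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.probability_surface <- function(object, what = c("probability", "phrase"),
                                         ...) {
  what <- match.arg(what)
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(
      x = "longitude", y = "latitude",
      title = sprintf("P(serum Se < %.1f µg/L)", attr(object, "threshold"))
    ) +
    ggplot2::theme_minimal()
  if (what == "probability") {
    p + ggplot2::geom_tile(ggplot2::aes(fill = .data$probability)) +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "probability")
  } else {
    p + ggplot2::geom_tile(ggplot2::aes(fill = .data$phrase)) +
      ggplot2::scale_fill_viridis_d(name = NULL, drop = FALSE)
  }
}

#' Map a kriging prediction or variance surface
#'
#' @param predictions Tibble from [krige_ok()].
#' @param what `"prediction"` or `"kriging_variance"`.
#' @return A ggplot.
#' @export
plot_prediction_surface <- function(predictions, what = c("prediction", "kriging_variance")) {
  what <- match.arg(what)
  lab <- if (what == "prediction") "serum Se (µg/L)" else "kriging variance (µg/L)²"
  ggplot2::ggplot(predictions, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[what]])) +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}
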