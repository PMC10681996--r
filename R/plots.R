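#' Kaplan-Meier step plot
#'
#' @param km step table from [km_estimate()] (optionally grouped).
#' @param conf_int draw the pointwise confidence band.
#' @return A ggplot object.
#' @export
plot_km <- function(km, conf_int = FALSE) {
  has_group <- "group" %in% names(km)
  start <- if (has_group) {
    dplyr::reframe(dplyr::group_by(km, .data$group),
                   time = 0, survival = 1, lower = 1, upper = 1)
  } else {
    tibble::tibble(time = 0, survival = 1, lower = 1, upper = 1)
  }
  dat <- dplyr::bind_rows(start, km)
  p <- if (has_group) {
    ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$survival,
                                      color = .data$group))
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$survival))
  }
  if (conf_int && all(is.finite(km$lower))) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$lower),
                                linetype = "dashed", alpha = 0.5) +
      ggplot2::geom_step(ggplot2::aes(y = .data$upper),
                         linetype = "dashed", alpha = 0.5)
  }
  p + ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.asp_cutpoint <- function(object, ...) {
  tr <- object$trace[!object$trace$degenerate, ]
  ggplot2::ggplot(tr, ggplot2::aes(.data$cutoff, -log10(.data$p))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("%s cutoff candidate", object$marker),
      y = "-log10 Wald p",
      title = sprintf("IQR-restricted cutpoint scan (selected %.4g)",
                      object$cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.asp_fixed_cutoff <- function(object, ...) {
  plot_km(object$km) +
    ggplot2::labs(title = sprintf("%s > %g, log-rank p = %.3g",
                                  object$marker, object$cutoff,
                                  object$logrank$p))
}

#' @export
autoplot.asp_strata <- function(object, ...) {
  plot_km(object$km) +
    ggplot2::labs(title = sprintf("combined strata (%s)", object$mode))
}

#' Mid-axial slice of a PET volume with optional mask contour
#'
#' @param vol a [pet_volume()].
#' @param mask optional [tumor_mask()] overlaid as a filled contour.
#' @param k axial slice index (default midplane).
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, mask = NULL, k = NULL) {
  if (is.null(k)) k <- ceiling(dim(vol$data)[3] / 2)
  d <- dim(vol$data)
  df <- expand.grid(x = seq_len(d[1]) * vol$spacing[1],
                    y = seq_len(d[2]) * vol$spacing[2])
  df$suv <- as.vector(vol$data[, , k])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$suv)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm", fill = "SUV") +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    df$m <- as.vector(mask$data[, , k] * 1)
    if (any(df$m > 0)) {
      p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$m),
                                     breaks = 0.5, color = "red",
                                     data = df)
    }
  }
  p
}
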