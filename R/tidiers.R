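#' Tidy a calibration fit
#'
#' One row per fitted parameter: the five global post-treatment parameters,
#' the spatial mean of the local `gs` field, and the frozen pre-treatment
#' values, with their bounds.
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `lower`, `upper`, `scope`.
#' @export
tidy.calibration_fit <- function(x, ...) {
  b <- x$bounds
  row <- function(term, estimate, scope) {
    bb <- if (term == "gs_mean") bounds_for(b, "gs") else bounds_for(b, term)
    tibble::tibble(term = term, estimate = estimate,
                   lower = bb[1], upper = bb[2], scope = scope)
  }
  dplyr::bind_rows(
    row("g0", x$pre$g0, "global (pre-treatment)"),
    row("D0", x$pre$D0, "global (pre-treatment, frozen)"),
    row("gs_mean", mean(as.vector(x$post$gs)[x$free_px]), "local (mean over pixels)"),
    row("fs", x$post$fs, "global"),
    row("kd", x$post$kd, "global"),
    row("gd", x$post$gd, "global"),
    row("gamma_d", x$post$gamma_d, "global"),
    row("theta", x$post$theta, "global (narrow range)")
  )
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    ccc_well = x$ccc_well, ccc_pixel = x$ccc_pixel,
    n_pixels_included = x$n_pixels_included,
    rss = x$deviance, converged = x$converged, n_iter = x$n_iter)
}

#' @export
tidy.bootstrap_dist <- function(x, ...) x$summary

#' @export
glance.bootstrap_dist <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, residual_sd = x$sigma)
}

#' Heatmap time series of a well series
#'
#' @param object A [well_series()].
#' @param times Subset of times to show (default: up to 6 evenly spaced).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.well_series <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    times <- object$times[unique(round(seq(1, length(object$times),
                                           length.out = 6)))]
  }
  df <- dplyr::filter(tidy(object), .data$time_h %in% times)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~time_h, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "cells") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "column", y = "row",
      title = sprintf("Cell density maps (%g nM, replicate %s)",
                      object$dose_nM, as.character(object$replicate_id)))
}

#' Fitted versus measured total counts of a calibration
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  df <- tibble::tibble(
    time_h = object$fit_times,
    fitted = colSums(object$fitted),
    measured = NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "black") +
    ggplot2::geom_vline(xintercept = object$series_meta$t_dox_h,
                        linetype = "dashed") +
    ggplot2::labs(x = "time (h)", y = "total cell count",
                  title = sprintf("Calibrated fit, CCC_well = %.3f",
                                  object$ccc_well))
}

#' Bar chart of total-effect sensitivity indices
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  df <- tidy(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total_effect,
                                   y = .data$parameter)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "total-effect index", y = NULL,
                  title = sprintf("Variance-based sensitivity (%d evaluations)",
                                  object$n_evaluations))
}

#' Weekly forecast versus held-out measurements
#'
#' Total well counts: predicted segments (with bands when sampled) against
#' the measured course, weekly boundaries dashed.
#'
#' @param object A `prediction_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_trace <- function(object, ...) {
  df <- purrr::map_dfr(object$segments, function(s) tibble::tibble(
    week = s$week, time_h = s$times,
    predicted = well_totals(s$predicted)$total_count,
    measured = well_totals(s$measured)$total_count))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured), color = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted,
                                    group = .data$week), color = "black") +
    ggplot2::geom_vline(xintercept = object$boundaries, linetype = "dashed",
                        color = "grey70") +
    ggplot2::labs(x = "time (h)", y = "total cell count",
                  title = sprintf("Weekly forecasts, dose %g nM (replicate %d held out)",
                                  object$dose_nM, object$test_index))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
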