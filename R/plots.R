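#' Plot an outcome across study days
#'
#' Subject trajectories (thin lines) with day means +/- SD, the standard
#' presentation for repeated-measures retinal outcomes.
#'
#' @param study a `study_result`.
#' @param outcome `"rvpd"` or `"rt"`.
#' @return A ggplot object.
#' @export
plot_outcome_by_day <- function(study, outcome = c("rvpd", "rt")) {
  outcome <- match.arg(outcome)
  col <- if (outcome == "rvpd") "rvpd_pct" else "mean_rt_um"
  lab <- if (outcome == "rvpd") "rVPD (% of en-face area)" else "Mean retinal thickness (µm)"
  d <- study$per_subject_day
  summ <- dplyr::summarise(dplyr::group_by(d, .data$day),
                           m = mean(.data[[col]]), s = stats::sd(.data[[col]]),
                           .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data[[col]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject), alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_pointrange(data = summ,
                             ggplot2::aes(y = .data$m, ymin = .data$m - .data$s,
                                          ymax = .data$m + .data$s),
                             colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "Day", y = lab) +
    ggplot2::theme_minimal()
}

#' Scatter of day-2 deltas with the fitted regression line
#'
#' Change in rVPD against change in PaO2 relative to the reference day.
#'
#' @param study a `study_result`.
#' @return A ggplot object.
#' @export
plot_delta_scatter <- function(study) {
  days <- study$config$days
  pao2 <- dplyr::filter(study$cohort, .data$variable == "PaO2")
  pao2 <- dplyr::select(pao2, "subject", "day", pao2 = "value")
  joined <- dplyr::inner_join(study$per_subject_day, pao2, by = c("subject", "day"))
  ref <- dplyr::filter(joined, .data$day == days[1])
  d2 <- dplyr::filter(joined, .data$day == days[2])
  m <- dplyr::inner_join(ref, d2, by = "subject", suffix = c("_0", "_2"))
  m$dpao2 <- m$pao2_2 - m$pao2_0
  m$drvpd <- m$rvpd_pct_2 - m$rvpd_pct_0
  ggplot2::ggplot(m, ggplot2::aes(x = .data$dpao2, y = .data$drvpd)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = expression(Delta * PaO[2] ~ "(mmHg)"),
                  y = expression(Delta * "rVPD (%)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot.rmcorr_fit` draws the per-subject fitted lines of a
#' repeated-measures correlation; `autoplot.study_result` is the rVPD-by-day
#' figure; `autoplot.enface_image`, `autoplot.vessel_mask` and
#' `autoplot.thickness_map` render the 2-D products on the physical grid.
#'
#' @param object the fitted object or image.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rmcorr_fit <- function(object, ...) {
  d <- object$data
  d$fit <- object$intercepts[d$subject] + object$slope * d$x
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, group = .data$subject)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$subject), show.legend = FALSE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit, colour = .data$subject),
                       show.legend = FALSE) +
    ggplot2::labs(subtitle = sprintf("r_rm = %.2f, p = %.3g", object$r_rm, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rmcorr_fit
#' @export
autoplot.study_result <- function(object, ...) plot_outcome_by_day(object, "rvpd")

raster_df <- function(m, spacing_um) {
  tibble::tibble(
    x_mm = rep((seq_len(nrow(m)) - 0.5) * spacing_um[1] / 1000, times = ncol(m)),
    y_mm = rep((seq_len(ncol(m)) - 0.5) * spacing_um[2] / 1000, each = nrow(m)),
    value = as.vector(m))
}

#' @rdname autoplot.rmcorr_fit
#' @export
autoplot.enface_image <- function(object, ...) {
  ggplot2::ggplot(raster_df(object$data, object$spacing_um),
                  ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rmcorr_fit
#' @export
autoplot.vessel_mask <- function(object, ...) {
  sp <- attr(object$data, "spacing_um") %||% c(1, 1)
  ggplot2::ggplot(raster_df(object$data * 1, sp),
                  ggplot2::aes(.data$x_mm, .data$y_mm, fill = factor(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "black", `1` = "white"), guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rmcorr_fit
#' @export
autoplot.thickness_map <- function(object, ...) {
  sp <- attr(object$data, "spacing_um") %||% c(1, 1)
  ggplot2::ggplot(raster_df(object$data, sp),
                  ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "thickness (µm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}
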