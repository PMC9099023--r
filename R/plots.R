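#' Plot an average-day activity profile
#'
#' Raw per-bin means as bars with the smoothed profile overlaid; the dark
#' phase can be shaded by supplying the schedule.
#'
#' @param object An [average_day()] profile.
#' @param schedule Optional [light_schedule()] for dark-phase shading.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.avg_day_profile <- function(object, schedule = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$zt))
  if (!is.null(schedule) && !is.na(schedule$photoperiod_h)) {
    p <- p + ggplot2::annotate("rect", xmin = schedule$photoperiod_h, xmax = 24,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p +
    ggplot2::geom_col(ggplot2::aes(y = .data$raw_mean), width = 24 / nrow(object),
                      fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.8) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 24)) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Activity (counts/bin)",
                  title = attr(object, "animal_id"))
}

#' Plot a Lomb-Scargle periodogram
#'
#' @param object A [lomb_scargle()] result.
#' @param alpha Significance level for the threshold line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.periodogram <- function(object, alpha = 0.05, ...) {
  thr <- significance_threshold(object, alpha)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$period_h, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "Period (h)", y = "Normalized power",
                  title = attr(object, "animal_id"))
}

#' Plot a photoperiodic response curve (optionally with its fit)
#'
#' @param object A [response_curve()] tibble.
#' @param fit Optional [fit_cdl()] object; adds the fitted logistic and a
#'   vertical line at the CDL.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppr_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$photoperiod_light_h,
                                    y = .data$proportion)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$proportion - .data$sem,
                                          ymax = .data$proportion + .data$sem)) +
    ggplot2::labs(x = "Photoperiod (h light)", y = "Diapause incidence")
  if (!is.null(fit) && !fit$degenerate) {
    Lgrid <- seq(min(object$photoperiod_light_h),
                 max(object$photoperiod_light_h), length.out = 200)
    par <- unlist(fit$params)
    fitted_df <- tibble::tibble(photoperiod_light_h = Lgrid,
                                proportion = ppr_logistic(Lgrid, par))
    p <- p + ggplot2::geom_line(data = fitted_df) +
      ggplot2::geom_vline(xintercept = fit$cdl_h, linetype = "dashed")
  }
  p
}

#' Double-plot style actogram of an activity series
#'
#' @param object An [activity_series()].
#' @param ... Unused.
#' @return A ggplot (one facet row per day).
#' @export
autoplot.activity_series <- function(object, ...) {
  m <- series_meta(object)
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(day = floor(.data$time_h / 24) + 1L,
                  hour = .data$time_h %% 24)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hour, y = .data$counts)) +
    ggplot2::geom_col(width = m$bin_minutes / 60) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$day)) +
    ggplot2::labs(x = "Time of day (h)", y = "Counts",
                  title = m$animal_id) +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}
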