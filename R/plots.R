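# Report figures.

#' Plot an hourly activity profile
#'
#' @param profile Output of [hourly_profile()] (or several row-bound with a
#'   `group` column).
#' @return A ggplot object: percent active per ZT-hour bin.
#' @export
plot_hourly_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$zt_hour, y = .data$percent_active)) +
    ggplot2::geom_step() +
    ggplot2::annotate("rect", xmin = 12, xmax = 24, ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Active periods (%)") +
    ggplot2::theme_classic()
}

#' Plot the activity-temperature regression with 95% bands
#'
#' @param fit An [fit_activity_temperature()] result.
#' @param points The points the fit was computed from (plus any flagged
#'   outliers to overlay); needs `mean_active_pct`, `mean_temp_c`.
#' @return A ggplot object.
#' @export
plot_activity_temperature <- function(fit, points) {
  xs <- seq(min(points$mean_active_pct), max(points$mean_active_pct),
            length.out = 80)
  bd <- fit$band(xs)
  ggplot2::ggplot(bd, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pi_lo, ymax = .data$pi_hi),
                         alpha = 0.10) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.20) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point(data = points,
                        ggplot2::aes(x = .data$mean_active_pct,
                                     y = .data$mean_temp_c)) +
    ggplot2::labs(x = "Active periods (%)", y = "Core body temperature (°C)") +
    ggplot2::theme_classic()
}

#' Cumulative zone-time distributions per group
#'
#' @param outcomes Outcome table from [compute_mouse_outcomes()].
#' @param zone `"interaction"` or `"avoidance"`.
#' @return A ggplot object of per-group ECDFs.
#' @export
plot_zone_ecdf <- function(outcomes, zone = c("interaction", "avoidance")) {
  zone <- match.arg(zone)
  col <- paste0("test_pct_", zone)
  ggplot2::ggplot(outcomes,
                  ggplot2::aes(x = .data[[col]], colour = .data$group)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = sprintf("Time in %s zone (%% of session)", zone),
                  y = "Cumulative frequency") +
    ggplot2::theme_classic()
}
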