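# Thermometry: core body-temperature series, window means, the
# activity-temperature regression with 95% confidence/prediction bands, and
# the severe-hypothermia outlier rule.

#' Construct a body-temperature series
#'
#' Core body temperature sampled every minute by the abdominal sensor.
#' Samples outside a physiological plausibility range are flagged, never
#' dropped: genuine severe hypothermia (down to ~31 degC in a stressed mouse)
#' must survive screening.
#'
#' @param temps_c Temperatures in degrees Celsius.
#' @param start_zt ZT (hours) of the first sample.
#' @param sample_interval_s Sampling interval in seconds (default 60).
#' @param plausible_range Two-element range in degC; values outside it are
#'   flagged in `$plausible` (default `c(25, 45)`).
#' @return An object of class `temperature_series`.
#' @export
temperature_series <- function(temps_c, start_zt = 0, sample_interval_s = 60,
                               plausible_range = c(25, 45)) {
  abort_if(length(temps_c) < 1L, "`temps_c` must be non-empty")
  abort_if(any(!is.finite(temps_c)), "temperatures must be finite")
  structure(
    list(temps_c = as.numeric(temps_c), start_zt = wrap_zt(start_zt),
         sample_interval_s = sample_interval_s,
         plausible = temps_c >= plausible_range[1] &
           temps_c <= plausible_range[2]),
    class = "temperature_series"
  )
}

# ZT of each temperature sample.
temp_zt <- function(series) {
  wrap_zt(series$start_zt +
            (seq_along(series$temps_c) - 1L) * series$sample_interval_s / 3600)
}

#' Mean body temperature over a ZT window
#'
#' @param series A [temperature_series()].
#' @param zt_from,zt_to Window in ZT hours, samples with ZT in
#'   `[zt_from, zt_to)`; may cross ZT 24.
#' @return Mean temperature in degC.
#' @export
window_mean_temp <- function(series, zt_from, zt_to) {
  abort_if(!inherits(series, "temperature_series"),
           "`series` must be a temperature_series")
  sel <- zt_in_window(temp_zt(series), zt_from, zt_to)
  abort_if(!any(sel), "no temperature samples in the requested ZT window")
  mean(series$temps_c[sel])
}

#' Regress body temperature on activity with 95% bands
#'
#' Ordinary least-squares fit of per-mouse mean body temperature on per-mouse
#' mean percent active over the same ZT window, with the Pearson correlation
#' and its two-sided p-value (t distribution, n - 2 df), plus point-wise 95%
#' confidence band (mean response) and 95% prediction band (single new
#' observation).
#'
#' @param points Data frame with columns `mean_active_pct` and `mean_temp_c`
#'   (one row per mouse); extra columns such as `mouse_id`, `group` are
#'   carried along.
#' @param level Band coverage (default 0.95).
#' @return An object of class `acti_temp_fit` with elements `slope`,
#'   `intercept`, `r`, `p_r`, `residual_se`, `n`, the fitted `lm` model, and
#'   a `band(x)` function returning `fit`, `ci_lo`, `ci_hi`, `pi_lo`, `pi_hi`
#'   at new x.
#' @export
fit_activity_temperature <- function(points, level = 0.95) {
  abort_if(nrow(points) < 3L, "need at least 3 points")
  x <- points$mean_active_pct
  y <- points$mean_temp_c
  abort_if(stats::sd(x) == 0, "degenerate x: all mean_active_pct equal")
  fit <- stats::lm(mean_temp_c ~ mean_active_pct, data = points)
  ct <- stats::cor.test(x, y, method = "pearson")
  band <- function(xnew) {
    nd <- data.frame(mean_active_pct = xnew)
    ci <- stats::predict(fit, nd, interval = "confidence", level = level)
    pi <- stats::predict(fit, nd, interval = "prediction", level = level)
    tibble::tibble(x = xnew, fit = ci[, "fit"],
                   ci_lo = ci[, "lwr"], ci_hi = ci[, "upr"],
                   pi_lo = pi[, "lwr"], pi_hi = pi[, "upr"])
  }
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r = unname(ct$estimate), p_r = ct$p.value,
         residual_se = summary(fit)$sigma, n = nrow(points),
         level = level, model = fit, band = band),
    class = "acti_temp_fit"
  )
}

#' @export
print.acti_temp_fit <- function(x, ...) {
  cat(sprintf(
    "Activity-temperature fit (n = %d)\n  Tb = %.4f + %.5f * active%%\n  Pearson r = %.4f, p = %.4g, residual SE = %.4f\n",
    x$n, x$intercept, x$slope, x$r, x$p_r, x$residual_se))
  invisible(x)
}

#' Flag a severe-hypothermia outlier
#'
#' Leave-one-out screen for a mouse whose body temperature cannot be
#' explained by its reduced activity: the regression is refit on all other
#' mice, and the candidate is flagged when its mean temperature lies strictly
#' below the lower 95% prediction band evaluated at its mean percent active.
#' The prediction band (not the narrower confidence band) is the correct
#' reference for a single animal's observation.
#'
#' @param points Data frame as for [fit_activity_temperature()], with a
#'   `mouse_id` column.
#' @param candidate `mouse_id` of the mouse to screen.
#' @param level Band coverage (default 0.95).
#' @return A list: `flagged` (logical), `candidate`, `observed_temp_c`,
#'   `predicted_temp_c`, `pi_lo`, `pi_hi`, `margin_c` (observed minus lower
#'   band; negative when flagged) and the leave-one-out `fit`.
#' @export
flag_hypothermia_outlier <- function(points, candidate, level = 0.95) {
  abort_if(!candidate %in% points$mouse_id, "candidate not among the points")
  rest <- points[points$mouse_id != candidate, , drop = FALSE]
  abort_if(nrow(rest) < 4L, "need at least 4 non-candidate points to refit")
  fit <- fit_activity_temperature(rest, level = level)
  cand <- points[points$mouse_id == candidate, , drop = FALSE][1L, ]
  bd <- fit$band(cand$mean_active_pct)
  list(flagged = cand$mean_temp_c < bd$pi_lo,  # strictly below
       candidate = candidate,
       observed_temp_c = cand$mean_temp_c,
       predicted_temp_c = bd$fit,
       pi_lo = bd$pi_lo, pi_hi = bd$pi_hi,
       margin_c = cand$mean_temp_c - bd$pi_lo,
       fit = fit)
}
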