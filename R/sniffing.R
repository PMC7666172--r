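# Sniffing: nose-to-mesh distances, the 2 cm / >= 500 ms bout rule, bout
# summaries and validation of automatic totals against manual annotation.

#' Per-frame nose-to-mesh distance
#'
#' Euclidean distance (cm) from the nose point to the nearest point of the
#' meshwork front-face segment. Frames whose nose likelihood falls below the
#' gate carry `NA` (undefined), which break bout runs downstream unless
#' bridged explicitly.
#'
#' @param session A [tracked_session()].
#' @param mesh A [mesh_segment()].
#' @param min_likelihood Pose-likelihood gate (default 0.9).
#' @return Numeric vector of distances (cm), `NA` where undefined.
#' @export
nose_mesh_distance <- function(session, mesh, min_likelihood = 0.9) {
  abort_if(!inherits(session, "tracked_session"),
           "`session` must be a tracked_session")
  fr <- session$frames
  d <- point_segment_distance(fr$x_n, fr$y_n, mesh[1, ], mesh[2, ])
  d[fr$lik_n < min_likelihood] <- NA_real_
  d
}

# Vectorized point-to-segment distance.
point_segment_distance <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- ((px - a[1]) * abx + (py - a[2]) * aby) / len2
  t <- pmin(pmax(t, 0), 1)
  unname(sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2))
}

#' Detect sniffing bouts
#'
#' A sniffing bout is a maximal run of frames whose nose-to-mesh distance is
#' at most `max_dist_cm`, lasting `min_dur_s` or more ("or more" is
#' inclusive: the frame-count threshold is `ceiling(min_dur_s * fps)`).
#' Undefined (`NA`) or out-of-range frames break runs; gaps of at most
#' `max_gap_frames` frames may be bridged (default 0: the rule is a
#' continuous stay).
#'
#' @param distances Per-frame distances (cm), `NA` = undefined.
#' @param fps Frames per second (required; the video frame rate is an input,
#'   never assumed).
#' @param max_dist_cm Proximity threshold in cm (default 2).
#' @param min_dur_s Minimum bout duration in seconds (default 0.5).
#' @param max_gap_frames Longest out-of-range/undefined gap (frames) bridged
#'   inside a bout (default 0).
#' @return Tibble of bouts: `start_s`, `end_s`, `duration_s`, sorted and
#'   non-overlapping. Times are frame-grid times: a bout spanning frames
#'   `[i, j]` starts at `(i - 1) / fps` and lasts `(j - i + 1) / fps`.
#' @export
detect_sniff_bouts <- function(distances, fps, max_dist_cm = 2.0,
                               min_dur_s = 0.5, max_gap_frames = 0L) {
  abort_if(length(distances) < 1L, "empty distance track")
  abort_if(!is_scalar_num(fps) || fps <= 0, "`fps` must be positive")
  inr <- !is.na(distances) & distances <= max_dist_cm
  if (max_gap_frames > 0L) {
    r <- rle(inr)
    gap <- !r$values & r$lengths <= max_gap_frames
    # only bridge gaps strictly between two in-range runs
    interior <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
    r$values[gap & interior] <- TRUE
    inr <- inverse.rle(r)
  }
  r <- rle(inr)
  min_frames <- as.integer(ceiling(min_dur_s * fps))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  tibble::tibble(
    start_s = (starts[keep] - 1L) / fps,
    end_s = ends[keep] / fps,
    duration_s = r$lengths[keep] / fps
  )
}

#' Summarize sniffing bouts
#'
#' @param bouts Tibble from [detect_sniff_bouts()].
#' @return One-row tibble: `total_time_s`, `n_bouts`, `mean_bout_duration_s`
#'   (the sniffing-intensity measure; `NA` when there are no bouts).
#' @export
summarize_sniffing <- function(bouts) {
  tibble::tibble(
    total_time_s = sum(bouts$duration_s),
    n_bouts = nrow(bouts),
    mean_bout_duration_s = if (nrow(bouts) >= 1L) mean(bouts$duration_s)
                           else NA_real_
  )
}

#' Validate automatic sniffing totals against manual annotation
#'
#' Pearson correlation and OLS line of automatically detected total sniffing
#' time against manually scored totals across paired sessions.
#'
#' @param auto_total_s,manual_total_s Paired per-mouse totals (seconds).
#' @return A list: `r`, `p`, `slope`, `intercept`, `n`, and the `lm` fit.
#' @export
validate_against_manual <- function(auto_total_s, manual_total_s) {
  abort_if(length(auto_total_s) != length(manual_total_s),
           "paired totals must have equal length")
  abort_if(length(auto_total_s) < 3L, "need >= 3 paired sessions")
  ct <- stats::cor.test(manual_total_s, auto_total_s, method = "pearson")
  fit <- stats::lm(auto_total_s ~ manual_total_s)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(auto_total_s), model = fit)
}
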