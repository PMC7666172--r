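# Actigraphy: epoch-count activity series, sleep-like inactivity scoring and
# hourly activity profiles on Zeitgeber time.
#
# The implanted abdominal sensor records 3-axis acceleration at 25 Hz and
# reports, every 12 s, how often the synthesized acceleration waveform crossed
# a movement threshold. Sleep-like inactivity is defined behaviorally: an
# epoch is inactive when it sits inside a run of >= 2 consecutive zero-count
# epochs (>= 24 s without voluntary movement); all other epochs are active.

EPOCHS_PER_HOUR <- 300L  # 3600 s / 12 s

#' Construct an acceleration trace
#'
#' A raw 3-axis acceleration recording in units of g, sampled at a fixed rate
#' (25 Hz for the wireless abdominal sensor).
#'
#' @param samples Numeric matrix with one row per sample and three columns
#'   (x, y, z acceleration in g).
#' @param sample_rate_hz Sampling rate in Hz (default 25).
#' @param start_zt Zeitgeber time of the first sample, hours in `[0, 24)`.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(samples, sample_rate_hz = 25, start_zt = 0) {
  samples <- as.matrix(samples)
  abort_if(ncol(samples) != 3L, "`samples` must have three columns (x, y, z)")
  abort_if(nrow(samples) < 1L, "`samples` must contain at least one sample")
  abort_if(!all(is.finite(samples)), "acceleration samples must be finite")
  abort_if(!is_scalar_num(sample_rate_hz) || sample_rate_hz <= 0,
           "`sample_rate_hz` must be a positive number")
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         start_zt = wrap_zt(start_zt)),
    class = "accel_trace"
  )
}

#' Construct an epoch activity series
#'
#' Movement counts on fixed 12-s epochs; 300 epochs are exactly one hour.
#'
#' @param counts Non-negative integer movement counts, one per epoch.
#' @param start_zt Zeitgeber time (hours) of the start of the first epoch.
#' @param valid Optional logical vector flagging epochs actually recorded;
#'   defaults to all `TRUE`. Missing epochs stay in place (uniform spacing)
#'   but are excluded from hourly percentages.
#' @param epoch_length_s Epoch length in seconds (fixed at 12 for the sensor).
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(counts, start_zt = 0, valid = NULL,
                         epoch_length_s = 12) {
  abort_if(length(counts) < 1L, "`counts` must be non-empty")
  abort_if(any(!is.finite(counts)) || any(counts < 0),
           "`counts` must be finite and non-negative")
  valid <- valid %||% rep(TRUE, length(counts))
  abort_if(length(valid) != length(counts),
           "`valid` must align with `counts`")
  structure(
    list(counts = as.integer(round(counts)), start_zt = wrap_zt(start_zt),
         valid = as.logical(valid), epoch_length_s = epoch_length_s),
    class = "epoch_series"
  )
}

#' @export
length.epoch_series <- function(x) length(x$counts)

# ZT (hours) of the start of each epoch.
epoch_zt <- function(series) {
  wrap_zt(series$start_zt +
            (seq_along(series$counts) - 1L) * series$epoch_length_s / 3600)
}

#' Count movement threshold crossings per epoch
#'
#' Reduces a raw acceleration trace to per-epoch movement counts the way the
#' on-board counter does: the synthesized movement waveform is the magnitude
#' of the sample-to-sample change of the acceleration-vector norm, and each
#' upward crossing of the threshold (from <= threshold to > threshold) within
#' an epoch increments that epoch's count. A trailing partial epoch is
#' dropped. The vendor's exact on-board waveform is undocumented, so this
#' path is an approximation; epoch-count input is the canonical substrate.
#'
#' @param trace An [accel_trace()].
#' @param threshold Crossing threshold in g (default 0.05).
#' @param epoch_length_s Epoch length in seconds (default 12).
#' @return An [epoch_series()].
#' @export
count_threshold_crossings <- function(trace, threshold = 0.05,
                                      epoch_length_s = 12) {
  abort_if(!inherits(trace, "accel_trace"), "`trace` must be an accel_trace")
  abort_if(!is_scalar_num(threshold) || threshold <= 0,
           "`threshold` must be positive")
  per_epoch <- as.integer(round(epoch_length_s * trace$sample_rate_hz))
  n <- nrow(trace$samples)
  abort_if(n < per_epoch, "trace shorter than one epoch")
  norm <- sqrt(rowSums(trace$samples^2))
  wave <- c(0, abs(diff(norm)))          # movement waveform, length n
  above <- wave > threshold
  crossing <- above & !c(FALSE, above[-n])  # upward crossings
  n_epochs <- n %/% per_epoch
  idx <- rep(seq_len(n_epochs), each = per_epoch)
  counts <- as.integer(tapply(crossing[seq_len(n_epochs * per_epoch)], idx, sum))
  epoch_series(counts, start_zt = trace$start_zt,
               epoch_length_s = epoch_length_s)
}

#' Score sleep-like inactivity
#'
#' Flags epoch i as inactive iff its count is zero and it belongs to a run of
#' at least two consecutive zero-count epochs (counts absent in two
#' consecutive 12-s measurements, i.e. >= 24 s without movement). Isolated
#' single zero epochs remain active; epochs at the recording edges treat the
#' missing neighbor as nonzero (a run cannot be started on unknown context).
#'
#' @param series An [epoch_series()].
#' @return Logical vector aligned to the series (`TRUE` = inactive), class
#'   `inactivity_mask`.
#' @export
inactivity_mask <- function(series) {
  abort_if(!inherits(series, "epoch_series"), "`series` must be an epoch_series")
  z <- series$counts == 0L
  n <- length(z)
  prev <- c(FALSE, z[-n])  # out-of-range neighbors treated as nonzero
  nxt  <- c(z[-1L], FALSE)
  flags <- z & (prev | nxt)
  structure(flags, class = "inactivity_mask")
}

#' Hourly activity profile
#'
#' Bins the scored series into ZT-hour bins and reports the percentage of
#' present (valid) epochs that are active. Bins with less than 90% of the 300
#' expected epochs present are emitted with `bin_valid = FALSE` and excluded
#' from downstream window means.
#'
#' @param series An [epoch_series()].
#' @param mask An [inactivity_mask()] aligned with `series`; computed if
#'   missing.
#' @param min_coverage Minimum fraction of the 300 epochs that must be
#'   present for a bin to count as valid (default 0.9).
#' @return A tibble with one row per hour bin: `zt_hour` (bin start),
#'   `percent_active`, `percent_inactive`, `n_epochs_present`, `bin_valid`.
#' @export
hourly_profile <- function(series, mask = NULL, min_coverage = 0.9) {
  abort_if(!inherits(series, "epoch_series"), "`series` must be an epoch_series")
  mask <- mask %||% inactivity_mask(series)
  abort_if(length(mask) != length(series$counts),
           "`mask` is not aligned with `series`")
  zt <- epoch_zt(series)
  # absolute hour index from series start so multi-day series keep bins apart
  abs_hour <- floor((series$start_zt * 3600 +
                       (seq_along(series$counts) - 1L) * series$epoch_length_s) / 3600)
  df <- tibble::tibble(abs_hour = abs_hour, zt_hour = wrap_zt(abs_hour),
                       inactive = as.logical(mask), valid = series$valid)
  out <- df |>
    dplyr::group_by(.data$abs_hour, .data$zt_hour) |>
    dplyr::summarise(
      n_epochs_present = sum(.data$valid),
      percent_active = 100 * sum(!.data$inactive & .data$valid) /
        max(sum(.data$valid), 1L),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      percent_active = ifelse(.data$n_epochs_present == 0L, NA_real_,
                              .data$percent_active),
      percent_inactive = 100 - .data$percent_active,
      bin_valid = .data$n_epochs_present >= min_coverage * EPOCHS_PER_HOUR
    ) |>
    dplyr::arrange(.data$abs_hour) |>
    dplyr::select("zt_hour", "percent_active", "percent_inactive",
                  "n_epochs_present", "bin_valid")
  class(out) <- c("hourly_profile", class(out))
  out
}

#' Epoch-weighted mean percent active over a ZT window
#'
#' Averages `percent_active` over valid bins whose start hour lies in
#' `[zt_from, zt_to)`, weighting each bin by its number of present epochs.
#' Windows crossing ZT 24 (midnight of Zeitgeber time) are supported.
#'
#' @param profile Output of [hourly_profile()].
#' @param zt_from,zt_to Window bounds in ZT hours; a bin contributes when its
#'   start lies in `[zt_from, zt_to)`. The conventional "ZT 13--15" window
#'   (bins starting at ZT 13, 14 and 15) is `zt_from = 13, zt_to = 16`.
#' @return Percent active in `[0, 100]`.
#' @export
window_mean_active <- function(profile, zt_from, zt_to) {
  sel <- zt_in_window(profile$zt_hour, zt_from, zt_to) & profile$bin_valid
  abort_if(!any(sel), "no valid bins in the requested ZT window")
  w <- profile$n_epochs_present[sel]
  sum(profile$percent_active[sel] * w) / sum(w)
}
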