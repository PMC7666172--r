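# Synthetic actigraphy and body temperature.
#
# Activity is a two-state (active/inactive) semi-Markov chain on the 12-s
# epoch grid. Inactive dwells are 2 + geometric epochs: sleep-like inactivity
# episodes last at least two epochs by construction, so the planted inactive
# fraction equals the run-based scored fraction (sub-epoch pauses are folded
# into active-state count variation). Active dwells are 1 + geometric with
# mean chosen so the stationary active fraction matches the phase target.
# Active epochs emit 1 + Poisson(lambda) movement counts; inactive epochs
# emit zero. Body temperature follows the planted linear coupling to the
# 30-min rolling active fraction plus a per-mouse offset and AR(1) noise;
# the optional severe-hypothermia trajectory superimposes a smooth trough
# reaching the configured temperature.

# Phase target active fraction at each epoch's ZT for a group.
phase_targets <- function(zt, group, act) {
  f <- ifelse(zt < 12, act$light_active, act$dark_active)
  if (group == "stress") {
    w <- zt >= act$stress_effect_zt[1] & zt < act$stress_effect_zt[2]
    f[w] <- act$stress_window_active
  } else if (group == "sleepdep") {
    w <- zt >= act$sleepdep_zt[1] & zt < act$sleepdep_zt[2]
    f[w] <- act$sleepdep_active
  }
  f
}

# Simulate the semi-Markov state sequence (TRUE = active) for per-epoch
# target fractions f (already including the mouse offset, clamped).
sim_state_sequence <- function(f, m_inactive) {
  n <- length(f)
  state <- logical(n)
  t <- 1L
  cur <- stats::runif(1) < f[1L]
  while (t <= n) {
    ft <- f[t]
    if (ft >= 0.98) { dwell <- if (cur) n else 1L }
    else if (ft <= 0.02) { dwell <- if (cur) 1L else n }
    else if (cur) {
      m_active <- max(1.01, m_inactive * ft / (1 - ft))
      dwell <- 1L + stats::rgeom(1L, 1 / m_active)
    } else {
      dwell <- 2L + stats::rgeom(1L, 1 / (m_inactive - 1))
    }
    end <- min(n, t + dwell - 1L)
    state[t:end] <- cur
    t <- end + 1L
    cur <- !cur
  }
  # fully degenerate targets override dwell mechanics
  state[f[seq_len(n)] >= 0.98] <- TRUE
  state[f[seq_len(n)] <= 0.02] <- FALSE
  state
}

#' Generate one mouse's actigraphy and body temperature
#'
#' @param cfg A [cohort_config()].
#' @param group `"control"`, `"stress"` or `"sleepdep"`.
#' @param mouse_offset Per-mouse deviation of the active fraction (added to
#'   every phase target, clamped to `[0.02, 0.98]`); drawn by
#'   [simulate_cohort()] from `N(0, between_sd)`.
#' @param outlier Plant the severe-hypothermia temperature trajectory
#'   (stress only); the activity profile is unaffected — severe hypothermia
#'   is not explained by reduced voluntary movement.
#' @return List: `epochs` ([epoch_series()]), `temperature`
#'   ([temperature_series()]), and `truth` (planted window active fraction
#'   target, temperature offset, outlier flag).
#' @export
gen_actigraphy <- function(cfg, group, mouse_offset = 0, outlier = FALSE) {
  act <- cfg$actigraphy
  tp <- cfg$temperature
  n <- act$n_epochs
  zt <- (seq_len(n) - 1L) * act$epoch_length_s / 3600
  f <- pmin(0.98, pmax(0.02, phase_targets(zt, group, act) + mouse_offset))
  state <- sim_state_sequence(f, act$inactive_dwell_mean_ep)
  counts <- integer(n)
  counts[state] <- 1L + stats::rpois(sum(state), act$lambda_active)
  epochs <- epoch_series(counts, start_zt = 0,
                         epoch_length_s = act$epoch_length_s)

  # per-minute temperature driven by the rolling active fraction
  ep_per_min <- as.integer(round(60 / act$epoch_length_s))
  n_min <- n %/% ep_per_min
  minute_active <- colMeans(matrix(state[seq_len(n_min * ep_per_min)],
                                   nrow = ep_per_min))
  k <- tp$roll_minutes
  cs <- cumsum(minute_active)
  froll <- (cs - c(rep(0, k), utils::head(cs, -k))) / pmin(seq_len(n_min), k)
  offset <- stats::rnorm(1L, 0, tp$mouse_offset_sd)
  ar <- stats::filter(stats::rnorm(n_min, 0,
                                   tp$ar_sigma * sqrt(1 - tp$ar_rho^2)),
                      tp$ar_rho, method = "recursive",
                      init = stats::rnorm(1L, 0, tp$ar_sigma))
  temps <- tp$beta0 + tp$beta1 * froll + offset + as.numeric(ar)
  if (outlier && cfg$outlier$enabled) {
    zt_min <- (seq_len(n_min) - 0.5) / 60
    o <- cfg$outlier
    s <- numeric(n_min)
    ramp_dn <- zt_min >= o$onset_zt & zt_min < o$trough_zt
    ramp_up <- zt_min >= o$trough_zt & zt_min < o$recovery_zt
    s[ramp_dn] <- (1 - cos(pi * (zt_min[ramp_dn] - o$onset_zt) /
                             (o$trough_zt - o$onset_zt))) / 2
    s[ramp_up] <- (1 + cos(pi * (zt_min[ramp_up] - o$trough_zt) /
                             (o$recovery_zt - o$trough_zt))) / 2
    # pull toward the trough temperature relative to the local baseline so
    # the planted minimum equals trough_c regardless of the activity profile
    base <- tp$beta0 + tp$beta1 * froll + offset
    temps <- temps + (o$trough_c - base) * s
  }
  temperature <- temperature_series(temps, start_zt = 0,
                                    sample_interval_s = tp$sample_interval_s)
  list(epochs = epochs, temperature = temperature,
       truth = list(window_active_target = mean(f[zt >= 13 & zt < 16]),
                    temp_offset = offset, outlier = outlier))
}
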