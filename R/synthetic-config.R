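# Cohort configuration: the study conditions the generator emulates.
#
# Defaults are calibrated to the published group statistics: group sizes
# 6 (control) / 13 (stress) / 9 (stress + sleep deprivation); ZT 13-15 active
# fractions 0.694 (control) and 0.401 (stress) with between-mouse SD 0.12
# (back-computed from the reported SEMs, 5.03 * sqrt(6) and 3.36 * sqrt(13));
# temperature coupling slope (37.47 - 36.79) / (0.694 - 0.401) ~= 2.32 degC
# per unit active fraction; one severe-hypothermia outlier with a 31.1 degC
# trough at ZT 17 recovering within the day; sniffing bout-count means 15.33
# (control) and a susceptible/resilient mixture averaging ~8.4 (stress);
# intensity-interaction coupling targeting Pearson r ~= 0.74 in
# high-social-interest mice and ~= 0.77 in the sleep-deprived group.

#' Synthetic cohort configuration
#'
#' Returns the full parameter set of the synthetic-cohort generator with
#' defaults calibrated to the published study conditions. Any element can be
#' overridden via `...` (named top-level entries are replaced wholesale;
#' nested lists may be passed partially and are merged shallowly).
#'
#' @param ... Named overrides of top-level entries.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  slope <- (37.47 - 36.79) / (0.694 - 0.401)
  cfg <- list(
    groups = c(control = 6L, stress = 13L, sleepdep = 9L),
    susceptible_n_stress = 6L,     # 6 of 13 susceptible (46.2%)
    social_n_sleepdep = 2L,        # 2 of 9 retain high social interest
    actigraphy = list(
      epoch_length_s = 12, n_epochs = 7200L,   # one full day, ZT 0-24
      light_active = 0.30, dark_active = 0.694,
      stress_window_active = 0.401,
      sleepdep_active = 0.92,
      stress_effect_zt = c(12.2, 16.5),  # homogeneous across ZT 13-16
      sleepdep_zt = c(12, 18),
      # between_sd is the target SD of *observed* per-mouse window active
      # fractions (back-computed from the reported group SEMs); the window
      # mean of a single mouse carries ~0.04 realization noise from the
      # dwell structure, so latent offsets are drawn with the difference.
      between_sd = 0.12, realization_sd = 0.04,
      inactive_dwell_mean_ep = 5,  # epochs; minimum run length 2
      lambda_active = 3            # active counts = 1 + Poisson(lambda)
    ),
    temperature = list(
      sample_interval_s = 60,
      beta1 = slope, beta0 = 37.47 - slope * 0.694,
      mouse_offset_sd = 0.12, ar_sigma = 0.08, ar_rho = 0.9,
      roll_minutes = 30
    ),
    outlier = list(
      enabled = TRUE, trough_c = 31.1, trough_zt = 17,
      onset_zt = 12.2, recovery_zt = 23.5
    ),
    social = list(
      fps = 30, duration_s = 150,
      likelihood_low_rate = 0.01,  # fraction of frames with dropped pose
      # planted zone-time targets, percent of session (test with target)
      zone_targets = list(
        control     = list(int = c(40, 8),  avd = c(20, 8)),
        resilient   = list(int = c(52, 1),  avd = c(8, 1)),
        susceptible = list(int = c(8, 2.4), avd = c(52, 2.4))
      ),
      habituation_target = list(int = c(30, 5), avd = c(30, 5)),
      # total distance targets (cm) per group for (habituation, test)
      distance = list(control = c(900, 900), stress = c(900, 700),
                      sleepdep = c(900, 1400)),
      distance_sd = 120,
      nose_offset_cm = 3,
      sniff = list(
        # bout-count Poisson means per phenotype
        n_bouts = c(control = 15.33, resilient = 12, susceptible = 4.2,
                    sleepdep = 8),
        # mean bout duration model: mu = base + coupling * (t_int - ref)
        base_s = c(control = 1.2, resilient = 1.2, susceptible = 1.1,
                   sleepdep = 0.8),
        coupling_s_per_s = c(control = 0.012, resilient = 0.012,
                             susceptible = 0, sleepdep = 0.009),
        ref_interaction_s = c(control = 60, resilient = 60, susceptible = 0,
                              sleepdep = 30),
        noise_sd = c(control = 0.08, resilient = 0.08, susceptible = 0.25,
                     sleepdep = 0.28),
        min_duration_s = 0.55,  # planted bouts are detectable by design
        duration_shape = 8,     # shifted-gamma shape for bout durations
        annotation_jitter_sd_s = 0.05
      )
    ),
    arena = list(width_cm = 30, length_cm = 40),
    imaging = list(
      img_px = 288L, um_per_px = 1.0,
      background = 0.20, gradient = 0.05, noise_sd = 0.02, contrast = 6,
      spot_diameter_um = c(12, 24),   # planted in-range diameters
      regions = c(VLPO = 25, MnPO = 25, MS = 20, LH = 20, LDT = 15,
                  DMH = 20, VLPAG = 15),
      stress_multiplier = c(DMH = 2, VLPAG = 2),  # others unchanged
      n_per_group = 4L, hemispheres = c("left", "right"),
      margin_px = 14L, min_gap_px = 5L
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "cohort_config")
}
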