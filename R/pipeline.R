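# Full-cohort analysis: per-mouse outcome table and the statistical
# comparisons of the study design, assembled into a report bundle.

#' Per-mouse outcome table
#'
#' Runs the actigraphy, thermometry, arena and sniffing stages on every
#' mouse of a cohort and merges the results into one row per mouse.
#'
#' @param cohort A [simulate_cohort()] result (or a list with the same
#'   shape built from files).
#' @param zt_window ZT window for activity/temperature means, default
#'   `c(13, 16)` (the three hourly bins starting at ZT 13, 14, 15).
#' @return Tibble with one row per mouse: window activity and temperature,
#'   zone occupancy for both sessions, sniffing summaries and manual totals.
#' @export
compute_mouse_outcomes <- function(cohort, zt_window = c(13, 16)) {
  arena <- arena_geometry(width_cm = cohort$config$arena$width_cm,
                          length_cm = cohort$config$arena$length_cm)
  mesh <- mesh_segment(arena)
  purrr::map_dfr(seq_len(nrow(cohort$mice)), function(i) {
    id <- cohort$mice$mouse_id[i]
    out <- tibble::tibble(mouse_id = id, group = cohort$mice$group[i])
    a <- cohort$actigraphy[[id]]
    if (!is.null(a)) {
      prof <- hourly_profile(a$epochs)
      out$mean_active_pct <- window_mean_active(prof, zt_window[1], zt_window[2])
      out$mean_temp_c <- window_mean_temp(a$temperature,
                                          zt_window[1], zt_window[2])
      out$min_hourly_temp_c <- min(vapply(0:23, function(h)
        window_mean_temp(a$temperature, h, h + 1), numeric(1)))
    }
    s <- cohort$sessions[[id]]
    if (!is.null(s)) {
      for (kind in c("habituation", "test")) {
        zo <- compute_zone_occupancy(s[[kind]]$session, arena)
        pre <- if (kind == "habituation") "hab_" else "test_"
        out[[paste0(pre, "pct_interaction")]] <- zo$pct_interaction
        out[[paste0(pre, "pct_avoidance")]] <- zo$pct_avoidance
        out[[paste0(pre, "distance_cm")]] <- zo$distance_cm
      }
      d <- nose_mesh_distance(s$test$session, mesh)
      bouts <- detect_sniff_bouts(d, fps = s$test$session$fps)
      sm <- summarize_sniffing(bouts)
      out$sniff_total_s <- sm$total_time_s
      out$sniff_n_bouts <- sm$n_bouts
      out$sniff_mean_duration_s <- sm$mean_bout_duration_s
      ann <- s$test$annotation
      out$manual_total_s <- sum(ann$end_s - ann$start_s)
    }
    out
  })
}

#' Run the full cohort analysis
#'
#' Executes all analysis stages on a cohort and returns the report bundle:
#' the ZT-window group comparison of activity and body temperature (one-way
#' ANOVA with Tukey comparisons; the hypothermia outlier excluded from the
#' temperature comparison once flagged), the activity-temperature regression
#' with the prediction-band outlier screen, zone-time mixed-design ANOVA
#' with Sidak comparisons and KS distribution comparisons against control,
#' susceptible/resilient classification and high-social-interest proportions
#' with Fisher tests, sniffing summaries (ANOVA with Tukey, automatic vs
#' manual validation) and the intensity-interaction correlation and ANCOVA
#' split by social-interest set.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param zt_window ZT window, default `c(13, 16)`.
#' @param fos Optional [gen_fos_cohort()]-shaped imaging dataset; when
#'   supplied, spots are counted, hemispheres averaged and groups compared
#'   per region.
#' @return List of class `report_bundle`; see elements in the vignette.
#' @export
run_full_analysis <- function(cohort, zt_window = c(13, 16), fos = NULL) {
  outcomes <- compute_mouse_outcomes(cohort, zt_window)
  bundle <- list(seed = cohort$seed, zt_window = zt_window)

  has_acti <- "mean_active_pct" %in% names(outcomes)
  if (has_acti) {
    # hypothermia outlier screen on control + stress mice: flag the mouse
    # with the largest negative temperature residual, leave-one-out
    pts <- outcomes |>
      dplyr::filter(.data$group %in% c("control", "stress")) |>
      dplyr::select("mouse_id", "group", "mean_active_pct", "mean_temp_c")
    resid <- stats::resid(stats::lm(mean_temp_c ~ mean_active_pct, data = pts))
    cand <- pts$mouse_id[which.min(resid)]
    flag <- flag_hypothermia_outlier(pts, cand)
    outcomes$hypothermia_flag <- outcomes$mouse_id == cand & flag$flagged
    bundle$hypothermia <- flag

    bundle$activity_anova <- oneway_anova_tukey(outcomes$mean_active_pct,
                                                outcomes$group)
    keep <- !outcomes$hypothermia_flag
    bundle$temperature_anova <- oneway_anova_tukey(
      outcomes$mean_temp_c[keep], outcomes$group[keep])
    bundle$activity_temperature_fit <- fit_activity_temperature(
      pts[!(pts$mouse_id %in% outcomes$mouse_id[outcomes$hypothermia_flag]), ])
    bundle$activity_temperature_ancova <- ancova_compare(
      pts |>
        dplyr::filter(!.data$mouse_id %in%
                        outcomes$mouse_id[outcomes$hypothermia_flag]) |>
        dplyr::transmute(x = .data$mean_active_pct, y = .data$mean_temp_c,
                         group = .data$group))
  }

  has_social <- "test_pct_interaction" %in% names(outcomes)
  if (has_social) {
    # susceptibility classification from the test session
    ctrl <- outcomes |>
      dplyr::filter(.data$group == "control") |>
      dplyr::transmute(.data$mouse_id,
                       pct_interaction = .data$test_pct_interaction,
                       pct_avoidance = .data$test_pct_avoidance)
    strs <- outcomes |>
      dplyr::filter(.data$group == "stress") |>
      dplyr::transmute(.data$mouse_id,
                       pct_interaction = .data$test_pct_interaction,
                       pct_avoidance = .data$test_pct_avoidance)
    cls <- classify_susceptibility(strs, ctrl)
    outcomes <- outcomes |>
      dplyr::left_join(cls[, c("mouse_id", "label")], by = "mouse_id") |>
      dplyr::mutate(label = dplyr::coalesce(
        .data$label, ifelse(.data$group == "control", "control", NA)))
    bundle$classification <- cls
    bundle$susceptible_fraction <-
      mean(cls$label == "susceptible")

    hs <- high_social_interest_set(
      outcomes |>
        dplyr::transmute(.data$mouse_id, .data$group,
                         pct_interaction = .data$test_pct_interaction,
                         pct_avoidance = .data$test_pct_avoidance))
    bundle$high_interest <- hs
    outcomes <- outcomes |>
      dplyr::left_join(hs$occupancy[, c("mouse_id", "high_interest")],
                       by = "mouse_id")
    pr <- hs$proportions
    tab_of <- function(g) {
      r <- pr[pr$group == g, ]
      c(r$n_high_interest, r$n - r$n_high_interest)
    }
    bundle$fisher_stress <- fisher_exact_two_sided(
      rbind(tab_of("control"), tab_of("stress")))
    bundle$fisher_sleepdep <- fisher_exact_two_sided(
      rbind(tab_of("control"), tab_of("sleepdep")))

    # zone-time mixed-design ANOVA (habituation vs test) with Sidak
    long <- outcomes |>
      dplyr::select("mouse_id", "group", "hab_pct_interaction",
                    "test_pct_interaction", "hab_pct_avoidance",
                    "test_pct_avoidance") |>
      tidyr::pivot_longer(-c("mouse_id", "group"),
                          names_to = c("level", "zone"),
                          names_pattern = "(hab|test)_pct_(.*)",
                          values_to = "value")
    bundle$rm_anova <- purrr::map(
      stats::setNames(c("interaction", "avoidance"),
                      c("interaction", "avoidance")),
      function(z) twoway_rm_anova_sidak(
        long |>
          dplyr::filter(.data$zone == z) |>
          dplyr::transmute(subject = .data$mouse_id, .data$group,
                           .data$level, .data$value)))
    bundle$ks_vs_control <- purrr::map(
      stats::setNames(c("stress", "sleepdep"), c("stress", "sleepdep")),
      function(g) list(
        interaction = ks_two_sample(
          outcomes$test_pct_interaction[outcomes$group == "control"],
          outcomes$test_pct_interaction[outcomes$group == g]),
        avoidance = ks_two_sample(
          outcomes$test_pct_avoidance[outcomes$group == "control"],
          outcomes$test_pct_avoidance[outcomes$group == g])))

    # sniffing: group comparisons and valence analysis
    bundle$sniff_count_t <- unpaired_t(
      outcomes$sniff_n_bouts[outcomes$group == "control"],
      outcomes$sniff_n_bouts[outcomes$group == "stress"])
    has_bouts <- !is.na(outcomes$sniff_mean_duration_s)
    bundle$sniff_intensity_anova <- oneway_anova_tukey(
      outcomes$sniff_mean_duration_s[has_bouts], outcomes$group[has_bouts])
    bundle$manual_validation <- purrr::map(
      stats::setNames(unique(outcomes$group), unique(outcomes$group)),
      function(g) {
        d <- outcomes[outcomes$group == g, ]
        validate_against_manual(d$sniff_total_s, d$manual_total_s)
      })

    hi <- outcomes |>
      dplyr::filter(.data$group %in% c("control", "stress"),
                    .data$high_interest, .data$sniff_n_bouts > 0)
    su <- outcomes |>
      dplyr::filter(.data$label == "susceptible" & !is.na(.data$label),
                    .data$sniff_n_bouts > 0)
    bundle$valence_high_interest <- pearson_test(hi$test_pct_interaction,
                                                 hi$sniff_mean_duration_s)
    bundle$valence_susceptible <-
      if (nrow(su) >= 3L) pearson_test(su$test_pct_interaction,
                                       su$sniff_mean_duration_s) else NULL
    bundle$valence_ancova <- if (nrow(su) >= 3L) ancova_compare(
      dplyr::bind_rows(
        tibble::tibble(x = hi$test_pct_interaction,
                       y = hi$sniff_mean_duration_s, group = "high_interest"),
        tibble::tibble(x = su$test_pct_interaction,
                       y = su$sniff_mean_duration_s, group = "susceptible"))
    ) else NULL
    sd_mice <- outcomes |>
      dplyr::filter(.data$group == "sleepdep", .data$sniff_n_bouts > 0)
    bundle$valence_sleepdep <- pearson_test(sd_mice$test_pct_interaction,
                                            sd_mice$sniff_mean_duration_s)
  }

  if (!is.null(fos)) {
    counted <- purrr::map_dbl(fos$images,
                              function(x) detect_spots(x$image)$count)
    dens <- purrr::map_dbl(fos$images,
                           function(x) detect_spots(x$image)$density_mm2)
    ctab <- fos$manifest |>
      dplyr::mutate(count = counted, density_mm2 = dens)
    avg <- hemisphere_average(ctab) |>
      dplyr::left_join(dplyr::distinct(ctab[, c("mouse_id", "group")]),
                       by = "mouse_id")
    bundle$fos_counts <- avg
    bundle$fos_tests <- fos_compare_groups(avg)
  }

  # group summary: mean +- SEM per metric (SD available via export flag)
  num_cols <- names(outcomes)[vapply(outcomes, is.numeric, logical(1))]
  bundle$group_summary <- outcomes |>
    tidyr::pivot_longer(dplyr::all_of(num_cols), names_to = "metric") |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(n = sum(!is.na(.data$value)),
                     mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     sem = .data$sd / sqrt(.data$n), .groups = "drop")
  bundle$outcomes <- outcomes
  structure(bundle, class = "report_bundle")
}

#' Export a report bundle to files
#'
#' Writes the per-mouse outcome table and group summary as CSV, the
#' statistical records as JSON, and (optionally) summary plots.
#'
#' @param bundle A [run_full_analysis()] result.
#' @param dir Output directory (created if needed).
#' @param plots Also write PDF plots (default `FALSE`).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(bundle, dir, plots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    outcomes = file.path(dir, "outcomes.csv"),
    summary = file.path(dir, "group_summary.csv"),
    stats = file.path(dir, "stats.json")
  )
  utils::write.csv(bundle$outcomes, paths["outcomes"], row.names = FALSE)
  utils::write.csv(bundle$group_summary, paths["summary"], row.names = FALSE)
  stats_records <- list(
    seed = bundle$seed, zt_window = bundle$zt_window,
    activity_anova = bundle$activity_anova,
    temperature_anova = bundle$temperature_anova,
    susceptible_fraction = bundle$susceptible_fraction,
    fisher_stress = bundle$fisher_stress,
    fisher_sleepdep = bundle$fisher_sleepdep,
    valence_high_interest = bundle$valence_high_interest,
    valence_susceptible = bundle$valence_susceptible,
    fos_tests = bundle$fos_tests
  )
  jsonlite::write_json(stats_records, paths["stats"], auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  if (plots) {
    p <- file.path(dir, "activity_temperature.pdf")
    grDevices::pdf(p, width = 5, height = 4)
    print(plot_activity_temperature(bundle$activity_temperature_fit,
                                    bundle$outcomes))
    grDevices::dev.off()
    paths <- c(paths, plot = p)
  }
  invisible(paths)
}
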