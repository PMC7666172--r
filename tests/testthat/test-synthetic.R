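# The synthetic-cohort generator: determinism, edge cases, format
# compatibility and consistency with the scoring rules.

test_that("identical seed and config give identical cohorts", {
  cfg <- cohort_config()
  c1 <- simulate_cohort(cfg, seed = 11)
  c2 <- simulate_cohort(cfg, seed = 11)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(c1$mice, c3$mice))
})

test_that("degenerate activity targets produce all-active / all-inactive", {
  cfg1 <- cohort_config(actigraphy = list(light_active = 1, dark_active = 1,
                                          between_sd = 0, realization_sd = 0))
  a1 <- gen_actigraphy(cfg1, "control")
  expect_equal(sum(inactivity_mask(a1$epochs)), 0L)

  cfg0 <- cohort_config(actigraphy = list(light_active = 0, dark_active = 0,
                                          between_sd = 0, realization_sd = 0))
  a0 <- gen_actigraphy(cfg0, "control")
  expect_true(all(a0$epochs$counts == 0L))
  expect_true(all(inactivity_mask(a0$epochs)))
})

test_that("simulated window means center on the generator parameter", {
  cfg <- cohort_config(actigraphy = list(between_sd = 0, realization_sd = 0))
  set.seed(702)
  v <- replicate(60, {
    a <- gen_actigraphy(cfg, "stress")
    window_mean_active(hourly_profile(a$epochs), 13, 16)
  })
  sem <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 40.1), 2 * sem + 0.5)
})

test_that("generated series satisfy the consuming formats and round-trip", {
  coh <- simulate_cohort(cohort_config(), seed = 13)
  es <- coh$actigraphy[["s01"]]$epochs
  expect_s3_class(es, "epoch_series")
  expect_true(all(es$counts >= 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(es, f)
  expect_identical(read_epoch_csv(f)$counts, es$counts)

  ts <- coh$actigraphy[["s01"]]$temperature
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_temperature_csv(ts, f2)
  expect_equal(read_temperature_csv(f2)$temps_c, ts$temps_c,
               tolerance = 1e-6)

  ses <- coh$sessions[["c01"]]$test$session
  for (dialect in c("dlc", "flat")) {
    f3 <- withr::local_tempfile(fileext = ".csv")
    write_pose_csv(ses, f3, dialect, px_per_cm = 8)
    back <- read_pose_csv(f3, fps = ses$fps, px_per_cm = 8)
    expect_equal(back$frames$x_n, ses$frames$x_n, tolerance = 1e-3)
    expect_equal(back$frames$y_c, ses$frames$y_c, tolerance = 1e-3)
  }
})

test_that("planted sniffing bouts are exactly what the detector recovers", {
  cfg <- cohort_config()
  arena <- arena_geometry()
  mesh <- mesh_segment(arena)
  set.seed(703)
  for (i in 1:8) {
    g <- gen_social_session(cfg, "control", "test")
    d <- nose_mesh_distance(g$session, mesh)
    got <- detect_sniff_bouts(d, fps = g$session$fps)
    expect_equal(nrow(got), nrow(g$truth$bouts))
    expect_equal(got$start_s, g$truth$bouts$start_s, tolerance = 1e-9)
    expect_equal(got$duration_s, g$truth$bouts$duration_s, tolerance = 1e-9)
  }
})

test_that("injected bouts below 500 ms are not detected", {
  cfg <- cohort_config(social = list(sniff = list(
    n_bouts = c(control = 10, resilient = 10, susceptible = 10, sleepdep = 10),
    base_s = c(control = 0.3, resilient = 0.3, susceptible = 0.3,
               sleepdep = 0.3),
    coupling_s_per_s = c(control = 0, resilient = 0, susceptible = 0,
                         sleepdep = 0),
    ref_interaction_s = c(control = 0, resilient = 0, susceptible = 0,
                          sleepdep = 0),
    noise_sd = c(control = 0, resilient = 0, susceptible = 0, sleepdep = 0),
    min_duration_s = 0.2, duration_shape = 50,
    annotation_jitter_sd_s = 0.05)))
  mesh <- mesh_segment(arena_geometry())
  set.seed(704)
  g <- gen_social_session(cfg, "control", "test")
  expect_gt(nrow(g$truth$bouts), 0L)
  expect_true(all(g$truth$bouts$duration_s < 0.5))
  d <- nose_mesh_distance(g$session, mesh)
  expect_equal(nrow(detect_sniff_bouts(d, fps = g$session$fps)), 0L)
})

test_that("habituation sessions are symmetric and maximal avoidance wins", {
  cfg <- cohort_config()
  arena <- arena_geometry()
  set.seed(705)
  occ <- purrr::map_dfr(1:25, function(i) {
    g <- gen_social_session(cfg, "control", "habituation")
    compute_zone_occupancy(g$session, arena)
  })
  expect_lt(abs(mean(occ$pct_interaction) - mean(occ$pct_avoidance)), 4)
  expect_equal(sum(purrr::map_int(1:25, function(i) {
    g <- gen_social_session(cfg, "control", "habituation")
    nrow(g$truth$bouts)
  })), 0L)

  # strong avoidance phenotype: avoidance time exceeds interaction time
  set.seed(706)
  wins <- purrr::map_lgl(1:30, function(i) {
    g <- gen_social_session(cfg, "susceptible", "test")
    zo <- compute_zone_occupancy(g$session, arena)
    zo$pct_avoidance > zo$pct_interaction
  })
  expect_gte(mean(wins), 0.99)
})

test_that("fos generator plants the requested spot configuration", {
  cfg <- cohort_config()
  set.seed(707)
  g0 <- gen_fos_image(cfg, n_spots = 0)
  expect_equal(nrow(g0$truth), 0L)
  g1 <- gen_fos_image(cfg, n_spots = 12)
  g2 <- gen_fos_image(cfg, n_spots = 24)
  expect_equal(nrow(g2$truth), 2L * nrow(g1$truth))
  expect_error(gen_fos_image(cfg, n_spots = 5000), "overlap")
})
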