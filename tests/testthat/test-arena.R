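# Zone occupancy, travel distance and susceptibility classification.

arena <- arena_geometry()

test_that("zone occupancy matches a per-frame membership oracle", {
  # stationary in the interaction zone for the whole session
  n <- 150 * 30
  s <- make_session(cbind(rep(15, n), rep(5, n)))
  zo <- compute_zone_occupancy(s, arena)
  expect_equal(zo$time_interaction_s, 150)
  expect_equal(zo$pct_interaction, 100)
  expect_equal(zo$distance_cm, 0)

  # stationary mid-arena: no zone time at all
  s2 <- make_session(cbind(rep(15, 100), rep(20, 100)))
  zo2 <- compute_zone_occupancy(s2, arena)
  expect_equal(zo2$time_interaction_s + zo2$time_avoidance_s, 0)

  # random trajectories against the brute-force per-frame loop
  set.seed(301)
  for (i in 1:200) {
    nf <- sample(50:400, 1L)
    cent <- cbind(runif(nf, 0, 30), runif(nf, 0, 40))
    zo <- compute_zone_occupancy(make_session(cent, fps = 25), arena)
    t_int <- sum(cent[, 2] <= arena$interaction_depth_cm) / 25
    t_avd <- sum(cent[, 2] >= 40 - arena$avoidance_depth_cm) / 25
    d <- sum(sqrt(diff(cent[, 1])^2 + diff(cent[, 2])^2))
    expect_equal(zo$time_interaction_s, t_int)
    expect_equal(zo$time_avoidance_s, t_avd)
    expect_equal(zo$distance_cm, d)
  }
})

test_that("low-likelihood centroid frames are bridged by interpolation", {
  cent <- cbind(c(0, 5, 500, 15, 20), rep(20, 5))
  lik <- c(1, 1, 0.1, 1, 1)  # dropped frame interpolates to x = 10
  s <- make_session(cent, fps = 1, lik_c = lik)
  zo <- compute_zone_occupancy(s, arena)
  expect_equal(zo$distance_cm, 20)  # jump in the dropped frame is ignored
})

test_that("classification applies strict control-referenced thresholds", {
  set.seed(302)
  controls <- tibble::tibble(mouse_id = paste0("c", 1:6),
                             pct_interaction = c(35, 38, 40, 42, 44, 41),
                             pct_avoidance = c(18, 22, 20, 19, 23, 18))
  m_i <- mean(controls$pct_interaction); s_i <- sd(controls$pct_interaction)
  m_a <- mean(controls$pct_avoidance); s_a <- sd(controls$pct_avoidance)
  stressed <- tibble::tibble(
    mouse_id = c("equal", "edge", "both", "one"),
    pct_interaction = c(m_i, m_i, m_i - 2 * s_i, m_i),
    pct_avoidance = c(m_a, m_a + s_a, m_a + 2 * s_a, m_a + 2 * s_a))
  cls <- classify_susceptibility(stressed, controls)
  expect_equal(cls$label,
               c("resilient", "resilient", "susceptible", "intermediate"))
  # boundary value mean + 1 SD does not meet the strict > criterion
  expect_false(cls$avoid_criterion[cls$mouse_id == "edge"])
  expect_error(classify_susceptibility(stressed, controls[1, ]), ">= 2")
})

test_that("classification is invariant under joint affine rescaling", {
  set.seed(303)
  controls <- tibble::tibble(mouse_id = paste0("c", 1:8),
                             pct_interaction = rnorm(8, 40, 6),
                             pct_avoidance = rnorm(8, 20, 6))
  stressed <- tibble::tibble(mouse_id = paste0("s", 1:10),
                             pct_interaction = rnorm(10, 30, 15),
                             pct_avoidance = rnorm(10, 35, 15))
  base <- classify_susceptibility(stressed, controls)$label
  resc <- function(df, a, b) dplyr::mutate(
    df, pct_interaction = a * pct_interaction + b,
    pct_avoidance = a * pct_avoidance + b)
  again <- classify_susceptibility(resc(stressed, 2.5, 7),
                                   resc(controls, 2.5, 7))$label
  expect_identical(base, again)
})

test_that("with vanishing control SD any deviating mouse is non-resilient", {
  controls <- tibble::tibble(mouse_id = paste0("c", 1:4),
                             pct_interaction = rep(40, 4) + 1e-9 * (1:4),
                             pct_avoidance = rep(20, 4) + 1e-9 * (1:4))
  stressed <- tibble::tibble(mouse_id = "s1", pct_interaction = 39,
                             pct_avoidance = 21)
  expect_true(classify_susceptibility(stressed, controls)$label != "resilient")
})

test_that("high-social-interest set applies the criteria to controls too", {
  occ <- tibble::tibble(
    mouse_id = paste0("m", 1:8),
    group = c(rep("control", 5), rep("stress", 3)),
    pct_interaction = c(40, 41, 39, 42, 10, 40, 8, 41),
    pct_avoidance = c(20, 21, 19, 22, 60, 20, 55, 21))
  hs <- high_social_interest_set(occ)
  # the deviant control (mouse m5) is excluded from the set
  expect_false(hs$occupancy$high_interest[5L])
  pr <- hs$proportions
  expect_equal(pr$n_high_interest[pr$group == "control"], 4L)
  expect_equal(pr$n_high_interest[pr$group == "stress"], 2L)

  # all mice at the control mean: everyone is high-interest
  flat <- tibble::tibble(mouse_id = paste0("m", 1:6),
                         group = rep(c("control", "stress"), each = 3),
                         pct_interaction = 40 + rep(1:3, 2),
                         pct_avoidance = 20 + rep(1:3, 2))
  expect_true(all(high_social_interest_set(flat)$occupancy$high_interest))
})
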