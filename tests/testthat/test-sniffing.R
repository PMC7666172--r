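# Nose-mesh geometry, the 2 cm / 500 ms bout rule and bout summaries.

test_that("nose-to-mesh distance matches a dense-sampling oracle", {
  arena <- arena_geometry(mesh_span_cm = c(10, 20))
  mesh <- mesh_segment(arena)
  # on the segment, perpendicular from the midpoint, and beyond an endpoint
  pts <- rbind(c(15, 0), c(15, 2), c(25, 1))
  s <- make_session(pts, nose = pts, fps = 30)
  d <- nose_mesh_distance(s, mesh)
  expect_equal(d[1], 0)
  expect_equal(d[2], 2)
  expect_equal(d[3], sqrt(5^2 + 1^2))

  set.seed(401)
  for (i in 1:50) {
    p <- c(runif(1, -5, 35), runif(1, -2, 42))
    sp <- make_session(rbind(p), fps = 30)
    expect_equal(nose_mesh_distance(sp, mesh),
                 oracle_point_segment(p[1], p[2], mesh[1, ], mesh[2, ]),
                 tolerance = 1e-6)
  }
})

test_that("bout detection honors the inclusive 500 ms boundary", {
  mk <- function(n_in, fps = 30) c(rep(5, 10), rep(1, n_in), rep(5, 10))
  expect_equal(nrow(detect_sniff_bouts(mk(12), fps = 30)), 0L)  # 400 ms
  b <- detect_sniff_bouts(mk(15), fps = 30)                     # 500 ms
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_s, 0.5)
  # non-integer frame product: ceiling applies (0.5 s at 25 fps = 12.5)
  expect_equal(nrow(detect_sniff_bouts(c(rep(5, 5), rep(1, 12), rep(5, 5)),
                                       fps = 25)), 0L)
  expect_equal(nrow(detect_sniff_bouts(c(rep(5, 5), rep(1, 13), rep(5, 5)),
                                       fps = 25)), 1L)
})

test_that("bout detection equals the run-length oracle on random tracks", {
  set.seed(402)
  for (i in 1:300) {
    n <- sample(30:500, 1L)
    d <- ifelse(runif(n) < 0.45, runif(n, 0, 2), runif(n, 2.0001, 10))
    fps <- sample(c(20, 25, 29.97, 30), 1L)
    got <- detect_sniff_bouts(d, fps = fps)
    want <- oracle_bouts(d <= 2, fps = fps)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$duration_s, want$duration_s)
    }
  }
})

test_that("undefined frames break runs unless bridged by max_gap_frames", {
  d <- c(rep(1, 10), NA, rep(1, 10), rep(5, 10))
  expect_equal(nrow(detect_sniff_bouts(d, fps = 30)), 0L)  # both halves short
  b <- detect_sniff_bouts(d, fps = 30, max_gap_frames = 1)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_s, 21 / 30)
  # a gap at the track edge is never bridged
  d_edge <- c(NA, rep(1, 20), rep(5, 5))
  expect_equal(detect_sniff_bouts(d_edge, fps = 30,
                                  max_gap_frames = 2)$duration_s, 20 / 30)
})

test_that("tightening the distance threshold never adds sniffing time", {
  set.seed(403)
  for (i in 1:50) {
    d <- runif(300, 0, 4)
    t2 <- sum(detect_sniff_bouts(d, 30, max_dist_cm = 2)$duration_s)
    t1 <- sum(detect_sniff_bouts(d, 30, max_dist_cm = 1)$duration_s)
    expect_lte(t1, t2)
  }
})

test_that("splitting a track preserves bouts that do not span the cut", {
  set.seed(404)
  d <- ifelse(runif(400) < 0.5, 1, 5)
  full <- detect_sniff_bouts(d, fps = 30)
  cut <- 200L
  left <- detect_sniff_bouts(d[1:cut], fps = 30)
  right <- detect_sniff_bouts(d[(cut + 1L):400], fps = 30)
  right$start_s <- right$start_s + cut / 30
  right$end_s <- right$end_s + cut / 30
  not_spanning <- full[full$end_s <= cut / 30 | full$start_s >= cut / 30, ]
  merged <- rbind(left, right)
  expect_true(all(not_spanning$start_s %in% merged$start_s))
})

test_that("bout summaries total, count and average correctly", {
  none <- summarize_sniffing(detect_sniff_bouts(rep(5, 100), 30))
  expect_equal(none$total_time_s, 0)
  expect_equal(none$n_bouts, 0L)
  expect_true(is.na(none$mean_bout_duration_s))

  b <- tibble::tibble(start_s = c(0, 10), end_s = c(1, 13),
                      duration_s = c(1, 3))
  sm <- summarize_sniffing(b)
  expect_equal(sm$total_time_s, 4)
  expect_equal(sm$n_bouts, 2L)
  expect_equal(sm$mean_bout_duration_s, 2)

  set.seed(405)
  for (i in 1:20) {
    durs <- runif(sample(1:30, 1), 0.5, 4)
    b <- tibble::tibble(start_s = cumsum(durs + 1) - durs - 1,
                        end_s = cumsum(durs + 1) - 1, duration_s = durs)
    sm <- summarize_sniffing(b)
    expect_equal(sm$total_time_s, sum(durs))
    expect_equal(sm$mean_bout_duration_s, mean(durs))
  }
})

test_that("automatic totals validate against manual annotation", {
  manual <- c(10, 20, 30, 40, 55)
  v <- validate_against_manual(manual, manual)
  expect_equal(v$r, 1)
  v2 <- validate_against_manual(0.9 * manual, manual)
  expect_equal(v2$r, 1)
  expect_equal(v2$slope, 0.9)
  expect_error(validate_against_manual(1:2, 1:2), ">= 3")

  # annotation noise degrades the correlation monotonically (on average)
  set.seed(406)
  truth <- runif(40, 5, 60)
  r_at <- vapply(c(0.5, 3, 12), function(sg) {
    mean(replicate(30, validate_against_manual(
      truth, truth + rnorm(40, 0, sg))$r))
  }, numeric(1))
  expect_true(all(diff(r_at) < 0))
})
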