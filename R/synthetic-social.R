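# Synthetic social-interaction sessions.
#
# A session is synthesized from a per-mouse zone-visit schedule whose zone
# totals equal the planted zone-time ground truth: the planted percent of
# session in the interaction and avoidance zones is sampled from the
# phenotype's distribution, split into visits, and the centroid follows a
# smooth steered/Ornstein-Uhlenbeck path through the scheduled zones (zone
# realization jitter ~1 s from boundary traversals). Sniffing bouts are
# injected inside interaction-zone visits: during a bout the nose is held
# within 2 cm of the mesh wall; outside bouts it is kept beyond 2 cm, so the
# planted bout list is the complete ground truth for the detector. Mean bout
# duration is generated with a positive linear coupling to the planted
# interaction time for high-social-interest phenotypes (targeting Pearson
# r ~= 0.74) and no coupling for the susceptible phenotype.

# zone-target key and sniff-parameter key for each phenotype
phenotype_zone_key <- function(phenotype) {
  switch(phenotype,
         control = "control",
         resilient = , sleepdep_social = "resilient",
         susceptible = , sleepdep_avoidant = "susceptible",
         stop("unknown phenotype: ", phenotype))
}

phenotype_sniff_key <- function(phenotype) {
  switch(phenotype,
         control = "control", resilient = "resilient",
         susceptible = "susceptible",
         sleepdep_social = , sleepdep_avoidant = "sleepdep",
         stop("unknown phenotype: ", phenotype))
}

# Split `total` into n positive chunks with random proportions.
split_chunks <- function(total, n) {
  if (n <= 1L) return(total)
  w <- stats::rgamma(n, shape = 4)
  total * w / sum(w)
}

# OU wander around an anchor, vectorized (a = per-frame pull retention).
ou_segment <- function(p0, anchor, n, step_sd, a = 0.8, v_max) {
  if (n <= 0L) return(matrix(numeric(), ncol = 2))
  out <- matrix(NA_real_, n, 2)
  for (d in 1:2) {
    noise <- stats::rnorm(n, 0, step_sd)
    dev <- stats::filter(noise, a, method = "recursive",
                         init = p0[d] - anchor[d])
    out[, d] <- anchor[d] + as.numeric(dev)
  }
  # cap the first-frame jump at v_max by prepending a straight approach
  out
}

# Straight steering from p0 toward target at speed v (cm/frame); returns the
# positions of the approach (possibly length 0 when already there).
steer_to <- function(p0, target, v) {
  d <- sqrt(sum((target - p0)^2))
  k <- ceiling(d / v)
  if (k <= 0L) return(matrix(numeric(), ncol = 2))
  t <- seq_len(k) / k
  cbind(p0[1] + t * (target[1] - p0[1]), p0[2] + t * (target[2] - p0[2]))
}

#' Generate a tracked social-interaction session with ground truth
#'
#' @param cfg A [cohort_config()].
#' @param phenotype One of `"control"`, `"resilient"`, `"susceptible"`,
#'   `"sleepdep_social"`, `"sleepdep_avoidant"`.
#' @param kind `"test"` (target present; sniffing bouts injected) or
#'   `"habituation"` (target absent; symmetric zone targets, no bouts).
#' @param distance_target_cm Total travel-distance target (cm).
#' @return List: `session` ([tracked_session()]), `truth` (planted zone
#'   percentages, planted bout table, planted mean-duration parameter) and
#'   `annotation` (manually-scored-style bout intervals: truth plus boundary
#'   jitter).
#' @export
gen_social_session <- function(cfg, phenotype, kind = c("test", "habituation"),
                               distance_target_cm = 900) {
  kind <- match.arg(kind)
  soc <- cfg$social
  arena <- arena_geometry(width_cm = cfg$arena$width_cm,
                          length_cm = cfg$arena$length_cm)
  fps <- soc$fps
  n_frames <- as.integer(round(soc$duration_s * fps))
  d_int <- arena$interaction_depth_cm
  d_avd <- arena$avoidance_depth_cm
  L <- arena$length_cm; W <- arena$width_cm

  tz <- if (kind == "habituation") {
    list(int = soc$habituation_target$int, avd = soc$habituation_target$avd)
  } else {
    soc$zone_targets[[phenotype_zone_key(phenotype)]]
  }
  pct_int <- max(1, stats::rnorm(1L, tz$int[1], tz$int[2]))
  pct_avd <- max(1, stats::rnorm(1L, tz$avd[1], tz$avd[2]))
  tot <- pct_int + pct_avd
  if (tot > 90) { pct_int <- pct_int * 90 / tot; pct_avd <- pct_avd * 90 / tot }
  t_int <- pct_int / 100 * soc$duration_s
  t_avd <- pct_avd / 100 * soc$duration_s
  t_mid <- soc$duration_s - t_int - t_avd

  # visit schedule: zone visits of ~20 s interleaved with middle-zone links
  n_iv <- max(1L, round(t_int / 20))
  n_av <- max(1L, round(t_avd / 20))
  zone_visits <- c(rep("int", n_iv), rep("avd", n_av))
  zone_durs <- c(split_chunks(t_int, n_iv), split_chunks(t_avd, n_av))
  ord <- sample(length(zone_visits))
  zone_visits <- zone_visits[ord]; zone_durs <- zone_durs[ord]
  n_mid <- length(zone_visits) + 1L
  mid_durs <- split_chunks(t_mid, n_mid)
  seg_zone <- character(0); seg_dur <- numeric(0)
  for (i in seq_along(zone_visits)) {
    seg_zone <- c(seg_zone, "mid", zone_visits[i])
    seg_dur <- c(seg_dur, mid_durs[i], zone_durs[i])
  }
  seg_zone <- c(seg_zone, "mid"); seg_dur <- c(seg_dur, mid_durs[n_mid])
  seg_frames <- round(seg_dur * fps)
  seg_frames[length(seg_frames)] <-
    n_frames - sum(seg_frames[-length(seg_frames)])
  keep <- seg_frames > 0L
  seg_zone <- seg_zone[keep]; seg_frames <- as.integer(seg_frames[keep])

  # anchors well inside each zone so OU excursions stay in-zone
  anchor_for <- function(zone) {
    y <- switch(zone,
                int = stats::runif(1L, 2, d_int - 2),
                avd = stats::runif(1L, L - d_avd + 2, L - 2),
                mid = stats::runif(1L, d_int + 3, L - d_avd - 3))
    c(stats::runif(1L, 3, W - 3), y)
  }
  v_steer <- 25 / fps  # cm per frame during zone changes
  step_sd <- max(0.02, (distance_target_cm +
                          stats::rnorm(1L, 0, soc$distance_sd) - 400) /
                   (n_frames * 1.25))
  pos <- matrix(NA_real_, 0, 2)
  cur <- anchor_for(seg_zone[1L])
  for (i in seq_along(seg_zone)) {
    anchor <- anchor_for(seg_zone[i])
    approach <- steer_to(cur, anchor, v_steer)
    k <- nrow(approach)
    if (k >= seg_frames[i]) {
      segpos <- approach[seq_len(seg_frames[i]), , drop = FALSE]
    } else {
      wander <- ou_segment(anchor, anchor, seg_frames[i] - k, step_sd)
      segpos <- rbind(approach, wander)
    }
    pos <- rbind(pos, segpos)
    cur <- pos[nrow(pos), ]
  }
  pos[, 1] <- pmin(pmax(pos[, 1], 0.2), W - 0.2)
  pos[, 2] <- pmin(pmax(pos[, 2], 0.2), L - 0.2)

  # nose from heading
  vel <- rbind(c(0, 0), diff(pos))
  speed <- sqrt(rowSums(vel^2))
  heading <- vel / pmax(speed, 1e-9)
  still <- speed < 0.05
  for (d in 1:2) {
    h <- heading[, d]; h[still] <- NA_real_
    if (all(is.na(h))) h[] <- d - 1 else {
      h <- bridge_low_likelihood(h, !is.na(h))
    }
    heading[, d] <- h
  }
  heading <- heading / pmax(sqrt(rowSums(heading^2)), 1e-9)
  nose <- pos + soc$nose_offset_cm * heading
  nose[, 1] <- pmin(pmax(nose[, 1], 0.2), W - 0.2)
  nose[, 2] <- pmin(pmax(nose[, 2], 2.2), L - 0.2)  # >2 cm off the mesh

  # planted sniffing bouts inside interaction-zone visits (test only)
  sn <- soc$sniff
  bouts <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                          duration_s = numeric())
  mu_dur <- NA_real_
  if (kind == "test") {
    key <- phenotype_sniff_key(phenotype)
    mu_dur <- sn$base_s[[key]] +
      sn$coupling_s_per_s[[key]] * (t_int - sn$ref_interaction_s[[key]]) +
      stats::rnorm(1L, 0, sn$noise_sd[[key]])
    mu_dur <- max(sn$min_duration_s + 0.05, mu_dur)
    n_b <- stats::rpois(1L, sn$n_bouts[[key]])
    if (n_b > 0L) {
      durs <- sn$min_duration_s +
        stats::rgamma(n_b, shape = sn$duration_shape,
                      scale = (mu_dur - sn$min_duration_s) / sn$duration_shape)
      bf <- pmax(1L, as.integer(round(durs * fps)))
      seg_end <- cumsum(seg_frames)
      seg_start <- seg_end - seg_frames + 1L
      iseg <- which(seg_zone == "int")
      gap <- as.integer(ceiling(0.35 * fps))
      cursor <- seg_start[iseg] + gap
      avail <- function(j) (seg_end[iseg[j]] - gap) - cursor[j] + 1
      placed <- integer(0); placed_len <- integer(0)
      for (b in seq_len(n_b)) {
        cap <- vapply(seq_along(iseg), avail, numeric(1))
        j <- which.max(cap)
        if (cap[j] >= bf[b]) {
          placed <- c(placed, cursor[j]); placed_len <- c(placed_len, bf[b])
          cursor[j] <- cursor[j] + bf[b] + gap
        }
      }
      if (length(placed) > 0L) {
        o <- order(placed)
        bouts <- tibble::tibble(
          start_s = (placed[o] - 1L) / fps,
          end_s = (placed[o] - 1L + placed_len[o]) / fps,
          duration_s = placed_len[o] / fps
        )
        for (b in seq_along(placed)) {
          idx <- placed[b]:(placed[b] + placed_len[b] - 1L)
          nose[idx, 2] <- stats::runif(length(idx), 0.5, 1.5)
          nose[idx, 1] <- pmin(pmax(pos[idx, 1], 1), W - 1)
        }
      }
    }
  }

  lik_c <- stats::runif(n_frames, 0.95, 1)
  lik_n <- stats::runif(n_frames, 0.95, 1)
  drop_c <- stats::runif(n_frames) < soc$likelihood_low_rate
  drop_n <- stats::runif(n_frames) < soc$likelihood_low_rate
  if (nrow(bouts) > 0L) {   # keep planted bouts clean of pose dropouts
    in_bout <- rep(FALSE, n_frames)
    for (b in seq_len(nrow(bouts))) {
      in_bout[(round(bouts$start_s[b] * fps) + 1L):
                round(bouts$end_s[b] * fps)] <- TRUE
    }
    drop_n[in_bout] <- FALSE
  }
  lik_c[drop_c] <- stats::runif(sum(drop_c), 0, 0.5)
  lik_n[drop_n] <- stats::runif(sum(drop_n), 0, 0.5)

  session <- tracked_session(
    tibble::tibble(x_c = pos[, 1], y_c = pos[, 2], lik_c = lik_c,
                   x_n = nose[, 1], y_n = nose[, 2], lik_n = lik_n),
    fps = fps, kind = kind)

  jit <- sn$annotation_jitter_sd_s
  annotation <- if (nrow(bouts) > 0L) {
    s <- bouts$start_s + stats::rnorm(nrow(bouts), 0, jit)
    e <- bouts$end_s + stats::rnorm(nrow(bouts), 0, jit)
    tibble::tibble(start_s = pmax(0, s), end_s = pmax(pmax(0, s) + 0.1, e))
  } else {
    tibble::tibble(start_s = numeric(), end_s = numeric())
  }

  list(session = session,
       truth = list(pct_interaction_target = pct_int,
                    pct_avoidance_target = pct_avd,
                    bouts = bouts, mu_duration_s = mu_dur,
                    t_interaction_target_s = t_int),
       annotation = annotation)
}
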