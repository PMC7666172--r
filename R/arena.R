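# Arena behavior: zone occupancy and travel distance from tracked
# social-interaction sessions, and control-referenced susceptible/resilient
# classification.
#
# The arena is a 30 x 40 cm chamber with a metal meshwork (holding the target
# mouse) at one short wall. The interaction zone is the band of the arena
# nearest the mesh wall, the avoidance zone the band at the opposite wall;
# zone depths are not standardized for this assay, so the default splits
# the arena length into thirds (13.33 cm each), fully configurable.

#' Arena geometry and calibration
#'
#' @param width_cm Arena width (short axis with the mesh wall), default 30.
#' @param length_cm Arena length, default 40.
#' @param interaction_depth_cm Depth of the interaction zone measured from
#'   the mesh wall; default one third of the length.
#' @param avoidance_depth_cm Depth of the avoidance zone at the opposite
#'   wall; default one third of the length.
#' @param px_per_cm Pixel calibration for pose/track files given in pixels
#'   (default 1: coordinates already in cm).
#' @param mesh_span_cm Two-element x-range of the meshwork front face along
#'   the mesh wall (default the full wall). The mesh wall is at y = 0.
#' @return An object of class `arena_geometry`.
#' @export
arena_geometry <- function(width_cm = 30, length_cm = 40,
                           interaction_depth_cm = length_cm / 3,
                           avoidance_depth_cm = length_cm / 3,
                           px_per_cm = 1,
                           mesh_span_cm = c(0, width_cm)) {
  abort_if(interaction_depth_cm <= 0 || avoidance_depth_cm <= 0,
           "zone depths must be positive")
  abort_if(interaction_depth_cm + avoidance_depth_cm > length_cm,
           "zone depths exceed arena length")
  abort_if(px_per_cm <= 0, "`px_per_cm` must be positive")
  structure(
    list(width_cm = width_cm, length_cm = length_cm,
         interaction_depth_cm = interaction_depth_cm,
         avoidance_depth_cm = avoidance_depth_cm,
         px_per_cm = px_per_cm, mesh_span_cm = mesh_span_cm),
    class = "arena_geometry"
  )
}

#' Front face of the meshwork as a segment
#'
#' @param arena An [arena_geometry()].
#' @return 2 x 2 matrix of segment endpoints (cm), class `mesh_segment`.
#' @export
mesh_segment <- function(arena) {
  seg <- rbind(c(arena$mesh_span_cm[1], 0), c(arena$mesh_span_cm[2], 0))
  abort_if(all(seg[1, ] == seg[2, ]), "mesh segment has zero length")
  structure(seg, class = "mesh_segment")
}

#' Construct a tracked session
#'
#' Per-frame body-part coordinates (at minimum centroid and nose) with pose
#' likelihoods, calibrated to arena cm with the mesh wall at y = 0.
#'
#' @param frames Tibble with columns `x_c`, `y_c`, `lik_c` (centroid) and
#'   `x_n`, `y_n`, `lik_n` (nose), one row per frame, coordinates in cm.
#' @param fps Frames per second.
#' @param kind `"habituation"` (target absent) or `"test"` (target present).
#' @return Object of class `tracked_session`.
#' @export
tracked_session <- function(frames, fps, kind = c("test", "habituation")) {
  kind <- match.arg(kind)
  abort_if(!is_scalar_num(fps) || fps <= 0, "`fps` must be positive")
  needed <- c("x_c", "y_c", "lik_c", "x_n", "y_n", "lik_n")
  abort_if(!all(needed %in% names(frames)),
           paste("`frames` must contain:", paste(needed, collapse = ", ")))
  abort_if(nrow(frames) < 1L, "session has no frames")
  structure(list(frames = tibble::as_tibble(frames), fps = fps, kind = kind),
            class = "tracked_session")
}

# Linear interpolation across low-likelihood frames; endpoints carried.
bridge_low_likelihood <- function(x, ok) {
  if (all(ok)) return(x)
  abort_if(!any(ok), "no frames above the likelihood threshold")
  idx <- seq_along(x)
  stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
}

#' Zone occupancy and travel distance for a session
#'
#' Zone membership is decided per frame from the centroid: interaction zone
#' when the centroid lies within `interaction_depth_cm` of the mesh wall,
#' avoidance zone when within `avoidance_depth_cm` of the opposite wall.
#' Frames with centroid likelihood below `min_likelihood` are bridged by
#' linear interpolation before zone assignment and distance summation.
#'
#' @param session A [tracked_session()].
#' @param arena An [arena_geometry()].
#' @param min_likelihood Pose-likelihood gate (default 0.9).
#' @return One-row tibble: `time_interaction_s`, `time_avoidance_s`,
#'   `pct_interaction`, `pct_avoidance`, `distance_cm`, `duration_s`.
#' @export
compute_zone_occupancy <- function(session, arena, min_likelihood = 0.9) {
  abort_if(!inherits(session, "tracked_session"),
           "`session` must be a tracked_session")
  abort_if(!inherits(arena, "arena_geometry"),
           "`arena` must be an arena_geometry")
  fr <- session$frames
  ok <- fr$lik_c >= min_likelihood
  x <- bridge_low_likelihood(fr$x_c, ok)
  y <- bridge_low_likelihood(fr$y_c, ok)
  n <- length(x)
  in_int <- y <= arena$interaction_depth_cm
  in_avd <- y >= arena$length_cm - arena$avoidance_depth_cm
  tibble::tibble(
    time_interaction_s = sum(in_int) / session$fps,
    time_avoidance_s = sum(in_avd) / session$fps,
    pct_interaction = 100 * sum(in_int) / n,
    pct_avoidance = 100 * sum(in_avd) / n,
    distance_cm = sum(sqrt(diff(x)^2 + diff(y)^2)),
    duration_s = n / session$fps
  )
}

#' Classify stressed mice as susceptible / resilient / intermediate
#'
#' Control-referenced thresholds: a stressed mouse's zone time is considered
#' changed when it exceeds the control mean by one control standard deviation
#' (sample SD, n - 1). Avoidance criterion: `pct_avoidance` strictly greater
#' than control mean + SD. Interaction criterion: `pct_interaction` strictly
#' less than control mean - SD. Both met: susceptible; neither: resilient;
#' exactly one: intermediate (kept as its own label unless
#' `intermediate_policy = "nearest"`, which assigns susceptible when the
#' avoidance criterion is the one met and resilient otherwise is not
#' meaningful, so nearest maps one-criterion mice to susceptible).
#'
#' @param stressed Tibble of stressed-mouse zone occupancies with `mouse_id`,
#'   `pct_interaction`, `pct_avoidance`.
#' @param controls Tibble of control-mouse zone occupancies (>= 2 rows).
#' @param intermediate_policy `"keep"` (default) or `"nearest"`.
#' @return `stressed` with added columns `avoid_criterion`,
#'   `interact_criterion`, `label`, plus attributes `avoid_threshold` and
#'   `interact_threshold`.
#' @export
classify_susceptibility <- function(stressed, controls,
                                    intermediate_policy = c("keep", "nearest")) {
  intermediate_policy <- match.arg(intermediate_policy)
  abort_if(nrow(controls) < 2L, "need >= 2 controls to define the SD")
  avoid_thr <- mean(controls$pct_avoidance) + stats::sd(controls$pct_avoidance)
  inter_thr <- mean(controls$pct_interaction) - stats::sd(controls$pct_interaction)
  out <- stressed |>
    dplyr::mutate(
      avoid_criterion = .data$pct_avoidance > avoid_thr,
      interact_criterion = .data$pct_interaction < inter_thr,
      label = dplyr::case_when(
        avoid_criterion & interact_criterion ~ "susceptible",
        !avoid_criterion & !interact_criterion ~ "resilient",
        TRUE ~ "intermediate"
      )
    )
  if (intermediate_policy == "nearest") {
    out$label[out$label == "intermediate"] <- "susceptible"
  }
  attr(out, "avoid_threshold") <- avoid_thr
  attr(out, "interact_threshold") <- inter_thr
  out
}

#' High-social-interest subset
#'
#' Applies the same two control-referenced criteria to every mouse regardless
#' of group (controls included: a control beyond its own cohort's thresholds
#' is excluded too). High social interest = neither criterion met.
#'
#' @param occupancy Tibble with `mouse_id`, `group`, `pct_interaction`,
#'   `pct_avoidance` for all mice.
#' @param control_group Value of `group` identifying controls.
#' @return List: `occupancy` with a logical `high_interest` column, and
#'   `proportions`, a per-group tibble of `n`, `n_high_interest`,
#'   `prop_high_interest`.
#' @export
high_social_interest_set <- function(occupancy, control_group = "control") {
  controls <- occupancy[occupancy$group == control_group, , drop = FALSE]
  abort_if(nrow(controls) < 2L, "need >= 2 controls to define the SD")
  avoid_thr <- mean(controls$pct_avoidance) + stats::sd(controls$pct_avoidance)
  inter_thr <- mean(controls$pct_interaction) - stats::sd(controls$pct_interaction)
  occupancy <- occupancy |>
    dplyr::mutate(high_interest = !(.data$pct_avoidance > avoid_thr) &
                    !(.data$pct_interaction < inter_thr))
  props <- occupancy |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     n_high_interest = sum(.data$high_interest),
                     prop_high_interest = mean(.data$high_interest),
                     .groups = "drop")
  list(occupancy = occupancy, proportions = props)
}
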