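# Assemble a full synthetic cohort with recorded ground truth.

#' Simulate a complete behavioral cohort
#'
#' Generates, for every mouse in the three groups, one day of actigraphy and
#' body temperature (stress-day schedule: stress or cage transfer just
#' before ZT 12) and the pair of social-interaction sessions (habituation
#' without the target, test with the target) with planted sniffing bouts and
#' manual-annotation tracks. Phenotypes are planted deterministically: all
#' controls are `control`; the stress group receives
#' `susceptible_n_stress` susceptible and the rest resilient phenotypes (in
#' randomized order); the sleep-deprived group receives `social_n_sleepdep`
#' high-social-interest (`sleepdep_social`) mice and the rest
#' `sleepdep_avoidant`. One stress mouse optionally carries the planted
#' severe-hypothermia trajectory. Identical seed and configuration give
#' identical cohorts.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed; all generator randomness derives from it.
#' @param modalities Character subset of `c("actigraphy", "social")`;
#'   restricting modalities speeds up large replicate studies. Imaging data
#'   are generated separately by [gen_fos_cohort()].
#' @return List of class `synthetic_cohort`: `config`, `seed`, `mice`
#'   (ground-truth tibble: `mouse_id`, `group`, `phenotype`, `outlier`,
#'   planted window activity / zone / bout truths), `actigraphy` and
#'   `sessions` (per-mouse lists).
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1L,
                            modalities = c("actigraphy", "social")) {
  withr::local_seed(as.integer(seed))
  groups <- cfg$groups
  mice <- tibble::tibble(
    mouse_id = c(sprintf("c%02d", seq_len(groups[["control"]])),
                 sprintf("s%02d", seq_len(groups[["stress"]])),
                 sprintf("d%02d", seq_len(groups[["sleepdep"]]))),
    group = rep(c("control", "stress", "sleepdep"), groups)
  )
  ph_stress <- sample(c(rep("susceptible", cfg$susceptible_n_stress),
                        rep("resilient",
                            groups[["stress"]] - cfg$susceptible_n_stress)))
  ph_sleepdep <- sample(c(rep("sleepdep_social", cfg$social_n_sleepdep),
                          rep("sleepdep_avoidant",
                              groups[["sleepdep"]] - cfg$social_n_sleepdep)))
  mice$phenotype <- c(rep("control", groups[["control"]]),
                      ph_stress, ph_sleepdep)
  mice$outlier <- FALSE
  if (cfg$outlier$enabled && groups[["stress"]] > 0L) {
    # the hypothermic mouse is one of the stressed mice
    idx <- which(mice$group == "stress")
    mice$outlier[sample(idx, 1L)] <- TRUE
  }

  actigraphy <- sessions <- stats::setNames(vector("list", nrow(mice)),
                                            mice$mouse_id)
  mice$window_active_target <- NA_real_
  mice$pct_interaction_target <- NA_real_
  mice$pct_avoidance_target <- NA_real_
  mice$n_bouts_planted <- NA_integer_
  mice$mu_duration_s <- NA_real_

  for (i in seq_len(nrow(mice))) {
    if ("actigraphy" %in% modalities) {
      latent_sd <- sqrt(max(cfg$actigraphy$between_sd^2 -
                              cfg$actigraphy$realization_sd^2, 0))
      offs <- stats::rnorm(1L, 0, latent_sd)
      a <- gen_actigraphy(cfg, mice$group[i], mouse_offset = offs,
                          outlier = mice$outlier[i])
      actigraphy[[i]] <- a
      mice$window_active_target[i] <- a$truth$window_active_target
    }
    if ("social" %in% modalities) {
      dist <- cfg$social$distance[[mice$group[i]]]
      hab <- gen_social_session(cfg, mice$phenotype[i], "habituation",
                                distance_target_cm = dist[1L])
      tst <- gen_social_session(cfg, mice$phenotype[i], "test",
                                distance_target_cm = dist[2L])
      sessions[[i]] <- list(habituation = hab, test = tst)
      mice$pct_interaction_target[i] <- tst$truth$pct_interaction_target
      mice$pct_avoidance_target[i] <- tst$truth$pct_avoidance_target
      mice$n_bouts_planted[i] <- nrow(tst$truth$bouts)
      mice$mu_duration_s[i] <- tst$truth$mu_duration_s
    }
  }
  structure(list(config = cfg, seed = as.integer(seed), mice = mice,
                 actigraphy = actigraphy, sessions = sessions),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort (seed %d): %s\n", x$seed,
              paste(sprintf("%s n=%d", names(x$config$groups),
                            x$config$groups), collapse = ", ")))
  invisible(x)
}
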