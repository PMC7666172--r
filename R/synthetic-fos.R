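# Synthetic fluorescence images with planted spots.
#
# Background is a flat base plus a smooth linear illumination gradient and
# Gaussian pixel noise; spots are hard disks of configured diameter (um)
# with amplitude `contrast * noise_sd`, placed without overlap and away from
# the frame border. Planted centers and diameters are returned as ground
# truth. The stress preset multiplies the planted spot count in the
# designated activated regions.

#' Generate a synthetic fluorescence image with planted spots
#'
#' @param cfg A [cohort_config()] (its `imaging` block is used).
#' @param n_spots Number of in-range disks to plant.
#' @param n_small,n_large Additional disks planted below / above the 9-30 um
#'   retention range (excluded by the size filter when detection works).
#' @param small_diameter_um,large_diameter_um Diameters for the out-of-range
#'   disks (defaults 6 and 36 um).
#' @param region,hemisphere Labels carried on the image.
#' @return List: `image` ([fluor_image()]) and `truth` (tibble of planted
#'   `x_px`, `y_px`, `diameter_um`, `in_range`).
#' @export
gen_fos_image <- function(cfg, n_spots, n_small = 0L, n_large = 0L,
                          small_diameter_um = 6, large_diameter_um = 36,
                          region = NA_character_,
                          hemisphere = NA_character_) {
  im <- cfg$imaging
  px <- im$img_px
  diam <- c(stats::runif(n_spots, im$spot_diameter_um[1],
                         im$spot_diameter_um[2]),
            rep(small_diameter_um, n_small), rep(large_diameter_um, n_large))
  in_range <- c(rep(TRUE, n_spots), rep(FALSE, n_small + n_large))
  radius_px <- diam / 2 / im$um_per_px
  n_all <- length(diam)

  # rejection-sample non-overlapping centers away from the border
  xs <- ys <- numeric(n_all)
  margin <- im$margin_px
  for (i in seq_len(n_all)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      cx <- stats::runif(1L, margin + radius_px[i], px - margin - radius_px[i])
      cy <- stats::runif(1L, margin + radius_px[i], px - margin - radius_px[i])
      if (i == 1L || all(sqrt((cx - xs[seq_len(i - 1L)])^2 +
                                (cy - ys[seq_len(i - 1L)])^2) >
                           radius_px[i] + radius_px[seq_len(i - 1L)] +
                             im$min_gap_px)) {
        ok <- TRUE; break
      }
    }
    abort_if(!ok, "cannot place requested spots without overlap")
    xs[i] <- cx; ys[i] <- cy
  }

  gx <- matrix(rep(seq_len(px), px), px)       # row coordinate
  gy <- t(gx)
  grad <- im$gradient * (gx + gy) / (2 * px)
  img <- im$background + grad +
    matrix(stats::rnorm(px * px, 0, im$noise_sd), px)
  amp <- im$contrast * im$noise_sd
  for (i in seq_len(n_all)) {
    sel <- (gx - xs[i])^2 + (gy - ys[i])^2 <= radius_px[i]^2
    img[sel] <- img[sel] + amp
  }
  img <- pmax(img, 0)
  list(image = fluor_image(img, um_per_px = im$um_per_px, region = region,
                           hemisphere = hemisphere),
       truth = tibble::tibble(x_px = xs, y_px = ys, diameter_um = diam,
                              in_range = in_range))
}

#' Generate a two-group regional c-Fos imaging dataset
#'
#' Plants, for every mouse x region x hemisphere, a spot count drawn around
#' the region's base rate, multiplied by the stress multiplier in the
#' activated regions for stressed mice.
#'
#' @param cfg A [cohort_config()].
#' @return List: `images` (list of [gen_fos_image()] results), `manifest`
#'   (tibble with `mouse_id`, `group`, `region`, `hemisphere`,
#'   `n_planted`).
#' @export
gen_fos_cohort <- function(cfg) {
  im <- cfg$imaging
  manifest <- tidyr::expand_grid(
    group = c("control", "stress"),
    mouse = seq_len(im$n_per_group),
    region = names(im$regions),
    hemisphere = im$hemispheres
  ) |>
    dplyr::mutate(mouse_id = paste0("fos_", .data$group, "_", .data$mouse))
  mult <- function(group, region) {
    ifelse(group == "stress" & region %in% names(im$stress_multiplier),
           im$stress_multiplier[region], 1)
  }
  base <- im$regions[manifest$region]
  lambda <- base * mult(manifest$group, manifest$region)
  manifest$n_planted <- stats::rpois(nrow(manifest), lambda)
  images <- purrr::pmap(manifest[, c("region", "hemisphere", "n_planted")],
                        function(region, hemisphere, n_planted) {
                          gen_fos_image(cfg, n_planted, region = region,
                                        hemisphere = hemisphere)
                        })
  list(images = images,
       manifest = manifest[, c("mouse_id", "group", "region", "hemisphere",
                               "n_planted")])
}
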