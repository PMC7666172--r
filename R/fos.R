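# c-Fos imaging: count immunofluorescent nuclei by local-background
# thresholding and equivalent-diameter filtering, normalize by ROI area,
# and average hemispheres.
#
# Detection mirrors the published procedure: an object is a connected
# component brighter than a threshold determined by the adjacent background,
# retained when its equivalent circular diameter falls in 9-30 um. The local
# background is a running median (radius `bg_radius_um`); "brighter" means
# exceeding background + k_sigma times the robust spread (MAD) of the
# background residuals. Touching cells are not split (no watershed).

#' Construct a calibrated fluorescence image
#'
#' @param intensity Non-negative numeric matrix of pixel intensities.
#' @param um_per_px Microns per pixel (> 0).
#' @param roi Optional logical matrix (same shape) restricting analysis to a
#'   region of interest; default whole frame.
#' @param region,hemisphere Optional labels carried into counts.
#' @return Object of class `fluor_image`.
#' @export
fluor_image <- function(intensity, um_per_px, roi = NULL,
                        region = NA_character_, hemisphere = NA_character_) {
  intensity <- as.matrix(intensity)
  abort_if(any(!is.finite(intensity)) || any(intensity < 0),
           "intensities must be finite and non-negative")
  abort_if(!is_scalar_num(um_per_px) || um_per_px <= 0,
           "`um_per_px` must be positive")
  roi <- roi %||% matrix(TRUE, nrow(intensity), ncol(intensity))
  abort_if(!all(dim(roi) == dim(intensity)), "ROI shape must match the image")
  abort_if(!any(roi), "ROI is empty")
  structure(list(intensity = intensity, um_per_px = um_per_px, roi = roi,
                 region = region, hemisphere = hemisphere),
            class = "fluor_image")
}

#' Detect fluorescent spots with local-background thresholding
#'
#' Pixels are foreground when `intensity > background + k_sigma * spread`,
#' where the background is the median-filtered image (radius `bg_radius_um`)
#' and the spread is the median absolute deviation of the in-ROI residuals
#' (intensity minus background). 8-connected components become candidate
#' objects; objects are retained when their equivalent circular diameter
#' `2 * sqrt(area_um2 / pi)` lies within `diameter_range_um` and their
#' centroid falls inside the ROI.
#'
#' @param img A [fluor_image()].
#' @param k_sigma Threshold offset in robust-spread units (default 3).
#' @param bg_radius_um Median-filter radius in um (default 50).
#' @param diameter_range_um Retained equivalent-diameter range in um
#'   (default `c(9, 30)`).
#' @return List of class `spot_set`: `spots` (tibble with `x_px`, `y_px`,
#'   `area_px`, `equivalent_diameter_um`), `count`, `density_mm2`
#'   (count per mm^2 of ROI), `roi_area_mm2`, and the filter settings.
#' @export
detect_spots <- function(img, k_sigma = 3, bg_radius_um = 50,
                         diameter_range_um = c(9, 30)) {
  abort_if(!inherits(img, "fluor_image"), "`img` must be a fluor_image")
  x <- img$intensity
  # EBImage expects intensities in [0, 1]; rescale (detection is invariant
  # to affine intensity rescaling because the threshold is background-local)
  rng <- range(x)
  xs <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  radius_px <- max(1L, as.integer(round(bg_radius_um / img$um_per_px)))
  radius_px <- min(radius_px, as.integer(floor(min(dim(x)) / 2)) - 1L)
  bg <- EBImage::medianFilter(xs, radius_px)
  resid <- xs - bg
  spread <- stats::mad(resid[img$roi], center = 0)
  fg <- resid > k_sigma * spread
  fg[!img$roi] <- FALSE
  lab <- EBImage::bwlabel(fg)
  n_obj <- max(lab)
  px_area_um2 <- img$um_per_px^2
  if (n_obj > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n_obj)
    cx <- tapply(row(lab)[lab > 0], lab[lab > 0], mean)
    cy <- tapply(col(lab)[lab > 0], lab[lab > 0], mean)
    eq_d <- 2 * sqrt(areas * px_area_um2 / pi)
    keep <- eq_d >= diameter_range_um[1] & eq_d <= diameter_range_um[2]
    spots <- tibble::tibble(x_px = as.numeric(cx)[keep],
                            y_px = as.numeric(cy)[keep],
                            area_px = areas[keep],
                            equivalent_diameter_um = eq_d[keep])
  } else {
    spots <- tibble::tibble(x_px = numeric(), y_px = numeric(),
                            area_px = numeric(),
                            equivalent_diameter_um = numeric())
  }
  roi_area_mm2 <- sum(img$roi) * px_area_um2 / 1e6
  structure(
    list(spots = spots, count = nrow(spots),
         density_mm2 = nrow(spots) / roi_area_mm2,
         roi_area_mm2 = roi_area_mm2, k_sigma = k_sigma,
         bg_radius_um = bg_radius_um, diameter_range_um = diameter_range_um,
         region = img$region, hemisphere = img$hemisphere),
    class = "spot_set"
  )
}

#' Average hemisphere counts per region and mouse
#'
#' The per-mouse regional count is the arithmetic mean of the two
#' hemispheres; a mouse with a single hemisphere available passes through
#' with `single_hemisphere = TRUE`.
#'
#' @param counts Tibble with columns `mouse_id`, `region`, `hemisphere`,
#'   `count` and optionally `density_mm2`.
#' @return Tibble with one row per mouse x region: `mean_count`,
#'   `mean_density_mm2` (if densities supplied), `n_hemispheres`,
#'   `single_hemisphere`.
#' @export
hemisphere_average <- function(counts) {
  abort_if(nrow(counts) < 1L, "no hemisphere counts supplied")
  abort_if(any(table(counts$mouse_id, counts$region) > 2L),
           "more than two hemispheres for a mouse x region")
  counts |>
    dplyr::group_by(.data$mouse_id, .data$region) |>
    dplyr::summarise(
      mean_count = mean(.data$count),
      mean_density_mm2 = if ("density_mm2" %in% names(counts))
        mean(.data$density_mm2) else NA_real_,
      n_hemispheres = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(single_hemisphere = .data$n_hemispheres == 1L)
}

#' Compare regional counts between groups
#'
#' Unpaired two-sided t test per region between two groups, with no
#' multiplicity correction across regions (matching the source analysis,
#' where each region is reported with its own t test).
#'
#' @param region_counts Tibble with columns `mouse_id`, `region`, `group`
#'   and a value column (default `mean_density_mm2`).
#' @param value Name of the value column to compare.
#' @return Tibble with one row per region: group means and the t-test
#'   record columns.
#' @export
fos_compare_groups <- function(region_counts, value = "mean_density_mm2") {
  grps <- unique(region_counts$group)
  abort_if(length(grps) != 2L, "exactly two groups are compared")
  region_counts |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(function(d, key) {
      a <- d[[value]][d$group == grps[1L]]
      b <- d[[value]][d$group == grps[2L]]
      abort_if(length(a) < 2L || length(b) < 2L, "need >= 2 mice per group")
      res <- unpaired_t(a, b)
      tibble::tibble(mean_a = mean(a), mean_b = mean(b),
                     group_a = grps[1L], group_b = grps[2L],
                     statistic = res$statistic, p = res$p,
                     degenerate = res$degenerate)
    }) |>
    dplyr::ungroup()
}
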