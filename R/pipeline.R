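# Frame-level pipeline composition: segmentation -> counting -> zones.

#' Calibrate the day's single-bird reference area from synthetic profiles
#'
#' Renders single-bird scenes at the given day (same imaging conditions as
#' `config`) and measures each bird's area with the same segmentation
#' settings used for detection, mirroring the per-day manual selection of
#' single-bird profiles: the reference area must be measured by the same
#' instrument that measures the blobs it will normalise.
#'
#' @param config a [scene_config()]; its `day`, size, colours and noise are
#'   reused. The scenes are seeded from `config$seed`.
#' @param n_profiles number of single-bird profiles to sample.
#' @param ... segmentation overrides passed to [segment_frame()]
#'   (`erosion_radius`, `min_area`, `levels`, ...).
#' @return a [estimate_reference_area()] result for `config$day`.
#' @export
calibrate_reference_area <- function(config, n_profiles = 25, ...) {
  areas <- numeric(0)
  for (i in seq_len(n_profiles)) {
    cfg <- config
    cfg$n_birds <- 1
    cfg$crowding_fraction <- 0
    cfg$wing_spread_prob <- 0
    cfg$occluders <- list()
    cfg$seed <- config$seed + 7000L + i
    sc <- generate_scene(cfg)
    seg <- segment_frame(sc$frame, geom = cfg$geom, ...)
    if (length(seg$regions) == 1) {
      areas <- c(areas, seg$regions[[1]]$area)
    }
  }
  estimate_reference_area(areas, day = config$day)
}

#' Detect and count birds per zone in one frame
#'
#' Runs [segment_frame()], converts each region's area to a bird count
#' ([count_region()]; BP model when given, direct normalisation rule
#' otherwise), assigns each region to its majority zone and sums counts
#' into a per-frame distribution.
#'
#' @param image a [frame_image()].
#' @param geom a [zone_geometry()].
#' @param ref a [estimate_reference_area()] result for the frame's day.
#' @param model optional trained `bp_model`.
#' @param ... segmentation overrides passed to [segment_frame()].
#' @return list with `segmentation`, `counts` (per region), `labels`
#'   (per-region zone) and `zone_counts` (a [frame_distribution()] row).
#' @export
detect_frame <- function(image, geom, ref, model = NULL, ...) {
  seg <- segment_frame(image, geom = geom, ...)
  counts <- vapply(seg$regions, count_region, integer(1), ref = ref,
                   model = model)
  labels <- vapply(seg$regions, assign_zone, character(1), geom = geom)
  zc <- frame_distribution(seg$regions, counts, geom,
                           frame_id = image$frame_id, labels = labels)
  list(segmentation = seg, counts = counts, labels = labels,
       zone_counts = zc)
}
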