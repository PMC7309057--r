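#' Define the pen's floor-zone geometry
#'
#' A pen floor is divided into three zones for distribution analysis: a
#' drinking zone (an axis-aligned rectangle centred on the nipple-drinker
#' water line, whose width is one body length of a three-week-old broiler),
#' a feeding zone (a disc around the tube feeder, radius = feeder radius
#' plus one body length), and the rest/exercise zone (everything else inside
#' the overall detection rectangle). The geometry is fixed across rearing
#' days at the three-week-old body length.
#'
#' All coordinates are 0-based pixel coordinates with the origin at the
#' top-left corner, x rightward and y downward. Rectangles are
#' `c(xmin, ymin, xmax, ymax)` with inclusive bounds.
#'
#' @param pen_rect numeric(4) overall detection rectangle.
#' @param drinking_rect numeric(4) drinking-zone rectangle; must lie inside
#'   `pen_rect` and not intersect the feeding disc.
#' @param feeding_disc numeric(3) `c(cx, cy, radius)` feeding-zone disc;
#'   must lie inside `pen_rect`.
#' @param body_length_px calibration length in pixels (body length of a
#'   three-week-old broiler at the camera's working distance).
#' @return an object of class `zone_geometry`.
#' @seealso [assign_zone()], [load_zone_config()], [default_zone_geometry()]
#' @export
zone_geometry <- function(pen_rect, drinking_rect, feeding_disc, body_length_px) {
  pen_rect <- as.numeric(pen_rect)
  drinking_rect <- as.numeric(drinking_rect)
  feeding_disc <- as.numeric(feeding_disc)
  stopifnot(length(pen_rect) == 4, length(drinking_rect) == 4,
            length(feeding_disc) == 3, length(body_length_px) == 1)
  if (pen_rect[3] <= pen_rect[1] || pen_rect[4] <= pen_rect[2]) {
    stop("pen_rect is degenerate (zero area)")
  }
  if (body_length_px <= 0) stop("body_length_px must be positive")
  rect_in_rect <- function(inner, outer) {
    inner[1] >= outer[1] && inner[2] >= outer[2] &&
      inner[3] <= outer[3] && inner[4] <= outer[4]
  }
  if (!rect_in_rect(drinking_rect, pen_rect)) {
    stop("drinking_rect lies outside pen_rect")
  }
  cx <- feeding_disc[1]; cy <- feeding_disc[2]; r <- feeding_disc[3]
  if (r <= 0) stop("feeding_disc radius must be positive")
  if (cx - r < pen_rect[1] || cx + r > pen_rect[3] ||
      cy - r < pen_rect[2] || cy + r > pen_rect[4]) {
    stop("feeding_disc lies outside pen_rect")
  }
  # rectangle/disc intersection test: distance from disc centre to the
  # closest point of the rectangle
  px <- clamp(cx, drinking_rect[1], drinking_rect[3])
  py <- clamp(cy, drinking_rect[2], drinking_rect[4])
  if ((px - cx)^2 + (py - cy)^2 <= r^2) {
    stop("drinking_rect and feeding_disc overlap; zones must be disjoint")
  }
  structure(
    list(pen_rect = pen_rect, drinking_rect = drinking_rect,
         feeding_disc = feeding_disc, body_length_px = body_length_px),
    class = "zone_geometry"
  )
}

#' @export
print.zone_geometry <- function(x, ...) {
  cat("Zone geometry (pixel coordinates, origin top-left)\n")
  cat(sprintf("  pen rectangle:      [%g, %g] x [%g, %g]\n",
              x$pen_rect[1], x$pen_rect[3], x$pen_rect[2], x$pen_rect[4]))
  cat(sprintf("  drinking rectangle: [%g, %g] x [%g, %g]\n",
              x$drinking_rect[1], x$drinking_rect[3],
              x$drinking_rect[2], x$drinking_rect[4]))
  cat(sprintf("  feeding disc:       centre (%g, %g), radius %g\n",
              x$feeding_disc[1], x$feeding_disc[2], x$feeding_disc[3]))
  cat(sprintf("  body length:        %g px\n", x$body_length_px))
  invisible(x)
}

#' Default zone geometry for a given frame size
#'
#' Places the water line along the top of the pen and the tube feeder in the
#' lower half, mimicking a typical research-pen layout: pen rectangle inset
#' 3% from the frame edges, drinking rectangle spanning the pen width with
#' width (in y) equal to one body length, feeding disc of radius
#' 0.75 + 1 body lengths around a centre at 65% of pen height.
#'
#' @param width,height frame size in pixels.
#' @param body_length_px calibration body length; default scales with the
#'   frame so that a three-week-old bird keeps its proportions.
#' @return a [zone_geometry()].
#' @export
default_zone_geometry <- function(width, height, body_length_px = NULL) {
  if (is.null(body_length_px)) {
    # consistent with the default growth model in scene_config()
    a21 <- default_bird_area(21, width, height)
    body_length_px <- round(2 * sqrt(1.6 * a21 / pi))
  }
  mx <- round(0.03 * width)
  my <- round(0.03 * height)
  pen <- c(mx, my, width - 1 - mx, height - 1 - my)
  half <- floor(body_length_px / 2)
  line_y <- pen[2] + half + 2
  drink <- c(pen[1], line_y - half, pen[3], line_y + half)
  feeder_r <- round(0.75 * body_length_px)
  disc <- c(round((pen[1] + pen[3]) / 2),
            round(pen[2] + 0.65 * (pen[4] - pen[2])),
            feeder_r + body_length_px)
  zone_geometry(pen, drink, disc, body_length_px)
}

#' Read a zone-geometry configuration from YAML or JSON
#'
#' The document must contain `pen_rect` (4 numbers), `drinking_rect`
#' (4 numbers), `feeding_disc` (3 numbers: cx, cy, radius) and
#' `body_length_px`. Validation errors name the violated constraint.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated [zone_geometry()].
#' @export
load_zone_config <- function(path) {
  if (!file.exists(path)) stop("zone config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("pen_rect", "drinking_rect", "feeding_disc", "body_length_px")
  miss <- setdiff(need, names(doc))
  if (length(miss) > 0) {
    stop("zone config missing fields: ", paste(miss, collapse = ", "))
  }
  zone_geometry(doc$pen_rect, doc$drinking_rect, doc$feeding_disc,
                doc$body_length_px)
}

#' Write a zone geometry to YAML or JSON
#' @param geom a [zone_geometry()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_zone_config <- function(geom, path) {
  doc <- list(pen_rect = geom$pen_rect, drinking_rect = geom$drinking_rect,
              feeding_disc = geom$feeding_disc,
              body_length_px = geom$body_length_px)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

# Fractions of a pixel set lying in the drinking rectangle and the feeding
# disc. x, y are 0-based pixel coordinates.
zone_fractions <- function(x, y, geom) {
  n <- length(x)
  if (n == 0L) {
    return(c(drinking = 0, feeding = 0))
  }
  dr <- geom$drinking_rect
  in_drink <- x >= dr[1] & x <= dr[3] & y >= dr[2] & y <= dr[4]
  fd <- geom$feeding_disc
  in_feed <- (x - fd[1])^2 + (y - fd[2])^2 <= fd[3]^2
  c(drinking = sum(in_drink) / n, feeding = sum(in_feed) / n)
}

#' Assign a segmented region to a floor zone
#'
#' A region is assigned to the drinking or feeding zone when strictly more
#' than 50% of its pixels lie inside that zone's geometry; otherwise it
#' belongs to the rest/exercise zone. An exact 50% overlap therefore goes to
#' rest. Because the drinking and feeding zones are validated to be
#' disjoint, at most one of the two fractions can exceed one half.
#'
#' @param region a `region` (see [extract_regions()]) or any list with
#'   0-based pixel coordinate vectors `x` and `y`.
#' @param geom a [zone_geometry()].
#' @return one of `"drinking"`, `"feeding"`, `"rest"`.
#' @export
assign_zone <- function(region, geom) {
  f <- zone_fractions(region$x, region$y, geom)
  if (f[["drinking"]] > 0.5) {
    "drinking"
  } else if (f[["feeding"]] > 0.5) {
    "feeding"
  } else {
    "rest"
  }
}

#' Per-frame zone occupancy counts
#'
#' Sums per-region bird counts into drinking/feeding totals over the regions
#' labelled for each zone; the rest-zone count is the remainder
#' `total - drinking - feeding`. A multi-bird region contributes its whole
#' count to its single majority zone. If counting overshoot would make the
#' rest count negative it is clamped to zero and the overshoot recorded in
#' the `warning` field.
#'
#' @param regions list of regions (may be empty).
#' @param counts integer vector of per-region bird counts, aligned with
#'   `regions`.
#' @param geom a [zone_geometry()].
#' @param frame_id identifier copied into the result.
#' @param labels optional precomputed zone labels (as from [assign_zone()]);
#'   computed when `NULL`.
#' @return an object of class `zone_counts`: a one-row data.frame with
#'   columns `frame_id`, `drinking`, `feeding`, `rest`, `total`, `warning`.
#' @export
#' @examples
#' # no regions at all
#' frame_distribution(list(), integer(0), default_zone_geometry(96, 72), "f0")
frame_distribution <- function(regions, counts, geom, frame_id = NA_character_,
                               labels = NULL) {
  if (length(regions) != length(counts)) {
    stop("counts must be aligned with regions")
  }
  counts <- as.integer(counts)
  if (is.null(labels)) {
    labels <- vapply(regions, assign_zone, character(1), geom = geom)
  }
  total <- sum(counts)
  d_num <- sum(counts[labels == "drinking"])
  f_num <- sum(counts[labels == "feeding"])
  rest <- total - d_num - f_num
  warning_rec <- NA_character_
  if (rest < 0) {
    warning_rec <- sprintf("rest count %d clamped to 0", rest)
    rest <- 0L
  }
  out <- data.frame(frame_id = frame_id, drinking = d_num, feeding = f_num,
                    rest = rest, total = total, warning = warning_rec,
                    stringsAsFactors = FALSE)
  class(out) <- c("zone_counts", class(out))
  out
}
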