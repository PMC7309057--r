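#' Construct a top-view frame image
#'
#' A frame is an 8-bit three-channel image (H x W x 3 integer array, RGB
#' order, values 0–255) together with the acquisition day (bird age) and a
#' frame identifier. The `roi` attribute marks pixels that take part in
#' histogramming; [remove_nontarget()] clears it outside the pen.
#'
#' @param pixels H x W x 3 numeric/integer array with values in `[0, 255]`.
#' @param day integer bird age in days.
#' @param frame_id identifier string.
#' @param roi optional H x W logical region-of-interest matrix; default all
#'   `TRUE`.
#' @return an object of class `frame_image` with fields `pixels`, `day`,
#'   `frame_id`, `roi`.
#' @export
frame_image <- function(pixels, day = NA_integer_, frame_id = "frame",
                        roi = NULL) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) stop("pixels must be an H x W x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  if (is.null(roi)) roi <- matrix(TRUE, d[1], d[2])
  structure(list(pixels = pixels, day = as.integer(day),
                 frame_id = frame_id, roi = roi),
            class = "frame_image")
}

#' @export
print.frame_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("frame_image '%s': %d x %d px, day %s, %d roi pixels\n",
              x$frame_id, d[2], d[1],
              ifelse(is.na(x$day), "?", x$day), sum(x$roi)))
  invisible(x)
}

#' Read an 8-bit RGB PNG as a frame image
#'
#' @param path path to a PNG file.
#' @param day bird age in days (used for per-day reference areas).
#' @param frame_id identifier; default the file stem.
#' @return a [frame_image()].
#' @export
read_frame <- function(path, day = NA_integer_, frame_id = NULL) {
  if (is.null(frame_id)) frame_id <- tools::file_path_sans_ext(basename(path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  frame_image(round(a * 255), day = day, frame_id = frame_id)
}

#' Write a frame image to PNG
#' @param frame a [frame_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  png::writePNG(frame$pixels / 255, path)
  invisible(path)
}

#' Write a binary mask to PNG (background 0, foreground 255)
#' @param mask a `binary_mask` (see [apply_threshold()]) or logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Tabulate segmented regions as a data.frame
#'
#' One row per region: frame id, region id, pixel area, centroid and
#' bounding box (0-based pixel coordinates). The shape written by the
#' detection pipeline's region CSV.
#'
#' @param regions list of regions from [extract_regions()].
#' @param frame_id identifier recycled across rows.
#' @return data.frame with columns `frame_id`, `region_id`, `area`,
#'   `centroid_x`, `centroid_y`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
regions_to_df <- function(regions, frame_id = NA_character_) {
  if (length(regions) == 0) {
    return(data.frame(frame_id = character(0), region_id = integer(0),
                      area = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), xmin = integer(0),
                      ymin = integer(0), xmax = integer(0),
                      ymax = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(regions, function(r) {
    data.frame(frame_id = frame_id, region_id = r$region_id, area = r$area,
               centroid_x = r$centroid[1], centroid_y = r$centroid[2],
               xmin = r$bbox[1], ymin = r$bbox[2], xmax = r$bbox[3],
               ymax = r$bbox[4], stringsAsFactors = FALSE)
  }))
}
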