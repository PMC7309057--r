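# Target (bird) detection: channel-pair classification + two-dimensional
# Otsu thresholding + morphological cleanup + connected regions.

#' Choose the channel pair for two-dimensional thresholding
#'
#' The default pipeline thresholds the joint (green, blue) histogram: on
#' brown litter the green and blue channels separate white birds from
#' background best among the RGB pairs. Mode `"value_vs_neighborhood"`
#' gives the classical two-dimensional Otsu feature instead: a channel's
#' value against its 3x3 neighbourhood mean, which is robust to isolated
#' pixel noise.
#'
#' @param first,second channel names among `"R"`, `"G"`, `"B"`. `second` is
#'   ignored (and may equal `first`) in `value_vs_neighborhood` mode.
#' @param mode `"joint"` or `"value_vs_neighborhood"`.
#' @return an object of class `channel_pair`.
#' @export
channel_pair <- function(first = "G", second = "B",
                         mode = c("joint", "value_vs_neighborhood")) {
  mode <- match.arg(mode)
  ok <- c("R", "G", "B")
  stopifnot(first %in% ok, second %in% ok)
  if (mode == "joint" && first == second) {
    stop("joint mode needs two distinct channels")
  }
  structure(list(first = first, second = second, mode = mode),
            class = "channel_pair")
}

#' Blank out everything outside the pen's detection rectangle
#'
#' Pixels outside the overall detection area are set to a background
#' sentinel colour (black) and removed from the region of interest, so they
#' are excluded from all downstream histograms and masks.
#'
#' @param image a [frame_image()].
#' @param pen a [zone_geometry()] or a numeric(4) rectangle
#'   `c(xmin, ymin, xmax, ymax)` in 0-based pixel coordinates.
#' @return a [frame_image()] with updated `pixels` and `roi`.
#' @export
remove_nontarget <- function(image, pen) {
  rect <- if (inherits(pen, "zone_geometry")) pen$pen_rect else as.numeric(pen)
  stopifnot(length(rect) == 4)
  if (rect[3] <= rect[1] || rect[4] <= rect[2]) {
    stop("pen rectangle is degenerate (zero area)")
  }
  d <- dim(image$pixels)
  if (rect[1] < 0 || rect[2] < 0 || rect[3] > d[2] - 1 || rect[4] > d[1] - 1) {
    stop("pen rectangle exceeds image bounds")
  }
  xs <- rep(0:(d[2] - 1), each = d[1])
  ys <- rep(0:(d[1] - 1), times = d[2])
  inside <- matrix(xs >= rect[1] & xs <= rect[3] &
                     ys >= rect[2] & ys <= rect[4], d[1], d[2])
  px <- image$pixels
  for (c3 in 1:3) {
    plane <- px[, , c3]
    plane[!inside] <- 0L
    px[, , c3] <- plane
  }
  frame_image(px, day = image$day, frame_id = image$frame_id,
              roi = image$roi & inside)
}

# channel plane by name
channel_plane <- function(image, name) {
  image$pixels[, , match(name, c("R", "G", "B"))]
}

# 3x3 neighbourhood mean of a matrix, restricted to roi pixels (neighbours
# outside the roi or the image do not contribute).
neighborhood_mean <- function(m, roi) {
  H <- nrow(m)
  W <- ncol(m)
  s <- matrix(0, H, W)
  n <- matrix(0, H, W)
  mm <- m
  mm[!roi] <- 0
  for (dy in -1:1) {
    for (dx in -1:1) {
      ys <- max(1, 1 - dy):min(H, H - dy)
      xs <- max(1, 1 - dx):min(W, W - dx)
      s[ys, xs] <- s[ys, xs] + mm[ys + dy, xs + dx]
      n[ys, xs] <- n[ys, xs] + roi[ys + dy, xs + dx]
    }
  }
  out <- s / pmax(n, 1)
  out[!roi] <- 0
  out
}

# Quantize 8-bit values to L levels (0 .. L-1).
quantize_levels <- function(v, levels) {
  pmin((as.numeric(v) * levels) %/% 256, levels - 1)
}

# The two quantized feature planes for a frame under a channel pair.
feature_planes <- function(image, pair, levels) {
  f1 <- channel_plane(image, pair$first)
  f2 <- if (pair$mode == "joint") {
    channel_plane(image, pair$second)
  } else {
    neighborhood_mean(f1, image$roi)
  }
  list(q1 = matrix(quantize_levels(f1, levels), nrow(image$roi)),
       q2 = matrix(quantize_levels(f2, levels), nrow(image$roi)))
}

#' Build the two-dimensional feature histogram of a frame
#'
#' For `mode = "joint"`, bin `(i, j)` counts region-of-interest pixels whose
#' quantized first-channel value is `i` and second-channel value is `j`
#' (0-based levels). For `mode = "value_vs_neighborhood"`, `j` indexes the
#' quantized 3x3 neighbourhood mean of the first channel.
#'
#' @param image a [frame_image()] (after [remove_nontarget()] if a pen is
#'   configured).
#' @param pair a [channel_pair()].
#' @param levels number of gray levels, in `[2, 256]`; 256 preserves the
#'   8-bit resolution, small values make exhaustive threshold search cheap.
#' @return an object of class `joint_histogram`: `bins` (L x L counts),
#'   `levels`, `pair`, `n` (pixels histogrammed).
#' @export
build_joint_histogram <- function(image, pair = channel_pair(), levels = 256) {
  stopifnot(levels >= 2, levels <= 256)
  keep <- which(image$roi)
  if (length(keep) == 0) stop("no pixels left after nontarget removal")
  fp <- feature_planes(image, pair, levels)
  q1 <- fp$q1[keep]
  q2 <- fp$q2[keep]
  bins <- matrix(0, levels, levels)
  tab <- table(factor(q1, levels = 0:(levels - 1)),
               factor(q2, levels = 0:(levels - 1)))
  bins[] <- as.numeric(tab)
  structure(list(bins = bins, levels = levels, pair = pair,
                 n = length(keep)),
            class = "joint_histogram")
}

#' Two-dimensional Otsu threshold selection
#'
#' Finds the threshold pair `(t1, t2)` (0-based levels) maximizing the
#' two-dimensional between-class variance: the two classes are the
#' histogram quadrants at and below / strictly above the pair, and the
#' objective is the trace of the between-class scatter of the two class
#' mean vectors about the global mean,
#' `w0 * ||mu0 - muT||^2 + w1 * ||mu1 - muT||^2`. Mass in the two
#' off-diagonal quadrants (typically edge pixels) contributes to the global
#' mean but to neither class, as in the classical formulation. Ties are
#' broken by the smallest `t1`, then smallest `t2`.
#'
#' @param hist a [build_joint_histogram()] result.
#' @return list with `t` (integer threshold pair), `objective`, and
#'   `degenerate` (`TRUE` when all mass sits in a single bin, in which case
#'   that bin's level pair is returned with objective 0).
#' @export
otsu_2d <- function(hist) {
  B <- hist$bins
  L <- hist$levels
  N <- sum(B)
  if (N <= 0) stop("empty histogram")
  nz <- which(B > 0)
  if (length(nz) == 1) {
    rc <- arrayInd(nz, dim(B))
    return(list(t = c(rc[1] - 1L, rc[2] - 1L), objective = 0,
                degenerate = TRUE))
  }
  P <- B / N
  I <- row(B) - 1
  J <- col(B) - 1
  cum2 <- function(M) t(apply(apply(M, 2, cumsum), 1, cumsum))
  W0 <- cum2(P)
  Mi0 <- cum2(I * P)
  Mj0 <- cum2(J * P)
  miT <- sum(I * P)
  mjT <- sum(J * P)
  rowAll <- function(C) matrix(C[, L], L, L)
  colAll <- function(C) matrix(C[L, ], L, L, byrow = TRUE)
  W1 <- 1 - rowAll(W0) - colAll(W0) + W0
  Mi1 <- miT - rowAll(Mi0) - colAll(Mi0) + Mi0
  Mj1 <- mjT - rowAll(Mj0) - colAll(Mj0) + Mj0
  term <- function(w, mi, mj) {
    v <- ((mi - w * miT)^2 + (mj - w * mjT)^2)
    out <- ifelse(w > 1e-12, v / pmax(w, 1e-12), 0)
    out
  }
  obj <- term(W0, Mi0, Mj0) + term(W1, Mi1, Mj1)
  best <- max(obj)
  # threshold pairs inducing the same partition have mathematically equal
  # objectives that can differ by rounding; treat near-equal as tied and
  # take the lexicographically smallest pair
  cand <- which(obj >= best - 1e-9 * max(best, 1e-12), arr.ind = TRUE)
  ord <- order(cand[, 1], cand[, 2])
  pick <- cand[ord[1], ]
  list(t = c(as.integer(pick[1] - 1), as.integer(pick[2] - 1)),
       objective = best, degenerate = FALSE)
}

#' Binarize a frame at a two-dimensional threshold pair
#'
#' A pixel is a foreground candidate when its quantized feature pair lies in
#' one of the two diagonal quadrants at `(t1, t2)`: both values strictly
#' above (the `"upper"` quadrant) or both at/below (`"lower"`). With
#' `polarity = "auto"` the foreground quadrant is chosen as the class whose
#' mean colour lies farther from the median pen colour, preferring the
#' smaller class on a tie — birds are the minority class and differ most
#' from the litter-dominated median, whether they are the bright or the
#' dark class.
#'
#' @param image a [frame_image()].
#' @param pair a [channel_pair()].
#' @param thresholds integer pair `(t1, t2)` from [otsu_2d()].
#' @param levels gray levels used when quantizing (must match the
#'   histogram's).
#' @param polarity `"auto"`, `"upper"` or `"lower"`.
#' @param min_contrast minimum Euclidean RGB distance between the
#'   foreground and background class mean colours; below it the frame is
#'   treated as containing no birds and the mask comes back empty. This
#'   stops the threshold from splitting the litter noise in half on a
#'   birdless pen. Set to 0 to disable.
#' @return an object of class `binary_mask`: `mask` (H x W logical) plus a
#'   `provenance` record of thresholds, pair, levels and chosen polarity.
#' @export
apply_threshold <- function(image, pair, thresholds, levels = 256,
                            polarity = c("auto", "upper", "lower"),
                            min_contrast = 30) {
  polarity <- match.arg(polarity)
  t1 <- thresholds[1]
  t2 <- thresholds[2]
  stopifnot(t1 >= 0, t2 >= 0, t1 <= levels - 1, t2 <= levels - 1)
  fp <- feature_planes(image, pair, levels)
  upper <- fp$q1 > t1 & fp$q2 > t2 & image$roi
  lower <- fp$q1 <= t1 & fp$q2 <= t2 & image$roi
  if (polarity == "auto") {
    keep <- which(image$roi)
    med <- vapply(1:3, function(c3) {
      stats::median(image$pixels[, , c3][keep])
    }, numeric(1))
    dist_to_med <- function(m) {
      idx <- which(m)
      if (length(idx) == 0) {
        return(-Inf)
      }
      mu <- vapply(1:3, function(c3) mean(image$pixels[, , c3][idx]),
                   numeric(1))
      sqrt(sum((mu - med)^2))
    }
    du <- dist_to_med(upper)
    dl <- dist_to_med(lower)
    polarity <- if (du > dl) {
      "upper"
    } else if (dl > du) {
      "lower"
    } else if (sum(upper) <= sum(lower)) "upper" else "lower"
  }
  mask <- if (polarity == "upper") upper else lower
  low_contrast <- FALSE
  if (min_contrast > 0) {
    mean_color <- function(m) {
      idx <- which(m)
      if (length(idx) == 0) {
        return(NULL)
      }
      vapply(1:3, function(c3) mean(image$pixels[, , c3][idx]), numeric(1))
    }
    mu_fg <- mean_color(mask)
    mu_bg <- mean_color(image$roi & !mask)
    if (is.null(mu_fg) || is.null(mu_bg) ||
        sqrt(sum((mu_fg - mu_bg)^2)) < min_contrast) {
      mask[] <- FALSE
      low_contrast <- TRUE
    }
  }
  structure(
    list(mask = mask,
         provenance = list(thresholds = c(t1, t2), levels = levels,
                           pair = pair, polarity = polarity,
                           min_contrast = min_contrast,
                           low_contrast = low_contrast)),
    class = "binary_mask"
  )
}

#' Morphological corrosion and small-component removal
#'
#' Erodes the mask with a Euclidean disc structuring element (the offsets
#' within `erosion_radius` of the centre; radius 1 is the 4-neighbour
#' cross), then removes 8-connected components smaller than `min_area`
#' pixels. Radius 0 and `min_area` 0 leave the mask unchanged.
#'
#' @param mask a `binary_mask` from [apply_threshold()] or a logical matrix.
#' @param erosion_radius disc radius in pixels (>= 0).
#' @param min_area minimum surviving component area in pixels (>= 0).
#' @return a `binary_mask` with updated provenance.
#' @export
morphological_cleanup <- function(mask, erosion_radius = 1, min_area = 30) {
  stopifnot(erosion_radius >= 0, min_area >= 0)
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  prov <- if (inherits(mask, "binary_mask")) mask$provenance else list()
  m <- erode_disc(m, erosion_radius)
  if (min_area > 0 && any(m)) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_area)
    if (length(small) > 0) m[lab %in% small] <- FALSE
  }
  prov$erosion_radius <- erosion_radius
  prov$min_area <- min_area
  structure(list(mask = m, provenance = prov), class = "binary_mask")
}

#' Extract connected foreground regions
#'
#' 8-connected components of the mask, returned in a deterministic order
#' (by bounding-box `ymin`, then `xmin`). Pixel coordinates are 0-based.
#'
#' @param mask a `binary_mask` or logical matrix.
#' @return list of `region` objects: `region_id`, `x`, `y` (pixel
#'   coordinates), `area`, `centroid` `(x, y)`, `bbox`
#'   `(xmin, ymin, xmax, ymax)`.
#' @export
extract_regions <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  lab <- label_components(m)
  n <- max(lab)
  if (n == 0L) {
    return(list())
  }
  idx <- which(lab > 0L)
  H <- nrow(m)
  comp <- lab[idx]
  x <- (idx - 1L) %/% H
  y <- (idx - 1L) %% H
  regions <- lapply(seq_len(n), function(k) {
    sel <- comp == k
    xs <- x[sel]
    ys <- y[sel]
    list(region_id = k, x = xs, y = ys, area = length(xs),
         centroid = c(mean(xs), mean(ys)),
         bbox = c(min(xs), min(ys), max(xs), max(ys)))
  })
  ord <- order(vapply(regions, function(r) r$bbox[2], numeric(1)),
               vapply(regions, function(r) r$bbox[1], numeric(1)))
  regions <- regions[ord]
  for (k in seq_along(regions)) {
    regions[[k]]$region_id <- k
    class(regions[[k]]) <- "region"
  }
  regions
}

#' Default minimum region area for a frame size
#'
#' 30 pixels at the 1440 x 1080 capture resolution, scaled with image area
#' (at least 1).
#' @param width,height frame size in pixels.
#' @return integer pixel count.
#' @export
default_min_area <- function(width, height) {
  max(1L, as.integer(round(30 * (width * height) / (1440 * 1080))))
}

#' Run the full segmentation pipeline on one frame
#'
#' Nontarget-area removal (when a geometry is supplied), two-dimensional
#' feature histogram, Otsu threshold selection, binarization with automatic
#' polarity, morphological cleanup and region extraction.
#'
#' @param image a [frame_image()].
#' @param geom optional [zone_geometry()]; its pen rectangle defines the
#'   detection area.
#' @param pair a [channel_pair()].
#' @param levels gray levels for the histogram/threshold search.
#' @param erosion_radius,min_area cleanup parameters; `min_area = NULL`
#'   uses [default_min_area()] for the frame size.
#' @param polarity,min_contrast passed to [apply_threshold()].
#' @return an object of class `segmentation`: `mask` (cleaned
#'   `binary_mask`), `regions`, `thresholds`, `objective`, `frame_id`.
#' @export
segment_frame <- function(image, geom = NULL, pair = channel_pair(),
                          levels = 256, erosion_radius = 1, min_area = NULL,
                          polarity = "auto", min_contrast = 30) {
  if (!is.null(geom)) image <- remove_nontarget(image, geom)
  if (is.null(min_area)) {
    d <- dim(image$pixels)
    min_area <- default_min_area(d[2], d[1])
  }
  hist <- build_joint_histogram(image, pair, levels)
  th <- otsu_2d(hist)
  raw <- apply_threshold(image, pair, th$t, levels, polarity = polarity,
                         min_contrast = min_contrast)
  cleaned <- morphological_cleanup(raw, erosion_radius, min_area)
  structure(
    list(mask = cleaned, regions = extract_regions(cleaned),
         thresholds = th$t, objective = th$objective,
         degenerate = th$degenerate, frame_id = image$frame_id),
    class = "segmentation"
  )
}
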