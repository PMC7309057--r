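# Synthetic top-view pen scenes with exact ground truth.
#
# The generator emulates what the pipeline's field imagery looks like from a
# ceiling camera: light elliptical bird silhouettes on darker litter, birds
# growing day by day, optional equipment occluders (feeder hanging chain,
# water line) drawn over the birds, optional touching "crowding" clusters,
# and optional wing-spread area inflation. Every bird's pixel set, zone
# label and occluded fraction are known exactly, so segmentation, counting
# and zonal assignment can be verified pixel-for-pixel.

#' Expected single-bird silhouette area for a given age
#'
#' Linear growth between the day-18 and day-35 anchor areas, scaled with
#' image area relative to the 480 x 360 reference frame (600 and 1500
#' pixels at that frame size). Ages outside the anchor range extrapolate
#' linearly.
#'
#' @param day age in days.
#' @param width,height frame size in pixels.
#' @param area_d18,area_d35 optional anchor overrides in pixels.
#' @return expected silhouette area in pixels.
#' @export
default_bird_area <- function(day, width, height,
                              area_d18 = NULL, area_d35 = NULL) {
  scale <- (width * height) / (480 * 360)
  if (is.null(area_d18)) area_d18 <- 600 * scale
  if (is.null(area_d35)) area_d35 <- 1500 * scale
  area_d18 + (day - 18) / (35 - 18) * (area_d35 - area_d18)
}

#' Specify an equipment occluder
#'
#' Occluders model pen equipment seen from above — the feeder hanging chain
#' and the nipple-drinker water line — which are drawn over the birds and
#' can hide part or all of a bird from the camera.
#'
#' @param kind `"feeder_chain"` or `"water_line"`.
#' @param path two-column matrix of 0-based pixel coordinates (a polyline).
#' @param thickness stroke thickness in pixels (>= 1).
#' @param color integer(3) 8-bit RGB colour of the occluder.
#' @return an object of class `occluder_spec`.
#' @export
occluder_spec <- function(kind = c("feeder_chain", "water_line"),
                          path, thickness = 6, color = c(70, 70, 72)) {
  kind <- match.arg(kind)
  path <- matrix(as.numeric(path), ncol = 2)
  if (nrow(path) < 2) stop("occluder path needs at least two points")
  if (thickness < 1) stop("occluder thickness must be >= 1")
  structure(list(kind = kind, path = path, thickness = thickness,
                 color = as.numeric(color)),
            class = "occluder_spec")
}

#' Default equipment occluders for a zone geometry
#'
#' One horizontal water line along the centre of the drinking rectangle and
#' one feeder chain crossing the feeding disc.
#'
#' @param geom a [zone_geometry()].
#' @param thickness stroke thickness in pixels.
#' @return list of [occluder_spec()].
#' @export
default_occluders <- function(geom, thickness = 6) {
  dr <- geom$drinking_rect
  line_y <- (dr[2] + dr[4]) / 2
  fd <- geom$feeding_disc
  list(
    occluder_spec("water_line",
                  rbind(c(dr[1], line_y), c(dr[3], line_y)),
                  thickness = thickness),
    occluder_spec("feeder_chain",
                  rbind(c(fd[1] - fd[3], fd[2] - fd[3]),
                        c(fd[1] + fd[3], fd[2] + fd[3])),
                  thickness = thickness)
  )
}

#' Configure a synthetic pen scene
#'
#' Defaults reflect the monitored research pen: 19 birds per pen (21 reared,
#' two removed for sampling), ages 18–35 days, white-feathered birds on
#' brown pine-shaving litter. Bird silhouettes are filled ellipses with axis
#' ratio ~1.6 whose area grows linearly with age; individual areas get a
#' multiplicative jitter. Failure-mode knobs (occluders, crowding clusters,
#' wing spreading) are off by default and enabled explicitly when a study
#' condition calls for them.
#'
#' @param width,height frame size in pixels.
#' @param day bird age in days (nominal range 18–35; growth extrapolates
#'   linearly outside it).
#' @param n_birds number of birds to place (>= 0).
#' @param geom a [zone_geometry()]; default [default_zone_geometry()] for
#'   the frame size.
#' @param occluders list of [occluder_spec()]; default none.
#' @param crowding_fraction fraction of birds placed in touching clusters
#'   of 2–3, in `[0, 1]`.
#' @param wing_spread_prob probability that a bird's silhouette area is
#'   inflated by `wing_spread_factor`, in `[0, 1]`.
#' @param wing_spread_factor area inflation factor for wing-spread birds.
#' @param seed integer random seed; the same config and seed give a
#'   bit-identical image and ground truth.
#' @param bird_color_mean,litter_color_mean integer(3) 8-bit RGB means.
#' @param noise_sd per-pixel additive Gaussian noise sd on the 8-bit scale.
#' @param axis_ratio ellipse major/minor axis ratio.
#' @param area_d18,area_d35 single-bird silhouette areas (px) anchoring the
#'   growth line; defaults scale with frame area from 600/1500 at 480x360.
#' @param area_jitter_sd relative sd of per-bird area jitter.
#' @param pin_birds optional matrix/data.frame of `(cx, cy)` centres for
#'   the first birds, placed exactly there (used to construct targeted
#'   failure modes, e.g. a bird under an occluder).
#' @param max_place_tries rejection-sampling retry bound per bird.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(width = 480, height = 360, day = 21, n_birds = 19,
                         geom = NULL, occluders = list(),
                         crowding_fraction = 0, wing_spread_prob = 0,
                         wing_spread_factor = 1.5, seed = 1,
                         bird_color_mean = c(230, 228, 222),
                         litter_color_mean = c(120, 96, 70),
                         noise_sd = 8, axis_ratio = 1.6,
                         area_d18 = NULL, area_d35 = NULL,
                         area_jitter_sd = 0.08, pin_birds = NULL,
                         max_place_tries = 1000) {
  if (is.null(geom)) geom <- default_zone_geometry(width, height)
  stopifnot(n_birds >= 0, crowding_fraction >= 0, crowding_fraction <= 1,
            wing_spread_prob >= 0, wing_spread_prob <= 1,
            noise_sd >= 0, axis_ratio >= 1)
  if (geom$pen_rect[1] < 0 || geom$pen_rect[2] < 0 ||
      geom$pen_rect[3] > width - 1 || geom$pen_rect[4] > height - 1) {
    stop("zone geometry does not fit inside the image")
  }
  if (!is.null(pin_birds)) {
    pin_birds <- matrix(as.numeric(as.matrix(pin_birds)), ncol = 2)
  }
  structure(
    list(width = width, height = height, day = day, n_birds = n_birds,
         geom = geom, occluders = occluders,
         crowding_fraction = crowding_fraction,
         wing_spread_prob = wing_spread_prob,
         wing_spread_factor = wing_spread_factor, seed = seed,
         bird_color_mean = as.numeric(bird_color_mean),
         litter_color_mean = as.numeric(litter_color_mean),
         noise_sd = noise_sd, axis_ratio = axis_ratio,
         area_d18 = area_d18, area_d35 = area_d35,
         area_jitter_sd = area_jitter_sd, pin_birds = pin_birds,
         max_place_tries = max_place_tries),
    class = "scene_config"
  )
}

# Radius of an ellipse (semi-axes a >= b, orientation theta) along the
# direction phi, both in radians.
ellipse_radius <- function(a, b, theta, phi) {
  1 / sqrt((cos(phi - theta) / a)^2 + (sin(phi - theta) / b)^2)
}

# Contact distance between ellipses i and j along direction phi (from i
# to j): the centre separation at which the two silhouettes just touch.
contact_distance <- function(shapes, i, j, phi) {
  ellipse_radius(shapes$a[i], shapes$b[i], shapes$theta[i], phi) +
    ellipse_radius(shapes$a[j], shapes$b[j], shapes$theta[j], phi + pi)
}

# Candidate position for bird i touching one of the already-placed cluster
# members without burrowing into the others: slight (3%) overlap with the
# attach target, and at least 95% of the pairwise contact distance from
# every other placed member. If no sampled direction is clear, the bird is
# slid outward along its ray until it clears everyone while still touching
# the member that limited it. Returns c(x, y).
attach_position <- function(shapes, px, py, placed_ids, i, tries = 50) {
  ratios <- function(x, y) {
    vapply(placed_ids, function(j) {
      psi <- atan2(y - py[j], x - px[j])
      sqrt((x - px[j])^2 + (y - py[j])^2) /
        contact_distance(shapes, j, i, psi)
    }, numeric(1))
  }
  best <- NULL
  best_dir <- NULL
  best_score <- -Inf
  for (t in seq_len(tries)) {
    target <- if (length(placed_ids) == 1) placed_ids else
      sample(placed_ids, 1)
    phi <- stats::runif(1, 0, 2 * pi)
    d <- 0.97 * contact_distance(shapes, target, i, phi)
    x <- px[target] + d * cos(phi)
    y <- py[target] + d * sin(phi)
    score <- min(ratios(x, y))
    if (score >= 0.95) {
      return(c(x, y))
    }
    if (score > best_score) {
      best_score <- score
      best <- c(x, y)
      best_dir <- c(target, phi, d)
    }
  }
  # slide outward along the best ray until clear of every member; contact
  # with the limiting member keeps the cluster connected
  target <- best_dir[1]
  phi <- best_dir[2]
  d0 <- best_dir[3]
  for (mult in seq(1, 3, by = 0.05)) {
    x <- px[target] + mult * d0 * cos(phi)
    y <- py[target] + mult * d0 * sin(phi)
    r <- ratios(x, y)
    if (min(r) >= 0.95) {
      return(c(x, y))
    }
  }
  best
}

# 0-based pixel coordinates covered by a filled ellipse, clipped to the
# image. Returns list(x, y, idx) with idx the linear index into an H x W
# matrix (column-major).
ellipse_pixels <- function(cx, cy, a, b, theta, width, height) {
  x0 <- max(0, floor(cx - a))
  x1 <- min(width - 1, ceiling(cx + a))
  y0 <- max(0, floor(cy - a))
  y1 <- min(height - 1, ceiling(cy + a))
  if (x1 < x0 || y1 < y0) {
    return(list(x = integer(0), y = integer(0), idx = integer(0)))
  }
  xs <- x0:x1
  ys <- y0:y1
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  ct <- cos(theta)
  st <- sin(theta)
  u <- (gx * ct + gy * st) / a
  v <- (-gx * st + gy * ct) / b
  inside <- u * u + v * v <= 1
  x <- rep(xs, each = length(ys))[inside]
  y <- rep(ys, times = length(xs))[inside]
  list(x = x, y = y, idx = x * height + y + 1L)
}

# Pixels within thickness/2 of a polyline (0-based coords), clipped to the
# image; returns linear indices into an H x W matrix.
polyline_pixels <- function(path, thickness, width, height) {
  half <- thickness / 2
  idx <- integer(0)
  for (s in seq_len(nrow(path) - 1)) {
    p <- path[s, ]
    q <- path[s + 1, ]
    x0 <- max(0, floor(min(p[1], q[1]) - half))
    x1 <- min(width - 1, ceiling(max(p[1], q[1]) + half))
    y0 <- max(0, floor(min(p[2], q[2]) - half))
    y1 <- min(height - 1, ceiling(max(p[2], q[2]) + half))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1
    ys <- y0:y1
    gx <- rep(xs, each = length(ys))
    gy <- rep(ys, times = length(xs))
    vx <- q[1] - p[1]
    vy <- q[2] - p[2]
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(gx)) else
      clamp(((gx - p[1]) * vx + (gy - p[2]) * vy) / len2, 0, 1)
    d2 <- (gx - (p[1] + t * vx))^2 + (gy - (p[2] + t * vy))^2
    hit <- d2 <= half^2
    idx <- c(idx, gx[hit] * height + gy[hit] + 1L)
  }
  unique(idx)
}

# Draw per-bird sizes for a scene: areas with jitter and optional
# wing-spread inflation; returns data.frame(area, a, b, theta, wing).
draw_bird_shapes <- function(config, n) {
  base_area <- default_bird_area(config$day, config$width, config$height,
                                 config$area_d18, config$area_d35)
  jitter <- pmax(0.5, 1 + stats::rnorm(n, 0, config$area_jitter_sd))
  wing <- stats::runif(n) < config$wing_spread_prob
  area <- base_area * jitter * ifelse(wing, config$wing_spread_factor, 1)
  a <- sqrt(config$axis_ratio * area / pi)
  b <- a / config$axis_ratio
  theta <- stats::runif(n, 0, pi)
  data.frame(area = area, a = a, b = b, theta = theta, wing = wing)
}

#' Render a synthetic pen scene with ground truth
#'
#' Places birds inside the pen rectangle (rejection sampling for isolated
#' birds; touching pairs/triples for the crowded fraction), paints them over
#' a litter background, draws occluders on top, and adds per-pixel Gaussian
#' noise. The returned ground truth records every bird's ellipse, its zone
#' label under the strict majority-overlap rule applied to its rendered
#' pixels, and the fraction of its silhouette hidden by occluders.
#'
#' @param config a [scene_config()].
#' @param frame_id identifier stored in the frame; default derived from the
#'   seed.
#' @return `list(frame, truth)` where `frame` is a [frame_image()] and
#'   `truth` a `ground_truth` object: `birds` (one row per bird: id,
#'   centroid, semi-axes, orientation, zone, occluded fraction, crowding and
#'   wing-spread flags, rendered pixel area), `zone_counts`, `total`,
#'   `fg_mask` (union of bird silhouettes), `occ_mask`.
#' @export
#' @examples
#' sc <- generate_scene(scene_config(width = 160, height = 120, n_birds = 3,
#'                                   seed = 7))
#' sc$truth$zone_counts
generate_scene <- function(config, frame_id = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(frame_id)) frame_id <- sprintf("synth_%06d", config$seed)
  W <- config$width
  H <- config$height
  pen <- config$geom$pen_rect
  with_seed(config$seed, {
    n <- config$n_birds
    shapes <- draw_bird_shapes(config, max(n, 1))[seq_len(n), , drop = FALSE]
    n_pinned <- if (is.null(config$pin_birds)) 0L else
      min(nrow(config$pin_birds), n)
    n_crowd <- round(config$crowding_fraction * (n - n_pinned))
    cx <- numeric(n)
    cy <- numeric(n)
    crowded <- logical(n)
    placed <- integer(0)

    sep_ok <- function(i, x, y, among = placed) {
      if (length(among) == 0) return(TRUE)
      all(sqrt((cx[among] - x)^2 + (cy[among] - y)^2) >
            shapes$a[among] + shapes$a[i] + 3)
    }
    place_free <- function(i) {
      lo_x <- pen[1] + shapes$a[i] + 1
      hi_x <- pen[3] - shapes$a[i] - 1
      lo_y <- pen[2] + shapes$a[i] + 1
      hi_y <- pen[4] - shapes$a[i] - 1
      if (lo_x >= hi_x || lo_y >= hi_y) stop("placement error: pen too small")
      for (try in seq_len(config$max_place_tries)) {
        x <- stats::runif(1, lo_x, hi_x)
        y <- stats::runif(1, lo_y, hi_y)
        if (sep_ok(i, x, y)) {
          cx[i] <<- x
          cy[i] <<- y
          placed <<- c(placed, i)
          return(invisible(TRUE))
        }
      }
      stop("placement error: could not place bird ", i, " after ",
           config$max_place_tries, " tries")
    }

    if (n_pinned > 0) {
      for (i in seq_len(n_pinned)) {
        cx[i] <- config$pin_birds[i, 1]
        cy[i] <- config$pin_birds[i, 2]
        placed <- c(placed, i)
      }
    }
    free_ids <- setdiff(seq_len(n), seq_len(n_pinned))
    crowd_ids <- utils::tail(free_ids, n_crowd)
    solo_ids <- setdiff(free_ids, crowd_ids)
    for (i in solo_ids) place_free(i)
    # crowded birds: clusters of 2-3 touching ellipses
    rem <- crowd_ids
    while (length(rem) > 0) {
      size <- min(length(rem), sample(2:3, 1))
      cluster <- rem[seq_len(size)]
      rem <- setdiff(rem, cluster)
      seed_id <- cluster[1]
      cluster_done <- FALSE
      for (round in 1:50) {
        place_free(seed_id)
        others <- setdiff(placed, cluster)
        ok <- TRUE
        for (i in cluster[-1]) {
          done <- FALSE
          for (try in 1:100) {
            pos <- attach_position(shapes, cx, cy,
                                   intersect(cluster, placed), i)
            x <- pos[1]
            y <- pos[2]
            inside <- x - shapes$a[i] >= pen[1] &&
              x + shapes$a[i] <= pen[3] &&
              y - shapes$a[i] >= pen[2] && y + shapes$a[i] <= pen[4]
            if (inside && sep_ok(i, x, y, among = others)) {
              cx[i] <- x
              cy[i] <- y
              placed <- c(placed, i)
              done <- TRUE
              break
            }
          }
          if (!done) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          cluster_done <- TRUE
          break
        }
        # re-place the whole cluster from a fresh seed point
        placed <- setdiff(placed, cluster)
      }
      if (!cluster_done) {
        stop("placement error: could not place crowded cluster")
      }
      crowded[cluster] <- TRUE
    }

    # rasterise
    ch <- lapply(config$litter_color_mean, function(v) matrix(v, H, W))
    fg <- matrix(FALSE, H, W)
    bird_px <- vector("list", n)
    for (i in seq_len(n)) {
      px <- ellipse_pixels(cx[i], cy[i], shapes$a[i], shapes$b[i],
                           shapes$theta[i], W, H)
      bird_px[[i]] <- px
      fg[px$idx] <- TRUE
      for (c3 in 1:3) ch[[c3]][px$idx] <- config$bird_color_mean[c3]
    }
    occ <- matrix(FALSE, H, W)
    for (oc in config$occluders) {
      oidx <- polyline_pixels(oc$path, oc$thickness, W, H)
      occ[oidx] <- TRUE
      for (c3 in 1:3) ch[[c3]][oidx] <- oc$color[c3]
    }

    pixels <- array(0L, c(H, W, 3))
    for (c3 in 1:3) {
      v <- ch[[c3]]
      if (config$noise_sd > 0) {
        v <- v + stats::rnorm(H * W, 0, config$noise_sd)
      }
      pixels[, , c3] <- as.integer(round(clamp(v, 0, 255)))
    }

    zone <- character(n)
    occluded_fraction <- numeric(n)
    area_px <- integer(n)
    for (i in seq_len(n)) {
      px <- bird_px[[i]]
      area_px[i] <- length(px$idx)
      occluded_fraction[i] <- if (area_px[i] == 0) 1 else
        mean(occ[px$idx])
      f <- zone_fractions(px$x, px$y, config$geom)
      zone[i] <- if (f[["drinking"]] > 0.5) "drinking" else
        if (f[["feeding"]] > 0.5) "feeding" else "rest"
    }

    birds <- data.frame(
      id = seq_len(n), centroid_x = cx, centroid_y = cy,
      axis_a = shapes$a, axis_b = shapes$b,
      orientation_deg = shapes$theta * 180 / pi,
      zone = zone, occluded_fraction = occluded_fraction,
      crowded = crowded, wing_spread = shapes$wing, area_px = area_px,
      stringsAsFactors = FALSE
    )
    zc <- c(drinking = sum(zone == "drinking"),
            feeding = sum(zone == "feeding"),
            rest = sum(zone == "rest"))
    truth <- structure(
      list(birds = birds, zone_counts = zc, total = n,
           fg_mask = fg, occ_mask = occ, config = config,
           frame_id = frame_id),
      class = "ground_truth"
    )
    frame <- frame_image(pixels, day = config$day, frame_id = frame_id)
    list(frame = frame, truth = truth)
  })
}

#' Generate (blob area, bird count) training pairs
#'
#' Emulates the library of merged-blob areas used to train the count
#' regression: each sample is the union pixel area of 1..k touching bird
#' ellipses (per-bird area jitter as in [generate_scene()]) with a small
#' multiplicative measurement noise, paired with the exact number of birds
#' merged. Reproducible under `config$seed`.
#'
#' @param config a [scene_config()]; the day sets the bird size.
#' @param n_samples number of pairs (>= 1).
#' @param cluster_sizes integer vector of admissible cluster sizes, sampled
#'   uniformly per blob.
#' @param measure_sd relative sd of the blob-area measurement noise.
#' @return data.frame with columns `area` (pixels) and `count`.
#' @export
#' @examples
#' pairs <- generate_area_count_pairs(scene_config(seed = 3), 10,
#'                                    cluster_sizes = 1)
#' stopifnot(all(pairs$count == 1))
generate_area_count_pairs <- function(config, n_samples, cluster_sizes = 1:4,
                                      measure_sd = 0.02) {
  stopifnot(inherits(config, "scene_config"), n_samples >= 1)
  with_seed(config$seed, {
    area <- numeric(n_samples)
    count <- integer(n_samples)
    for (s in seq_len(n_samples)) {
      k <- if (length(cluster_sizes) == 1) cluster_sizes else
        sample(cluster_sizes, 1)
      shapes <- draw_bird_shapes(config, k)
      # place k touching ellipses on a scratch plane
      px <- numeric(k)
      py <- numeric(k)
      for (i in seq_len(k)[-1]) {
        pos <- attach_position(shapes, px, py, seq_len(i - 1), i)
        px[i] <- pos[1]
        py[i] <- pos[2]
      }
      pad <- max(shapes$a) + 2
      ox <- px - min(px) + pad
      oy <- py - min(py) + pad
      gw <- ceiling(max(ox) + pad)
      gh <- ceiling(max(oy) + pad)
      u <- matrix(FALSE, gh, gw)
      for (i in seq_len(k)) {
        e <- ellipse_pixels(ox[i], oy[i], shapes$a[i], shapes$b[i],
                            shapes$theta[i], gw, gh)
        u[e$idx] <- TRUE
      }
      blob <- sum(u)
      noise <- if (measure_sd > 0) 1 + stats::rnorm(1, 0, measure_sd) else 1
      area[s] <- blob * max(noise, 0)
      count[s] <- k
    }
    data.frame(area = area, count = count)
  })
}

#' Write a scene to disk
#'
#' Writes the rendered frame as PNG, the per-bird ground truth as CSV (id,
#' centroid, semi-axes, orientation, zone, occluded fraction, flags, pixel
#' area) and a JSON sidecar with per-zone counts and the full scene
#' configuration including the seed.
#'
#' @param scene result of [generate_scene()].
#' @param dir output directory (created if needed).
#' @param stem file stem; default the frame id.
#' @return named character vector of the three paths written.
#' @export
write_scene <- function(scene, dir, stem = NULL) {
  if (is.null(stem)) stem <- scene$frame$frame_id
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  csv_path <- file.path(dir, paste0(stem, "_birds.csv"))
  json_path <- file.path(dir, paste0(stem, "_truth.json"))
  write_frame(scene$frame, img_path)
  utils::write.csv(scene$truth$birds, csv_path, row.names = FALSE)
  cfg <- scene$truth$config
  sidecar <- list(
    frame_id = scene$frame$frame_id,
    day = cfg$day,
    zone_counts = as.list(scene$truth$zone_counts),
    total = scene$truth$total,
    config = list(
      width = cfg$width, height = cfg$height, day = cfg$day,
      n_birds = cfg$n_birds, crowding_fraction = cfg$crowding_fraction,
      wing_spread_prob = cfg$wing_spread_prob,
      wing_spread_factor = cfg$wing_spread_factor, seed = cfg$seed,
      bird_color_mean = cfg$bird_color_mean,
      litter_color_mean = cfg$litter_color_mean, noise_sd = cfg$noise_sd,
      axis_ratio = cfg$axis_ratio, area_jitter_sd = cfg$area_jitter_sd
    ),
    zone_geometry = list(
      pen_rect = cfg$geom$pen_rect,
      drinking_rect = cfg$geom$drinking_rect,
      feeding_disc = cfg$geom$feeding_disc,
      body_length_px = cfg$geom$body_length_px
    )
  )
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  c(image = img_path, birds = csv_path, truth = json_path)
}

#' Read a scene's ground-truth sidecar files
#'
#' Rebuilds a light `ground_truth` object (no pixel masks) from the CSV and
#' JSON written by [write_scene()].
#'
#' @param json_path path to the `*_truth.json` sidecar; the birds CSV is
#'   located by name next to it.
#' @return a `ground_truth` object with `birds`, `zone_counts`, `total`,
#'   `frame_id`, `day` and `geom`.
#' @export
read_ground_truth <- function(json_path) {
  doc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  csv_path <- sub("_truth\\.json$", "_birds.csv", json_path)
  birds <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  zc <- unlist(doc$zone_counts)
  structure(
    list(birds = birds,
         zone_counts = c(drinking = zc[["drinking"]],
                         feeding = zc[["feeding"]], rest = zc[["rest"]]),
         total = doc$total, frame_id = doc$frame_id, day = doc$day,
         geom = zone_geometry(doc$zone_geometry$pen_rect,
                              doc$zone_geometry$drinking_rect,
                              doc$zone_geometry$feeding_disc,
                              doc$zone_geometry$body_length_px)),
    class = "ground_truth"
  )
}
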