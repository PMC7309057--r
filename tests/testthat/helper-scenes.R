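# Shared fixtures: small scene configurations and brute-force oracles.

# A small pen scene that keeps unit tests fast.
test_cfg <- function(..., width = 160, height = 120, n_birds = 5, seed = 1,
                     noise_sd = 0) {
  scene_config(width = width, height = height, n_birds = n_birds,
               seed = seed, noise_sd = noise_sd, ...)
}

# Scene configuration with exactly one drinking-zone bird fully hidden
# under an equipment patch; all other birds stay clear of the occluder.
occluded_drinking_cfg <- function(width = 320, height = 240, n_birds = 19,
                                  seed = 1) {
  geom <- default_zone_geometry(width, height)
  dr <- geom$drinking_rect
  bx <- (dr[1] + dr[3]) / 2
  by <- (dr[2] + dr[4]) / 2
  a_expect <- sqrt(1.6 * default_bird_area(21, width, height) / pi)
  patch <- 2 * (1.1 * a_expect + 4)
  occ <- occluder_spec("water_line", rbind(c(bx - 1, by), c(bx + 1, by)),
                       thickness = patch)
  scene_config(width = width, height = height, n_birds = n_birds,
               seed = seed, occluders = list(occ), pin_birds = cbind(bx, by))
}

# Exhaustive-search oracle for the two-dimensional Otsu criterion:
# evaluates the between-class scatter at every threshold pair by direct
# summation over the histogram.
brute_otsu_2d <- function(bins) {
  L <- nrow(bins)
  P <- bins / sum(bins)
  I <- row(bins) - 1
  J <- col(bins) - 1
  miT <- sum(I * P)
  mjT <- sum(J * P)
  best <- -Inf
  best_t <- c(0L, 0L)
  for (t1 in 0:(L - 1)) {
    for (t2 in 0:(L - 1)) {
      c0 <- I <= t1 & J <= t2
      c1 <- I > t1 & J > t2
      obj <- 0
      for (cls in list(c0, c1)) {
        w <- sum(P[cls])
        if (w > 1e-12) {
          mi <- sum((I * P)[cls]) / w
          mj <- sum((J * P)[cls]) / w
          obj <- obj + w * ((mi - miT)^2 + (mj - mjT)^2)
        }
      }
      if (obj > best * (1 + 1e-9) + 1e-15) {
        best <- obj
        best_t <- c(t1, t2)
      }
    }
  }
  list(t = best_t, objective = best)
}

# Random joint histogram on L levels with a controllable number of
# occupied bins.
random_histogram <- function(levels, n_bins = levels, max_count = 50) {
  bins <- matrix(0, levels, levels)
  pick <- sample(levels * levels, n_bins)
  bins[pick] <- sample(1:max_count, n_bins, replace = TRUE)
  structure(list(bins = bins, levels = levels,
                 pair = channel_pair("G", "B"), n = sum(bins)),
            class = "joint_histogram")
}

# A flat two-colour frame: columns 1:split in col_left, the rest in
# col_right. The default split makes the left (bird-coloured) class the
# minority so polarity selection is unambiguous.
two_color_frame <- function(col_left = c(230, 228, 222),
                            col_right = c(120, 96, 70),
                            width = 40, height = 30, split = 12) {
  px <- array(0L, c(height, width, 3))
  for (c3 in 1:3) {
    px[, 1:split, c3] <- col_left[c3]
    px[, (split + 1):width, c3] <- col_right[c3]
  }
  frame_image(px, day = 21, frame_id = "twocolor")
}
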