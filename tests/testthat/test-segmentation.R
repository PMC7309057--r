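test_that("nontarget removal blanks pixels outside the pen only", {
  fr <- two_color_frame()
  full <- remove_nontarget(fr, c(0, 0, 39, 29))
  expect_identical(full$pixels, fr$pixels)
  expect_true(all(full$roi))
  left <- remove_nontarget(fr, c(0, 0, 19, 29))
  expect_true(all(left$pixels[, 21:40, ] == 0))
  expect_identical(left$pixels[, 1:20, ], fr$pixels[, 1:20, ])
  expect_false(any(left$roi[, 21:40]))
  expect_error(remove_nontarget(fr, c(5, 5, 5, 20)), "degenerate")
})

test_that("joint histograms count quantized channel pairs exactly", {
  px <- array(0L, c(1, 2, 3))
  px[1, 1, ] <- c(0, 10, 200)
  px[1, 2, ] <- c(0, 10, 200)
  fr <- frame_image(px)
  h <- build_joint_histogram(fr, channel_pair("G", "B"), levels = 256)
  expect_equal(sum(h$bins), 2)
  expect_equal(h$bins[10 + 1, 200 + 1], 2)

  # 2x2 image, 4 levels: quantization bin = value %/% 64
  px <- array(0L, c(2, 2, 3))
  px[1, 1, ] <- c(0, 0, 0)      # (0, 0)
  px[1, 2, ] <- c(0, 70, 70)    # (1, 1)
  px[2, 1, ] <- c(0, 70, 200)   # (1, 3)
  px[2, 2, ] <- c(0, 255, 255)  # (3, 3)
  h4 <- build_joint_histogram(frame_image(px), channel_pair("G", "B"),
                              levels = 4)
  want <- matrix(0, 4, 4)
  want[1, 1] <- 1
  want[2, 2] <- 1
  want[2, 4] <- 1
  want[4, 4] <- 1
  expect_equal(h4$bins, want)
})

test_that("histogram mass equals the region-of-interest pixel count", {
  sc <- generate_scene(test_cfg(noise_sd = 8, seed = 2))
  fr <- remove_nontarget(sc$frame, sc$truth$config$geom)
  h <- build_joint_histogram(fr, levels = 32)
  expect_equal(sum(h$bins), sum(fr$roi))
})

test_that("neighbourhood-mean mode histograms the local average", {
  px <- array(0L, c(3, 3, 3))
  px[, , 2] <- matrix(c(0, 0, 0, 0, 90, 0, 0, 0, 0), 3, 3)
  fr <- frame_image(px)
  h <- build_joint_histogram(fr, channel_pair("G", "G",
                                              mode = "value_vs_neighborhood"),
                             levels = 256)
  # centre pixel: value 90, 3x3 mean 10
  expect_equal(h$bins[91, 11], 1)
  expect_equal(sum(h$bins), 9)
})

test_that("otsu_2d matches exhaustive search on small histograms", {
  set.seed(42)
  for (case in 1:40) {
    L <- sample(3:16, 1)
    h <- random_histogram(L, n_bins = sample(2:(L * L), 1))
    got <- otsu_2d(h)
    want <- brute_otsu_2d(h$bins)
    expect_equal(got$objective, want$objective, tolerance = 1e-10)
    expect_equal(got$t, want$t)
  }
})

test_that("otsu_2d separates two colour populations at full depth", {
  set.seed(7)
  n <- 4000
  g <- c(round(rnorm(n, 200, 6)), round(rnorm(n, 90, 6)))
  b <- c(round(rnorm(n, 210, 6)), round(rnorm(n, 80, 6)))
  px <- array(0L, c(80, 100, 3))
  px[, , 2] <- pmin(pmax(g, 0), 255)
  px[, , 3] <- pmin(pmax(b, 0), 255)
  h <- build_joint_histogram(frame_image(px), channel_pair("G", "B"), 256)
  th <- otsu_2d(h)
  expect_gt(th$t[1], 110)
  expect_lt(th$t[1], 190)
  expect_gt(th$t[2], 100)
  expect_lt(th$t[2], 200)
})

test_that("a single-bin histogram is flagged degenerate with objective 0", {
  bins <- matrix(0, 8, 8)
  bins[3, 5] <- 100
  h <- structure(list(bins = bins, levels = 8, pair = channel_pair(),
                      n = 100),
                 class = "joint_histogram")
  got <- otsu_2d(h)
  expect_true(got$degenerate)
  expect_equal(got$objective, 0)
  expect_equal(got$t, c(2L, 4L))
})

test_that("thresholding a noiseless scene recovers bird pixels exactly", {
  cfg <- test_cfg(width = 320, height = 240, n_birds = 19, seed = 8)
  sc <- generate_scene(cfg)
  fr <- remove_nontarget(sc$frame, cfg$geom)
  h <- build_joint_histogram(fr)
  th <- otsu_2d(h)
  mask <- apply_threshold(fr, channel_pair(), th$t)
  expect_identical(mask$mask, sc$truth$fg_mask)
  expect_equal(mask$provenance$polarity, "upper")
})

test_that("polarity auto-selection handles dark birds on light litter", {
  cfg <- test_cfg(width = 320, height = 240, n_birds = 19, seed = 8,
                  bird_color_mean = c(40, 45, 50),
                  litter_color_mean = c(190, 185, 170))
  sc <- generate_scene(cfg)
  seg <- segment_frame(sc$frame, geom = cfg$geom, erosion_radius = 0,
                       min_area = 0)
  expect_identical(seg$mask$mask, sc$truth$fg_mask)
  expect_equal(seg$mask$provenance$polarity, "lower")
})

test_that("disc erosion of a 3x3 square keeps only the centre pixel", {
  m <- matrix(FALSE, 7, 7)
  m[3:5, 3:5] <- TRUE
  out <- morphological_cleanup(m, erosion_radius = 1, min_area = 0)
  want <- matrix(FALSE, 7, 7)
  want[4, 4] <- TRUE
  expect_equal(out$mask, want)
  ident <- morphological_cleanup(m, erosion_radius = 0, min_area = 0)
  expect_equal(ident$mask, m)
})

test_that("min_area filtering is monotone in the number of regions", {
  set.seed(3)
  m <- matrix(runif(60 * 80) < 0.3, 60, 80)
  n_prev <- Inf
  for (ma in c(0, 2, 5, 10, 25)) {
    n <- length(extract_regions(morphological_cleanup(m, 0, ma)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("regions are 8-connected, ordered, and conserve area", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE
  m[3, 3] <- TRUE  # diagonal touch: one region
  m[8:9, 6:8] <- TRUE
  regions <- extract_regions(m)
  expect_length(regions, 2)
  expect_equal(regions[[1]]$area, 2)
  expect_equal(regions[[2]]$area, 6)
  expect_equal(regions[[1]]$bbox[2], 1)  # topmost first (0-based ymin)
  expect_equal(sum(vapply(regions, function(r) r$area, numeric(1))), sum(m))
  expect_length(extract_regions(matrix(FALSE, 4, 4)), 0)
})

test_that("the segmentation pipeline is deterministic", {
  sc <- generate_scene(test_cfg(noise_sd = 8, seed = 10))
  a <- segment_frame(sc$frame, geom = sc$truth$config$geom)
  b <- segment_frame(sc$frame, geom = sc$truth$config$geom)
  expect_identical(a$mask$mask, b$mask$mask)
  expect_identical(regions_to_df(a$regions), regions_to_df(b$regions))
})

test_that("a bird outside the pen rectangle yields no region", {
  # pen restricted to the left half; pin one bird well inside the right half
  geom <- zone_geometry(pen_rect = c(4, 4, 155, 115),
                        drinking_rect = c(4, 8, 155, 30),
                        feeding_disc = c(80, 80, 25),
                        body_length_px = 20)
  cfg <- scene_config(width = 320, height = 120, n_birds = 3, seed = 2,
                      geom = geom, noise_sd = 0,
                      pin_birds = cbind(250, 60))
  sc <- generate_scene(cfg)
  seg <- segment_frame(sc$frame, geom = geom, erosion_radius = 0,
                       min_area = 0)
  expect_length(seg$regions, 2)
  cx <- vapply(seg$regions, function(r) r$centroid[1], numeric(1))
  expect_true(all(cx <= 155))
})
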