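test_that("scene generation is bit-identical under a fixed seed", {
  cfg <- test_cfg(noise_sd = 8, seed = 11)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$truth$birds, b$truth$birds)
  cfg2 <- test_cfg(noise_sd = 8, seed = 12)
  expect_false(identical(generate_scene(cfg2)$frame$pixels, a$frame$pixels))
})

test_that("an empty scene renders pure litter and zero ground truth", {
  cfg <- test_cfg(n_birds = 0)
  sc <- generate_scene(cfg)
  expect_equal(sc$truth$total, 0)
  expect_equal(unname(sum(sc$truth$zone_counts)), 0)
  expect_false(any(sc$truth$fg_mask))
  for (c3 in 1:3) {
    expect_true(all(sc$frame$pixels[, , c3] == cfg$litter_color_mean[c3]))
  }
})

test_that("isolated birds render as n disjoint foreground components", {
  cfg <- test_cfg(width = 320, height = 240, n_birds = 19, seed = 4)
  sc <- generate_scene(cfg)
  expect_equal(sc$truth$total, 19)
  regions <- extract_regions(sc$truth$fg_mask)
  expect_length(regions, 19)
})

test_that("zone counts always sum to the total bird count", {
  for (seed in 1:5) {
    sc <- generate_scene(test_cfg(seed = seed, crowding_fraction = 0.4,
                                  n_birds = 8, width = 240, height = 180))
    expect_equal(unname(sum(sc$truth$zone_counts)), sc$truth$total)
  }
})

test_that("birds grow between day 18 and day 35", {
  s18 <- generate_scene(test_cfg(day = 18, seed = 2, n_birds = 6,
                                 width = 240, height = 180))
  s35 <- generate_scene(test_cfg(day = 35, seed = 2, n_birds = 6,
                                 width = 240, height = 180))
  expect_gt(mean(s35$truth$birds$area_px), mean(s18$truth$birds$area_px))
})

test_that("wing-spread inflation enlarges the silhouette", {
  plain <- generate_scene(test_cfg(seed = 3, n_birds = 4, width = 240,
                                   height = 180))
  spread <- generate_scene(test_cfg(seed = 3, n_birds = 4, width = 240,
                                    height = 180, wing_spread_prob = 1))
  expect_true(all(spread$truth$birds$wing_spread))
  expect_gt(mean(spread$truth$birds$area_px),
            1.3 * mean(plain$truth$birds$area_px))
})

test_that("ground-truth zone labels agree with assign_zone on bird pixels", {
  cfg <- test_cfg(width = 320, height = 240, n_birds = 12, seed = 9)
  sc <- generate_scene(cfg)
  regions <- extract_regions(sc$truth$fg_mask)
  got <- sort(vapply(regions, assign_zone, character(1), geom = cfg$geom))
  expect_equal(got, sort(sc$truth$birds$zone))
})

test_that("a pinned bird under an occluder is fully hidden", {
  cfg <- occluded_drinking_cfg(seed = 5)
  sc <- generate_scene(cfg)
  expect_equal(sc$truth$birds$occluded_fraction[1], 1)
  expect_equal(sc$truth$birds$zone[1], "drinking")
  expect_equal(sum(sc$truth$birds$occluded_fraction > 0.5), 1)
})

test_that("area/count pairs behave like unions of touching silhouettes", {
  cfg <- scene_config(seed = 21)
  single <- generate_area_count_pairs(cfg, 40, cluster_sizes = 1)
  expect_true(all(single$count == 1))
  mixed <- generate_area_count_pairs(cfg, 400, cluster_sizes = 1:2)
  m1 <- mean(mixed$area[mixed$count == 1])
  m2 <- mean(mixed$area[mixed$count == 2])
  expect_gt(m2 / m1, 1.8)
  expect_lt(m2 / m1, 2.2)
  expect_identical(generate_area_count_pairs(cfg, 25),
                   generate_area_count_pairs(cfg, 25))
})

test_that("invalid configurations are rejected", {
  geom <- default_zone_geometry(400, 300)
  expect_error(scene_config(width = 160, height = 120, geom = geom),
               "fit inside")
  expect_error(generate_scene(test_cfg(n_birds = 400, width = 160,
                                       height = 120,
                                       max_place_tries = 30)),
               "placement error")
})

test_that("scenes round-trip through their sidecar files", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(test_cfg(seed = 6, noise_sd = 8))
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  gt <- read_ground_truth(paths[["truth"]])
  expect_equal(gt$total, sc$truth$total)
  expect_equal(gt$zone_counts, sc$truth$zone_counts)
  expect_equal(gt$birds$zone, sc$truth$birds$zone)
  expect_equal(gt$geom$pen_rect, sc$truth$config$geom$pen_rect)
  fr <- read_frame(paths[["image"]], day = gt$day)
  expect_identical(fr$pixels, sc$frame$pixels)
})
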