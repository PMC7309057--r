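test_that("the reference area is the arithmetic mean of the samples", {
  expect_equal(estimate_reference_area(100, day = 20)$s, 100)
  ref <- estimate_reference_area(c(90, 110), day = 21)
  expect_equal(ref$s, 100)
  expect_equal(ref$sd, sqrt(200), tolerance = 1e-12)
  expect_equal(ref$n_samples, 2)
  expect_error(estimate_reference_area(numeric(0), 21), "at least one")
  expect_error(estimate_reference_area(c(10, -5), 21), "positive")
})

test_that("area normalization is exact division by the reference", {
  ref <- estimate_reference_area(50, day = 20)
  expect_equal(normalize_area(100, ref)$s_bar_i, 2)
  expect_equal(normalize_area(50, ref)$s_bar_i, 1)
  z <- normalize_area(0, ref)
  expect_equal(z$s_bar_i, 0)
  expect_true(z$flagged)
})

test_that("synthetic reference areas grow from day 18 to day 35", {
  r18 <- calibrate_reference_area(test_cfg(day = 18, width = 240,
                                           height = 180, noise_sd = 8),
                                  n_profiles = 8, erosion_radius = 0)
  r35 <- calibrate_reference_area(test_cfg(day = 35, width = 240,
                                           height = 180, noise_sd = 8),
                                  n_profiles = 8, erosion_radius = 0)
  expect_gt(r35$s, r18$s)
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5, -1.5)),
               c(1, 2, 3, -1, -2))
  expect_equal(round_half_up(0.00365, 4), 0.0037)
  expect_equal(round_half_up(0.062593, 4), 0.0626)
})

test_that("the model-free counting rule is the rounded area ratio", {
  ref <- estimate_reference_area(50, day = 20)
  expect_equal(count_region(list(area = 150), ref), 3L)
  expect_equal(count_region(list(area = 80), ref), 2L)
  expect_equal(count_region(list(area = 70), ref), 1L)
  expect_equal(count_region(list(area = 75), ref), 2L)  # 1.5 rounds up
  expect_equal(count_region(list(area = 5), ref), 1L)   # clamped to >= 1
  # oracle: brute-force arithmetic over a grid of areas
  for (area in seq(10, 400, by = 13)) {
    want <- max(1, floor(area / 50 + 0.5))
    expect_equal(count_region(list(area = area), ref), want)
  }
})

test_that("training recovers an exact rounding relationship", {
  set.seed(31)
  a <- runif(1000, 0.8, 4.2)
  pairs <- data.frame(s_bar = a, count = pmax(1, round(a)))
  fit <- train_bp(pairs, seed = 1)
  expect_gte(fit$metrics$R, 0.99)
})

test_that("training is deterministic and refuses tiny data sets", {
  pairs <- generate_area_count_pairs(scene_config(seed = 17), 120)
  pairs$s_bar <- pairs$area / mean(pairs$area[pairs$count == 1])
  f1 <- train_bp(pairs[, c("s_bar", "count")], seed = 4, epochs = 120)
  f2 <- train_bp(pairs[, c("s_bar", "count")], seed = 4, epochs = 120)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_error(train_bp(pairs[1:10, c("s_bar", "count")]), "at least 30")
  bad <- pairs[1:40, c("s_bar", "count")]
  bad$count[3] <- 0
  expect_error(train_bp(bad), "positive integers")
})

test_that("a trained model round-trips through JSON exactly", {
  pairs <- generate_area_count_pairs(scene_config(seed = 23), 200)
  pairs$s_bar <- pairs$area / mean(pairs$area[pairs$count == 1])
  fit <- train_bp(pairs[, c("s_bar", "count")], seed = 2, epochs = 150)
  path <- withr::local_tempfile(fileext = ".json")
  write_bp_model(fit$model, path)
  back <- read_bp_model(path)
  x <- seq(0.5, 4.5, by = 0.1)
  expect_equal(predict(back, x), predict(fit$model, x), tolerance = 1e-12)
})

test_that("per-blob counts from the trained model are nearly always exact", {
  cfg <- scene_config(seed = 29)
  pairs <- generate_area_count_pairs(cfg, 800)
  s1 <- mean(pairs$area[pairs$count == 1])
  pairs$s_bar <- pairs$area / s1
  fit <- train_bp(pairs[, c("s_bar", "count")], seed = 3)
  clean_cfg <- scene_config(seed = 57, area_jitter_sd = 0)
  clean <- generate_area_count_pairs(clean_cfg, 200, measure_sd = 0)
  ref <- estimate_reference_area(s1, day = clean_cfg$day)
  got <- vapply(clean$area, function(a) {
    count_region(list(area = a), ref, model = fit$model)
  }, integer(1))
  expect_gte(mean(got == clean$count), 0.95)
})

test_that("frame totals are additive over regions", {
  cfg <- test_cfg(width = 320, height = 240, n_birds = 10, seed = 13,
                  noise_sd = 8)
  sc <- generate_scene(cfg)
  ref <- calibrate_reference_area(cfg, n_profiles = 6, erosion_radius = 0)
  det <- detect_frame(sc$frame, cfg$geom, ref, erosion_radius = 0)
  expect_equal(det$zone_counts$total, sum(det$counts))
  expect_equal(det$zone_counts$rest,
               det$zone_counts$total - det$zone_counts$drinking -
                 det$zone_counts$feeding)
})
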