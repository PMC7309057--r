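test_that("perfect detection gives rates (1, 0, 0)", {
  t <- detection_tally("drinking", true_num = 50, detected = 50)
  m <- detection_metrics(t)
  expect_equal(m$accuracy, 1)
  expect_equal(m$miss_rate, 0)
  expect_equal(m$false_rate, 0)
  expect_error(detection_metrics(detection_tally("feeding", 0, 0)),
               "undefined")
  expect_error(detection_tally("feeding", -1, 0), "nonnegative")
})

test_that("missed detections decompose into their cause sub-counts", {
  t <- detection_tally("feeding", 100, 90, missed_crowding = 4,
                       missed_occlusion = 5, missed_other = 1,
                       false_det = 0)
  expect_equal(t$missed, 10)
})

test_that("fit metrics match hand arithmetic", {
  m <- fit_metrics(fit_series(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(m$MSE, 1 / 3)
  expect_equal(m$MAE, 1 / 9)
  expect_equal(m$R, 0.5)
  perfect <- fit_metrics(fit_series(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(c(perfect$R, perfect$MSE, perfect$MAE), c(1, 0, 0))
  null_model <- fit_metrics(fit_series(c(1, 2, 3), c(2, 2, 2)))
  expect_equal(null_model$R, 0)
  expect_error(fit_metrics(fit_series(c(2, 2), c(1, 2))), "zero variance")
  expect_error(fit_metrics(fit_series(c(0, 2), c(1, 2))), "MAE undefined")
})

test_that("fit metrics agree with independent recomputation", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    y <- sample(1:20, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    y_hat <- y + rnorm(n)
    m <- fit_metrics(fit_series(y, y_hat))
    ss_res <- 0
    ss_tot <- 0
    mae <- 0
    for (k in seq_len(n)) {
      ss_res <- ss_res + (y[k] - y_hat[k])^2
      ss_tot <- ss_tot + (y[k] - mean(y))^2
      mae <- mae + abs(y[k] - y_hat[k]) / y[k]
    }
    expect_equal(m$R, 1 - ss_res / ss_tot, tolerance = 1e-12)
    expect_equal(m$MSE, ss_res / n, tolerance = 1e-12)
    expect_equal(m$MAE, mae / n, tolerance = 1e-12)
    expect_equal(pearson_r(fit_series(y, y_hat)), cor(y, y_hat))
  }
})

make_run <- function(n_frames = 8, mutate = identity) {
  preds <- list()
  truths <- list()
  for (i in seq_len(n_frames)) {
    cfg <- test_cfg(width = 240, height = 180, n_birds = 6 + (i %% 3),
                    seed = 300 + i, noise_sd = 8)
    sc <- generate_scene(cfg, frame_id = sprintf("fr%02d", i))
    zc <- sc$truth$zone_counts
    preds[[i]] <- data.frame(frame_id = sc$frame$frame_id,
                             drinking = zc[["drinking"]],
                             feeding = zc[["feeding"]],
                             rest = zc[["rest"]],
                             total = sc$truth$total)
    truths[[i]] <- sc$truth
  }
  list(pred = mutate(do.call(rbind, preds)), truth = truths)
}

test_that("a perfect run scores accuracy 1 in every populated zone", {
  run <- make_run()
  rep1 <- evaluate_run(run$pred, run$truth)
  for (z in c("drinking", "feeding", "rest")) {
    if (!is.null(rep1$metrics[[z]])) {
      expect_equal(rep1$metrics[[z]]$accuracy, 1)
      expect_equal(rep1$metrics[[z]]$miss_rate, 0)
    }
  }
  rep2 <- evaluate_run(run$pred, run$truth)
  expect_identical(rep1$table, rep2$table)
})

test_that("the tally identity detected = true - missed + false always holds", {
  run <- make_run(mutate = function(p) {
    p$drinking[2] <- p$drinking[2] + 1  # one false detection
    p$rest[2] <- max(0, p$rest[2] - 1)
    p$feeding[5] <- max(0, p$feeding[5] - 1)  # one miss
    p
  })
  rep <- evaluate_run(run$pred, run$truth)
  for (z in c("drinking", "feeding", "rest")) {
    ta <- rep$tallies[[z]]
    expect_equal(ta$detected, ta$true_num - ta$missed + ta$false_det)
  }
})

test_that("frame misalignment is reported by frame id", {
  run <- make_run(4)
  run$pred$frame_id[3] <- "bogus"
  expect_error(evaluate_run(run$pred, run$truth), "bogus")
})

test_that("fully occluded zone birds are attributed to occlusion misses", {
  preds <- list()
  truths <- list()
  for (i in 1:5) {
    cfg <- occluded_drinking_cfg(seed = 700 + i)
    sc <- generate_scene(cfg, frame_id = sprintf("oc%02d", i))
    zc <- sc$truth$zone_counts
    preds[[i]] <- data.frame(frame_id = sc$frame$frame_id,
                             drinking = zc[["drinking"]] - 1L,
                             feeding = zc[["feeding"]],
                             rest = zc[["rest"]],
                             total = sc$truth$total - 1L)
    truths[[i]] <- sc$truth
  }
  rep <- evaluate_run(do.call(rbind, preds), truths)
  expect_equal(rep$tallies$drinking$missed_occlusion, 5)
  expect_equal(rep$tallies$drinking$missed_crowding, 0)
})

test_that("reports round-trip to CSV and JSON", {
  run <- make_run(4)
  rep <- evaluate_run(run$pred, run$truth)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep, csv, js)
  back <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(back$zone, rep$table$zone)
  expect_equal(back$detected, rep$table$detected)
  doc <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(doc$zones$true, rep$table$true)
})
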