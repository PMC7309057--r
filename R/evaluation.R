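# Detection-rate and model-fit evaluation for zone-distribution runs.

#' Build a per-zone detection tally
#'
#' Accumulated counts for one zone over an evaluation set: the true number
#' of birds in the zone, the number detected, missed detections broken down
#' by cause (crowding, occlusion, others), and false detections.
#'
#' @param zone zone label.
#' @param true_num true number of birds in the zone (summed over frames).
#' @param detected number detected automatically.
#' @param missed_crowding,missed_occlusion,missed_other missed detections
#'   by cause; their sum is the total missed count.
#' @param false_det number of false detections.
#' @return an object of class `detection_tally`.
#' @export
detection_tally <- function(zone, true_num, detected, missed_crowding = 0,
                            missed_occlusion = 0, missed_other = 0,
                            false_det = 0) {
  vals <- c(true_num, detected, missed_crowding, missed_occlusion,
            missed_other, false_det)
  if (any(vals < 0)) stop("tally counts must be nonnegative")
  structure(
    list(zone = zone, true_num = true_num, detected = detected,
         missed_crowding = missed_crowding,
         missed_occlusion = missed_occlusion, missed_other = missed_other,
         missed = missed_crowding + missed_occlusion + missed_other,
         false_det = false_det),
    class = "detection_tally"
  )
}

#' Detection rates from a tally
#'
#' The three rates of the distribution evaluation: accuracy
#' `R_accuracy = T_num / T_truenum`, missed-detection rate
#' `R_miss = T_miss / T_truenum`, and false-detection rate
#' `R_false = T_false / T_truenum`. Reported values are rounded half away
#' from zero to 4 decimals; the raw ratios are retained.
#'
#' @param tally a [detection_tally()] with `true_num > 0`.
#' @return an object of class `detection_metrics` with fields `zone`,
#'   `accuracy`, `miss_rate`, `false_rate` (rounded) and `raw` (unrounded).
#' @export
#' @examples
#' t <- detection_tally("drinking", true_num = 671, detected = 632,
#'                      missed_crowding = 8, missed_occlusion = 32,
#'                      missed_other = 2, false_det = 3)
#' detection_metrics(t)
detection_metrics <- function(tally) {
  if (tally$true_num <= 0) {
    stop("metrics undefined: true count is zero in zone ", tally$zone)
  }
  raw <- c(accuracy = tally$detected / tally$true_num,
           miss_rate = tally$missed / tally$true_num,
           false_rate = tally$false_det / tally$true_num)
  structure(
    list(zone = tally$zone,
         accuracy = round_half_up(raw[["accuracy"]], 4),
         miss_rate = round_half_up(raw[["miss_rate"]], 4),
         false_rate = round_half_up(raw[["false_rate"]], 4),
         raw = raw),
    class = "detection_metrics"
  )
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("%s zone: R_accuracy = %.4f, R_miss = %.4f, R_false = %.4f\n",
              x$zone, x$accuracy, x$miss_rate, x$false_rate))
  invisible(x)
}

#' Pair actual and fitted count series
#'
#' @param y actual counts.
#' @param y_hat fitted counts; same length as `y` (>= 1).
#' @return an object of class `fit_series`.
#' @export
fit_series <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 1) {
    stop("y and y_hat must have equal length >= 1")
  }
  structure(list(y = as.numeric(y), y_hat = as.numeric(y_hat),
                 y_bar = mean(y)),
            class = "fit_series")
}

#' Model-fit criteria: R, MSE and relative MAE
#'
#' `R = 1 - sum((y - y_hat)^2) / sum((y - y_bar)^2)` (the
#' coefficient-of-determination reading, the only dimensionless form
#' bounded above by 1), `MSE = sum((y - y_hat)^2) / n`, and
#' `MAE = (1/n) * sum(|y - y_hat| / y)` — note this "mean absolute error"
#' divides each absolute error by the actual count, so it is a relative
#' error and requires every `y` to be nonzero. For a conventional
#' correlation see [pearson_r()].
#'
#' @param series a [fit_series()] with `n >= 2`.
#' @return an object of class `fit_metrics` with fields `R`, `MSE`, `MAE`,
#'   `n`.
#' @export
#' @examples
#' fit_metrics(fit_series(c(1, 2, 3), c(1, 2, 4)))  # MSE 1/3, MAE 1/9, R 0.5
fit_metrics <- function(series) {
  y <- series$y
  y_hat <- series$y_hat
  n <- length(y)
  if (n < 2) stop("need at least 2 observations")
  ss_tot <- sum((y - series$y_bar)^2)
  if (ss_tot <= 0) stop("R undefined: zero variance in actual counts")
  if (any(y == 0)) stop("MAE undefined: actual count of zero")
  ss_res <- sum((y - y_hat)^2)
  structure(
    list(R = 1 - ss_res / ss_tot, MSE = ss_res / n,
         MAE = mean(abs(y - y_hat) / y), n = n),
    class = "fit_metrics"
  )
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("fit over %d samples: R = %.4f, MSE = %.4f, MAE = %.4f\n",
              x$n, x$R, x$MSE, x$MAE))
  invisible(x)
}

#' Pearson correlation between actual and fitted counts
#' @param series a [fit_series()].
#' @return numeric scalar.
#' @export
pearson_r <- function(series) stats::cor(series$y, series$y_hat)

# Attribute a frame/zone's missed detections to causes using the ground
# truth: occlusion first (birds > 50% hidden), then crowding, then others.
attribute_causes <- function(n_miss, birds_in_zone) {
  n_occ_birds <- sum(birds_in_zone$occluded_fraction > 0.5)
  n_crowd_birds <- sum(birds_in_zone$crowded &
                         birds_in_zone$occluded_fraction <= 0.5)
  occ <- min(n_miss, n_occ_birds)
  crowd <- min(n_miss - occ, n_crowd_birds)
  c(crowding = crowd, occlusion = occ, other = n_miss - occ - crowd)
}

#' Evaluate a detection run against ground truth
#'
#' Accumulates per-zone detection tallies over aligned frames, computes the
#' per-zone detection rates, and fits the per-frame total counts
#' (actual vs predicted) with [fit_metrics()]. For each frame and zone, a
#' shortfall of the predicted count is a missed detection and an excess a
#' false detection, so the identity
#' `detected = true - missed + false` holds by construction. Missed
#' detections in synthetic runs are attributed to causes from the ground
#' truth (occlusion when a zone bird is more than half hidden, crowding
#' when it sits in a touching cluster, otherwise "others").
#'
#' @param predicted data.frame of per-frame zone counts (columns
#'   `frame_id`, `drinking`, `feeding`, `rest`, `total`), e.g. rbind-ed
#'   [frame_distribution()] rows.
#' @param truth list of `ground_truth` objects aligned with `predicted`.
#' @return an object of class `evaluation_report`: `tallies` (list of
#'   per-zone [detection_tally()]), `metrics` (per-zone
#'   [detection_metrics()]), `fit` ([fit_metrics()] on per-frame totals, or
#'   `NULL` when undefined), `table` (a report data.frame, one row per
#'   zone), `per_frame`.
#' @export
evaluate_run <- function(predicted, truth) {
  if (nrow(predicted) != length(truth)) {
    stop("predicted and truth must cover the same frames")
  }
  truth_ids <- vapply(truth, function(tr) tr$frame_id, character(1))
  bad <- which(predicted$frame_id != truth_ids)
  if (length(bad) > 0) {
    stop("frame misalignment at '", predicted$frame_id[bad[1]],
         "' vs '", truth_ids[bad[1]], "'")
  }
  zones <- c("drinking", "feeding", "rest")
  acc <- list()
  for (z in zones) {
    acc[[z]] <- c(true_num = 0, detected = 0, crowding = 0, occlusion = 0,
                  other = 0, false_det = 0)
  }
  per_frame <- predicted
  per_frame$true_total <- vapply(truth, function(tr) tr$total, numeric(1))
  for (f in seq_along(truth)) {
    tr <- truth[[f]]
    for (z in zones) {
      t_z <- unname(tr$zone_counts[[z]])
      p_z <- predicted[[z]][f]
      miss <- max(t_z - p_z, 0)
      fals <- max(p_z - t_z, 0)
      causes <- attribute_causes(miss, tr$birds[tr$birds$zone == z, ,
                                                drop = FALSE])
      acc[[z]] <- acc[[z]] + c(t_z, p_z, causes[["crowding"]],
                               causes[["occlusion"]], causes[["other"]],
                               fals)
    }
  }
  tallies <- lapply(zones, function(z) {
    detection_tally(z, acc[[z]][["true_num"]], acc[[z]][["detected"]],
                    missed_crowding = acc[[z]][["crowding"]],
                    missed_occlusion = acc[[z]][["occlusion"]],
                    missed_other = acc[[z]][["other"]],
                    false_det = acc[[z]][["false_det"]])
  })
  names(tallies) <- zones
  metrics <- lapply(tallies, function(ta) {
    if (ta$true_num > 0) detection_metrics(ta) else NULL
  })
  fit <- NULL
  if (all(per_frame$true_total > 0) && nrow(per_frame) >= 2 &&
      stats::var(per_frame$true_total) > 0) {
    fit <- fit_metrics(fit_series(per_frame$true_total, per_frame$total))
  }
  tab <- do.call(rbind, lapply(zones, function(z) {
    ta <- tallies[[z]]
    me <- metrics[[z]]
    data.frame(zone = z, true = ta$true_num, detected = ta$detected,
               missed_crowding = ta$missed_crowding,
               missed_occlusion = ta$missed_occlusion,
               missed_other = ta$missed_other, false = ta$false_det,
               R_ac = if (is.null(me)) NA_real_ else me$accuracy,
               R_miss = if (is.null(me)) NA_real_ else me$miss_rate,
               R_false = if (is.null(me)) NA_real_ else me$false_rate,
               stringsAsFactors = FALSE)
  }))
  structure(list(tallies = tallies, metrics = metrics, fit = fit,
                 table = tab, per_frame = per_frame),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Zone-distribution evaluation\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#'
#' The CSV mirrors the per-zone report table (zone, true, detected, missed
#' detections by cause, false detections, and the three rates); the JSON
#' additionally carries the fit metrics.
#'
#' @param report an [evaluate_run()] result.
#' @param csv_path,json_path output paths (`NULL` to skip one).
#' @return invisible list of written paths.
#' @export
write_evaluation_report <- function(report, csv_path = NULL,
                                    json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$table, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    doc <- list(zones = report$table,
                fit = if (is.null(report$fit)) NULL else {
                  list(R = report$fit$R, MSE = report$fit$MSE,
                       MAE = report$fit$MAE, n = report$fit$n)
                })
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(list(csv = csv_path, json = json_path))
}
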