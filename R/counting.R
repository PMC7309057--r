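# Area-based bird counting: per-day single-bird reference area, area
# normalisation, and a small backpropagation-trained feedforward regression
# network mapping normalised blob area to bird count.

#' Estimate the per-day single-bird reference area
#'
#' The reference area of a day is the arithmetic mean of single-bird
#' silhouette areas sampled on that day. Frames from each day are analysed
#' against their own day's reference, so growth between days never biases
#' the normalisation.
#'
#' @param single_bird_areas numeric vector of single-bird areas in pixels
#'   (nonempty, all positive).
#' @param day integer age in days the samples were taken.
#' @return an object of class `reference_area` with fields `day`, `s`
#'   (mean area), `n_samples`, `sd`.
#' @export
#' @examples
#' estimate_reference_area(c(90, 110), day = 21)
estimate_reference_area <- function(single_bird_areas, day) {
  if (length(single_bird_areas) == 0) {
    stop("need at least one single-bird area")
  }
  if (any(single_bird_areas <= 0)) stop("all areas must be positive")
  structure(
    list(day = as.integer(day), s = mean(single_bird_areas),
         n_samples = length(single_bird_areas),
         sd = if (length(single_bird_areas) > 1) {
           stats::sd(single_bird_areas)
         } else {
           0
         }),
    class = "reference_area"
  )
}

#' @export
print.reference_area <- function(x, ...) {
  cat(sprintf("reference area, day %d: s = %.1f px (n = %d, sd = %.1f)\n",
              x$day, x$s, x$n_samples, x$sd))
  invisible(x)
}

#' Normalize a region area by the day's reference area
#'
#' @param s_i raw region area in pixels.
#' @param ref a [estimate_reference_area()] result (`s > 0`).
#' @param region_id optional identifier carried through.
#' @return a one-row data.frame (`region_id`, `s_i`, `s_bar_i`, `flagged`);
#'   a zero area is returned as 0 with `flagged = TRUE`.
#' @export
normalize_area <- function(s_i, ref, region_id = NA_integer_) {
  stopifnot(ref$s > 0)
  data.frame(region_id = region_id, s_i = s_i, s_bar_i = s_i / ref$s,
             flagged = s_i <= 0)
}

# forward pass of the 1-input MLP: sigmoid hidden layers, linear output
bp_forward <- function(model, x) {
  a <- matrix(x, nrow = 1)
  nl <- length(model$weights)
  for (l in seq_len(nl)) {
    z <- model$weights[[l]] %*% a + as.numeric(model$biases[[l]])
    a <- if (l < nl) 1 / (1 + exp(-z)) else z
  }
  as.numeric(a)
}

#' Predict counts from normalized areas
#' @param object a `bp_model`.
#' @param newdata numeric vector of normalized areas.
#' @param ... unused.
#' @return numeric vector of (unrounded) predicted counts.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  z <- (newdata - object$input_center) / object$input_scale
  bp_forward(object, z)
}

#' Train the backpropagation count-regression network
#'
#' Fits a feedforward network with one input (normalized blob area), one
#' sigmoidal hidden layer and a linear output (bird count) by
#' Levenberg-Marquardt minimisation of the squared error — the classical
#' trainer for small regression networks of this shape — from a
#' Nguyen-Widrow-style initialisation (steep sigmoids with transition
#' centres spread over the input range). The data are split 0.70/0.15/0.15
#' into training, validation and test sets by a seeded shuffle; training
#' stops early when the validation error has not improved for `patience`
#' iterations and the best-validation weights are kept. Fit quality
#' (R, MSE, MAE; see [fit_metrics()]) is reported on the held-out test
#' split.
#'
#' @param pairs data.frame with columns `s_bar` (normalized area) and
#'   `count` (true bird count, positive integers); at least 30 rows.
#' @param hidden_sizes width of the hidden layer; default 10. The
#'   architecture has exactly one hidden layer.
#' @param seed integer seed for the shuffle and weight initialisation.
#' @param epochs maximum training iterations.
#' @param patience early-stopping patience in iterations.
#' @return `list(model, metrics)`: a `bp_model` (weights, biases, input
#'   scaling, `training_meta`) and the test-split [fit_metrics()].
#' @export
train_bp <- function(pairs, hidden_sizes = 10, seed = 1, epochs = 500,
                     patience = 20) {
  stopifnot(all(c("s_bar", "count") %in% names(pairs)))
  if (length(hidden_sizes) != 1 || hidden_sizes < 1) {
    stop("the count network has exactly one hidden layer; ",
         "hidden_sizes must be a single width")
  }
  n <- nrow(pairs)
  if (n < 30) stop("need at least 30 (area, count) pairs, got ", n)
  if (any(pairs$count <= 0) || any(pairs$count != round(pairs$count))) {
    stop("counts must be positive integers")
  }
  h <- as.integer(hidden_sizes)
  with_seed(seed, {
    idx <- sample(n)
    n_tr <- floor(0.70 * n)
    n_va <- floor(0.15 * n)
    tr <- idx[seq_len(n_tr)]
    va <- idx[n_tr + seq_len(n_va)]
    te <- idx[(n_tr + n_va + 1):n]
    ctr <- mean(pairs$s_bar[tr])
    scl <- stats::sd(pairs$s_bar[tr])
    if (!is.finite(scl) || scl <= 0) scl <- 1
    x_tr <- (pairs$s_bar[tr] - ctr) / scl
    y_tr <- pairs$count[tr]
    x_va <- (pairs$s_bar[va] - ctr) / scl
    y_va <- pairs$count[va]

    # Nguyen-Widrow-style init: hidden sigmoids steep (|w| = 0.7 h) with
    # centres spread across the observed input range; linear output starts
    # at the null model (mean count)
    W1 <- sample(c(-1, 1), h, replace = TRUE) * 0.7 * h
    b1 <- -W1 * seq(min(x_tr), max(x_tr), length.out = h)
    W2 <- stats::runif(h, -0.1, 0.1)
    b2 <- mean(y_tr)

    fwd <- function(x) {
      z <- outer(x, W1) + rep(b1, each = length(x))
      a1 <- 1 / (1 + exp(-z))
      list(a1 = a1, y = as.numeric(a1 %*% W2 + b2))
    }
    p <- c(W1, b1, W2, b2)
    unpack <- function(par) {
      W1 <<- par[seq_len(h)]
      b1 <<- par[h + seq_len(h)]
      W2 <<- par[2 * h + seq_len(h)]
      b2 <<- par[3 * h + 1]
    }

    lambda <- 0.01
    best <- list(mse = Inf, p = p, ep = 0L)
    stale <- 0
    ep <- 0L
    for (ep in seq_len(epochs)) {
      f <- fwd(x_tr)
      if (!all(is.finite(f$y))) {
        stop("training diverged: non-finite loss at iteration ", ep)
      }
      e <- y_tr - f$y
      sse <- sum(e^2)
      sp <- f$a1 * (1 - f$a1)
      # Jacobian of residuals wrt (W1, b1, W2, b2)
      J <- cbind(-(sp * x_tr) * rep(W2, each = n_tr),
                 -sp * rep(W2, each = n_tr),
                 -f$a1,
                 -1)
      g <- crossprod(J, e)
      jtj <- crossprod(J)
      moved <- FALSE
      for (damp in 1:30) {
        delta <- tryCatch(solve(jtj + lambda * diag(ncol(J)), -g),
                          error = function(err) NULL)
        if (!is.null(delta)) {
          p_new <- p + as.numeric(delta)
          unpack(p_new)
          sse_new <- sum((y_tr - fwd(x_tr)$y)^2)
          if (is.finite(sse_new) && sse_new < sse) {
            p <- p_new
            lambda <- max(lambda / 10, 1e-12)
            moved <- TRUE
            break
          }
        }
        lambda <- lambda * 10
        if (lambda > 1e10) break
      }
      if (!moved) {
        unpack(p)
        break
      }
      mse_va <- mean((y_va - fwd(x_va)$y)^2)
      if (mse_va < best$mse - 1e-12) {
        best <- list(mse = mse_va, p = p, ep = ep)
        stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= patience) break
      }
    }
    unpack(best$p)

    model <- structure(
      list(weights = list(matrix(W1, h, 1), matrix(W2, 1, h)),
           biases = list(matrix(b1, h, 1), matrix(b2, 1, 1)),
           hidden_sizes = h,
           input_center = ctr, input_scale = scl,
           training_meta = list(split = c(train = 0.70, validation = 0.15,
                                          test = 0.15),
                                seed = seed, epochs_run = ep,
                                best_epoch = best$ep, max_epochs = epochs,
                                patience = patience, n_pairs = n,
                                val_mse = best$mse)),
      class = "bp_model"
    )
    yhat_te <- predict(model, pairs$s_bar[te])
    metrics <- fit_metrics(fit_series(pairs$count[te], yhat_te))
    list(model = model, metrics = metrics)
  })
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf(paste0("bp_model: 1-[%s]-1 (sigmoid hidden, linear out), ",
                     "trained %d epochs on %d pairs (seed %d)\n"),
              paste(x$hidden_sizes, collapse = ","),
              x$training_meta$epochs_run, x$training_meta$n_pairs,
              x$training_meta$seed))
  invisible(x)
}

#' Serialize / restore a trained count model as JSON
#'
#' @param model a `bp_model`.
#' @param path output (input) path.
#' @return `path` invisibly; `read_bp_model()` returns the `bp_model`.
#' @export
write_bp_model <- function(model, path) {
  doc <- list(hidden_sizes = model$hidden_sizes,
              weights = model$weights,
              biases = lapply(model$biases, as.numeric),
              input_center = model$input_center,
              input_scale = model$input_scale,
              training_meta = model$training_meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bp_model
#' @export
read_bp_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(doc$weights, function(w) {
    if (is.null(dim(w))) matrix(w, nrow = 1) else w
  })
  biases <- lapply(doc$biases, function(v) matrix(v, ncol = 1))
  structure(
    list(weights = weights, biases = biases,
         hidden_sizes = doc$hidden_sizes,
         input_center = doc$input_center, input_scale = doc$input_scale,
         training_meta = doc$training_meta),
    class = "bp_model"
  )
}

#' Convert a region's area to a bird count
#'
#' With a trained model, the count is the model's prediction at the
#' normalized area, rounded half away from zero. Without one, the direct
#' normalisation rule is used: `round(s_i / s)`. Either way a region that
#' survived the minimum-area filter counts at least one bird.
#'
#' @param region a `region` (or any list with an `area` field).
#' @param ref a [estimate_reference_area()] result.
#' @param model optional `bp_model`.
#' @return integer bird count (>= 1).
#' @export
#' @examples
#' ref <- estimate_reference_area(c(50), day = 21)
#' count_region(list(area = 150), ref)  # round(3.0) = 3
#' count_region(list(area = 80), ref)   # round(1.6) = 2
count_region <- function(region, ref, model = NULL) {
  s_bar <- region$area / ref$s
  raw <- if (is.null(model)) s_bar else predict(model, s_bar)
  max(1L, as.integer(round_half_up(raw)))
}
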