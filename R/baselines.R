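# Clustering segmentation baselines: k-means and fuzzy c-means on per-pixel
# RGB vectors, used for method comparison against the two-dimensional Otsu
# pipeline. Informational timing only — clustering speed is hardware-bound.

# Pick the "bird" cluster: the centre farthest (Euclidean, RGB) from the
# median pen colour — same polarity reasoning as apply_threshold(): birds
# are the minority class and differ most from the litter-dominated median.
bird_cluster <- function(centers, med) {
  d <- sqrt(rowSums(sweep(centers, 2, med)^2))
  which.max(d)
}

pixel_matrix <- function(image) {
  keep <- which(image$roi)
  cbind(R = image$pixels[, , 1][keep],
        G = image$pixels[, , 2][keep],
        B = image$pixels[, , 3][keep])
}

labels_to_mask <- function(labels, fg, image) {
  keep <- which(image$roi)
  m <- matrix(FALSE, nrow(image$roi), ncol(image$roi))
  m[keep] <- labels == fg
  m
}

# Seeded initial centres: k distinct pixel values (padded with jitter when
# the image has fewer distinct colours than clusters).
init_centers <- function(X, k, seed) {
  with_seed(seed, {
    ux <- unique(X)
    if (nrow(ux) >= k) {
      ux[sample(nrow(ux), k), , drop = FALSE]
    } else {
      extra <- ux[sample(nrow(ux), k - nrow(ux), replace = TRUE), ,
                  drop = FALSE] + matrix(stats::runif((k - nrow(ux)) * 3),
                                         ncol = 3)
      rbind(ux, extra)
    }
  })
}

#' K-means segmentation baseline
#'
#' Lloyd's algorithm (via [stats::kmeans()]) on per-pixel RGB vectors with
#' seeded initial centres; the bird cluster is the one whose centre lies
#' farthest from the median pen colour. If a cluster empties during
#' iteration, the fit is restarted with a fresh seeded initialisation that
#' includes the pixel farthest from the current centres.
#'
#' @param image a [frame_image()].
#' @param k number of clusters (>= 2); default 3 (birds, litter,
#'   equipment).
#' @param seed integer seed controlling initialisation.
#' @param max_iter maximum Lloyd iterations.
#' @param tol unused by Lloyd's integer-assignment convergence; kept for
#'   interface symmetry with [fcm_segment()].
#' @return `list(result, mask)`: a `clustering_result` (fields `labels`
#'   H x W integer with 0 outside the roi, `centers`, `iterations`,
#'   `converged`, `objective`) and a `binary_mask` of the bird cluster.
#' @export
kmeans_segment <- function(image, k = 3, seed = 1, max_iter = 100,
                           tol = 1e-4) {
  stopifnot(k >= 2)
  X <- pixel_matrix(image)
  centers <- init_centers(X, k, seed)
  fit <- NULL
  for (attempt in 1:5) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = centers,
                                     iter.max = max_iter,
                                     algorithm = "Lloyd")),
      error = function(e) e
    )
    if (!inherits(fit, "error")) break
    # empty-cluster rule: re-seed, forcing in the pixel farthest from the
    # current centres
    d2 <- apply(centers, 1, function(ce) colSums((t(X) - ce)^2))
    far <- which.max(apply(d2, 1, min))
    centers <- init_centers(X, k, seed + attempt)
    centers[1, ] <- X[far, ]
  }
  if (inherits(fit, "error")) stop("k-means failed: ", fit$message)
  med <- apply(X, 2, stats::median)
  fg <- bird_cluster(fit$centers, med)
  labels <- matrix(0L, nrow(image$roi), ncol(image$roi))
  labels[which(image$roi)] <- fit$cluster - 1L
  result <- structure(
    list(labels = labels, centers = fit$centers, iterations = fit$iter,
         converged = fit$iter < max_iter, objective = fit$tot.withinss,
         objective_trace = NULL),
    class = "clustering_result"
  )
  mask <- structure(
    list(mask = labels_to_mask(fit$cluster, fg, image),
         provenance = list(method = "kmeans", k = k, seed = seed)),
    class = "binary_mask"
  )
  list(result = result, mask = mask)
}

#' Fuzzy c-means segmentation baseline
#'
#' Standard FCM alternating updates on per-pixel RGB vectors: memberships
#' `u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1))`, centres as
#' membership^m-weighted means. A pixel at zero distance from a centre gets
#' full membership in that centre. Iteration stops when the largest centre
#' shift falls below `tol` or after `max_iter` rounds. The mask is the
#' maximum-membership defuzzification of the bird cluster (farthest centre
#' from the median pen colour).
#'
#' @param image a [frame_image()].
#' @param c_clusters number of clusters (>= 2); default 3.
#' @param m fuzzifier (> 1); default 2.
#' @param seed integer seed for the initial centres.
#' @param max_iter,tol convergence controls.
#' @return `list(result, mask)` as in [kmeans_segment()]; `result` also
#'   carries `objective_trace`, the fuzzy objective after every iteration
#'   (non-increasing), and `membership` (n x c).
#' @export
fcm_segment <- function(image, c_clusters = 3, m = 2, seed = 1,
                        max_iter = 100, tol = 1e-4) {
  stopifnot(c_clusters >= 2, m > 1)
  X <- pixel_matrix(image)
  n <- nrow(X)
  centers <- init_centers(X, c_clusters, seed)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  U <- NULL
  memberships <- function(centers) {
    d2 <- vapply(seq_len(c_clusters), function(j) {
      rowSums(sweep(X, 2, centers[j, ])^2)
    }, numeric(n))
    d2 <- pmax(d2, 0)
    pw <- d2^(1 / (m - 1))
    U <- 1 / (pw * rowSums(1 / pmax(pw, .Machine$double.xmin)))
    zero <- d2 <= 0
    if (any(zero)) {
      rows <- which(rowSums(zero) > 0)
      U[rows, ] <- 0
      U[cbind(rows, max.col(-d2[rows, , drop = FALSE]))] <- 1
    }
    list(U = U, d2 = d2)
  }
  for (iter in seq_len(max_iter)) {
    mu <- memberships(centers)
    U <- mu$U
    trace <- c(trace, sum(U^m * mu$d2))
    Um <- U^m
    new_centers <- t(vapply(seq_len(c_clusters), function(j) {
      w <- Um[, j]
      colSums(X * w) / sum(w)
    }, numeric(3)))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- memberships(centers)
  U <- mu$U
  cl <- max.col(U)
  med <- apply(X, 2, stats::median)
  fg <- bird_cluster(centers, med)
  labels <- matrix(0L, nrow(image$roi), ncol(image$roi))
  labels[which(image$roi)] <- cl - 1L
  result <- structure(
    list(labels = labels, centers = centers, iterations = iter,
         converged = converged, objective = sum(U^m * mu$d2),
         objective_trace = trace, membership = U),
    class = "clustering_result"
  )
  mask <- structure(
    list(mask = labels_to_mask(cl, fg, image),
         provenance = list(method = "fcm", c = c_clusters, m = m,
                           seed = seed)),
    class = "binary_mask"
  )
  list(result = result, mask = mask)
}

#' Wall-clock timing of segmentation methods
#'
#' Runs each method on each frame and records elapsed seconds. Purely
#' informational: clustering speed depends on the hardware and is never
#' asserted against.
#'
#' @param images list of [frame_image()].
#' @param methods character vector among `"otsu2d"`, `"kmeans"`, `"fcm"`;
#'   each runs with its default parameters.
#' @return data.frame with columns `frame_id`, `method`, `seconds`.
#' @export
timing_harness <- function(images, methods = c("otsu2d", "kmeans", "fcm")) {
  stopifnot(length(images) >= 1)
  runs <- list(
    otsu2d = function(im) segment_frame(im),
    kmeans = function(im) kmeans_segment(im),
    fcm = function(im) fcm_segment(im)
  )
  out <- expand.grid(frame_id = vapply(images, function(im) im$frame_id,
                                       character(1)),
                     method = methods, stringsAsFactors = FALSE)
  out$seconds <- NA_real_
  for (r in seq_len(nrow(out))) {
    im <- images[[match(out$frame_id[r],
                        vapply(images, function(i) i$frame_id,
                               character(1)))]]
    out$seconds[r] <- unname(system.time(runs[[out$method[r]]](im))["elapsed"])
  }
  out
}
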