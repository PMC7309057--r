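#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so `round_half_up(2.5)` is 3 and `round_half_up(-2.5)` is -3), unlike
#' [base::round()]'s round-half-to-even. All reported rates and all
#' area-to-count conversions in this package use this rule so that `.5`
#' boundaries behave predictably.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, -1.5))
#' round_half_up(3 / 671, 4)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shift a logical matrix by (dy, dx), padding with FALSE.
shift_logical <- function(m, dy, dx) {
  H <- nrow(m)
  W <- ncol(m)
  out <- matrix(FALSE, H, W)
  ys <- max(1, 1 - dy):min(H, H - dy)
  xs <- max(1, 1 - dx):min(W, W - dx)
  if (length(ys) > 0 && length(xs) > 0) {
    out[ys, xs] <- m[ys + dy, xs + dx]
  }
  out
}

# Binary erosion with a Euclidean disc structuring element: the set of
# offsets (dy, dx) with dy^2 + dx^2 <= radius^2. radius = 1 is the
# 4-neighbourhood cross. Pixels beyond the image border count as background.
erode_disc <- function(mask, radius) {
  if (radius <= 0) {
    return(mask)
  }
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  out <- mask
  for (k in seq_len(nrow(offs))) {
    if (offs$dy[k] == 0 && offs$dx[k] == 0) next
    out <- out & shift_logical(mask, offs$dy[k], offs$dx[k])
  }
  out
}

# Label 8-connected components of a logical matrix. Returns an integer
# matrix (0 = background). Implementation: row runs + union-find, so the
# cost is linear in the number of runs rather than pixels^2.
label_components <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  lab <- matrix(0L, H, W)
  # collect foreground runs per row
  row_id <- integer(0)
  run_s <- integer(0)
  run_e <- integer(0)
  runs_per_row <- vector("list", H)
  for (y in seq_len(H)) {
    r <- rle(mask[y, ])
    if (!any(r$values)) {
      runs_per_row[[y]] <- integer(0)
      next
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    idx <- length(row_id) + seq_along(keep)
    runs_per_row[[y]] <- idx
    row_id <- c(row_id, rep.int(y, length(keep)))
    run_s <- c(run_s, starts[keep])
    run_e <- c(run_e, ends[keep])
  }
  n_runs <- length(row_id)
  if (n_runs == 0L) {
    return(lab)
  }
  parent <- seq_len(n_runs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (y in 2:H) {
    if (H < 2) break
    above <- runs_per_row[[y - 1]]
    here <- runs_per_row[[y]]
    if (length(above) == 0 || length(here) == 0) next
    for (i in here) {
      for (j in above) {
        # 8-connectivity: runs touch if column ranges overlap when the
        # upper run is widened by one pixel on each side
        if (run_s[i] <= run_e[j] + 1L && run_e[i] >= run_s[j] - 1L) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n_runs), find, integer(1))
  comp <- match(roots, unique(roots))
  for (k in seq_len(n_runs)) {
    lab[row_id[k], run_s[k]:run_e[k]] <- comp[k]
  }
  lab
}

# md5 checksum of a file, used for run manifests.
file_checksum <- function(path) unname(tools::md5sum(path))
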