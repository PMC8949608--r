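# Bead recovery from grayscale frames: Hough-gradient circle detection and
# the per-frame distance feature.

#' Hough circle detector parameters
#'
#' The four tunables of the gradient-vote circle detector, mirroring the
#' conventional (OpenCV-style) parameterization: an edge threshold, a centre
#' accumulator threshold, and radius bounds. The defaults were tuned once
#' against the package's synthetic frame renderer and suit high-contrast disks
#' a few pixels in radius.
#'
#' @param param_1 Edge threshold on the Sobel gradient magnitude, expressed on
#'   a 0-255 intensity scale (default 50).
#' @param param_2 Centre accumulator threshold: minimum gradient votes for an
#'   accepted centre (default 100; votes are summed over a 3 x 3
#   neighbourhood, so a well-rendered disk of radius 3-5 px scores well above
#   150 while line-edge artifacts stay under 60).
#' @param min_radius,max_radius Radius bounds in pixels.
#' @param min_dist Minimum separation between accepted centres (px); defaults
#'   to `min_radius`.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(param_1 = 50, param_2 = 100,
                            min_radius = 1, max_radius = 6,
                            min_dist = NULL) {
  check_scalar(param_1, "param_1", lower = 0, strict = TRUE)
  check_scalar(param_2, "param_2", lower = 0, strict = TRUE)
  check_scalar(min_radius, "min_radius", lower = 0, strict = TRUE)
  check_scalar(max_radius, "max_radius", lower = min_radius)
  if (is.null(min_dist)) min_dist <- min_radius
  check_scalar(min_dist, "min_dist", lower = 0, strict = TRUE)
  structure(list(param_1 = param_1, param_2 = param_2,
                 min_radius = min_radius, max_radius = max_radius,
                 min_dist = min_dist),
            class = "detector_params")
}

# detector matched to the rendered bead size: radius bounds = rendered bead
# radius -/+ 2 px
detector_for_geometry <- function(geometry, radius_um = 1.5,
                                  param_1 = 50, param_2 = 100) {
  r_px <- radius_um / geometry$um_per_px
  detector_params(param_1 = param_1, param_2 = param_2,
                  min_radius = max(1, floor(r_px - 2)),
                  max_radius = ceiling(r_px + 2))
}

#' Detect circular particles in a grayscale frame
#'
#' Hough Gradient Method: Sobel gradients are computed on the (lightly
#' smoothed) image; every pixel whose gradient magnitude exceeds `param_1`
#' votes for candidate centres along its gradient direction, both ways, at
#' every radius in `[min_radius, max_radius]`. Accumulator peaks with at least
#' `param_2` votes become centres (greedy non-maximum suppression at
#' `min_dist`); each centre's radius is the modal edge-pixel distance. The
#' result is deterministic for a fixed frame and parameters; an empty result
#' is valid. Multi-channel input is converted to grayscale by channel
#' averaging first.
#'
#' @param frame Numeric matrix in \[0, 1\] (or 3-D array, converted to gray).
#' @param params A [detector_params()].
#' @return A tibble with columns `x_px`, `y_px` (0-based pixel coordinates of
#'   centres), `radius_px`, `votes`, ordered by decreasing votes.
#' @export
detect_particles <- function(frame, params = detector_params()) {
  frame <- to_gray(frame)
  if (!is.matrix(frame) || any(dim(frame) < 3)) {
    stop("`frame` must be a grayscale matrix of at least 3 x 3 pixels",
         call. = FALSE)
  }
  img <- gaussian_blur(frame, 1)
  h <- nrow(img); w <- ncol(img)

  # Sobel gradients (x = columns rightward, y = rows downward)
  p <- pad_replicate(img)
  i <- 2:(h + 1); j <- 2:(w + 1)
  gx <- (p[i - 1, j + 1] + 2 * p[i, j + 1] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i, j - 1] + p[i + 1, j - 1])
  gy <- (p[i + 1, j - 1] + 2 * p[i + 1, j] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i - 1, j] + p[i - 1, j + 1])
  mag <- sqrt(gx^2 + gy^2)

  edge <- which(mag * 255 >= params$param_1)
  empty <- tibble::tibble(x_px = numeric(0), y_px = numeric(0),
                          radius_px = numeric(0), votes = numeric(0))
  if (length(edge) == 0) return(empty)
  ey <- (edge - 1) %% h          # 0-based row
  ex <- (edge - 1) %/% h         # 0-based col
  ux <- gx[edge] / mag[edge]
  uy <- gy[edge] / mag[edge]

  # accumulate centre votes along the gradient line, both directions
  acc <- numeric(h * w)
  radii <- seq(params$min_radius, params$max_radius)
  for (d in radii) {
    for (s in c(-1, 1)) {
      cx <- round(ex + s * d * ux)
      cy <- round(ey + s * d * uy)
      ok <- cx >= 0 & cx < w & cy >= 0 & cy < h
      if (!any(ok)) next
      idx <- cy[ok] + cx[ok] * h + 1
      acc <- acc + tabulate(idx, nbins = h * w)
    }
  }
  accm <- matrix(acc, nrow = h)
  # concentrate rounding-scattered votes before peak picking
  accs <- box_sum3(accm)

  peaks <- local_maxima(accs, params$param_2)
  if (nrow(peaks) == 0) return(empty)
  peaks <- peaks[order(-peaks$votes, peaks$y, peaks$x), , drop = FALSE]

  # greedy non-maximum suppression
  keep <- logical(nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    sel <- peaks[keep, , drop = FALSE]
    d2 <- (sel$x - peaks$x[k])^2 + (sel$y - peaks$y[k])^2
    keep[k] <- all(d2 >= params$min_dist^2)
  }
  peaks <- peaks[keep, , drop = FALSE]

  # radius = modal distance of supporting edge pixels (ties -> smaller radius)
  rad <- vapply(seq_len(nrow(peaks)), function(k) {
    dd <- round(sqrt((ex - peaks$x[k])^2 + (ey - peaks$y[k])^2))
    dd <- dd[dd >= params$min_radius & dd <= params$max_radius]
    if (length(dd) == 0) return(params$min_radius)
    tab <- tabulate(dd + 1)
    which.max(tab) - 1
  }, numeric(1))

  tibble::tibble(x_px = peaks$x, y_px = peaks$y,
                 radius_px = rad, votes = peaks$votes)
}

pad_replicate <- function(m) {
  m <- rbind(m[1, ], m, m[nrow(m), ])
  cbind(m[, 1], m, m[, ncol(m)])
}

# 3x3 box sum with zero-padded borders
box_sum3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  z <- matrix(0, h + 2, w + 2)
  z[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + z[(1 + di):(h + di), (1 + dj):(w + dj)]
  }
  out
}

# strict local maxima (ties resolved toward the top-left) above a threshold;
# returns 0-based coordinates
local_maxima <- function(m, threshold) {
  h <- nrow(m); w <- ncol(m)
  z <- matrix(-Inf, h + 2, w + 2)
  z[2:(h + 1), 2:(w + 1)] <- m
  ge <- function(di, dj) z[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)]
  is_peak <- m >= threshold &
    m >  ge(0, 1) & m >  ge(1, 0) & m >  ge(1, 1) & m >  ge(1, -1) &
    m >= ge(0, -1) & m >= ge(-1, 0) & m >= ge(-1, -1) & m >= ge(-1, 1)
  idx <- which(is_peak)
  data.frame(x = (idx - 1) %/% h, y = (idx - 1) %% h, votes = m[idx])
}

#' Per-frame distance feature of a detection result
#'
#' The mean absolute distance of detected centres to the reference line:
#' `X = mean(|x_n - ref_x|)`. Only x-coordinates enter; the y-coordinates and
#' the ordering of the detections are irrelevant. An empty detection result
#' yields a flagged missing feature, not an error.
#'
#' @param result Detection tibble from [detect_particles()] (or any data frame
#'   with an `x_px` column).
#' @param ref_x Reference-line x-coordinate, in the same units as `x_px`.
#' @return A one-row tibble with columns `value`, `n`, `missing`.
#' @export
extract_feature <- function(result, ref_x) {
  check_scalar(ref_x, "ref_x")
  n <- nrow(result)
  if (n == 0) {
    return(tibble::tibble(value = NA_real_, n = 0L, missing = TRUE))
  }
  tibble::tibble(value = mean(abs(result$x_px - ref_x)), n = as.integer(n),
                 missing = FALSE)
}
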