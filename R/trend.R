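# Watching window maintenance and macroscopic motion labelling: imputation,
# smoothing, least-squares trend, threshold classification.

#' Trend-analysis parameters
#'
#' @param k Watching-window length in frames (default 30). The window is a
#'   first-in first-out queue holding the `k` most recent features.
#' @param u Span used both for missing-value imputation (mean of the `u` most
#'   recent observed features) and as the moving-average smoothing kernel
#'   length (default 5).
#' @param delta Decision threshold on the absolute trend slope, in
#'   feature-units per frame (default 0.05). Slopes with `|b| <= delta` are
#'   classified as no net motion.
#' @param polarity_flip Swap the two DEP labels to match setups where rising
#'   features mean repulsion (default `FALSE`).
#' @return An object of class `trend_params`.
#' @export
trend_params <- function(k = 30, u = 5, delta = 0.05, polarity_flip = FALSE) {
  check_scalar(k, "k", lower = 2)
  check_scalar(u, "u", lower = 1)
  if (u > k) stop("`u` must not exceed `k`", call. = FALSE)
  check_scalar(delta, "delta", lower = 0)
  stopifnot(is.logical(polarity_flip), length(polarity_flip) == 1)
  structure(list(k = as.integer(k), u = as.integer(u), delta = delta,
                 polarity_flip = polarity_flip),
            class = "trend_params")
}

#' Create an empty watching window
#'
#' A FIFO buffer of at most `k` per-frame features, with a parallel record of
#' which entries were imputed.
#'
#' @param k Window capacity (frames).
#' @param u Imputation/smoothing span, `u <= k`.
#' @return An object of class `watch_window`.
#' @export
watch_window <- function(k = 30, u = 5) {
  check_scalar(k, "k", lower = 2)
  check_scalar(u, "u", lower = 1)
  if (u > k) stop("`u` must not exceed `k`", call. = FALSE)
  structure(list(values = numeric(0), imputed = logical(0),
                 k = as.integer(k), u = as.integer(u)),
            class = "watch_window")
}

#' Impute a missing feature from recent observations
#'
#' When a frame yields no detections, the missing feature is sampled as the
#' arithmetic mean of the `u` most recent non-missing (non-imputed) features.
#'
#' @param window A [watch_window()].
#' @return The imputed value, or `NA_real_` when no prior observed feature
#'   exists (the window is not ready and the frame should be skipped).
#' @export
impute_missing <- function(window) {
  obs <- window$values[!window$imputed]
  if (length(obs) == 0) return(NA_real_)
  mean(utils::tail(obs, window$u))
}

#' Push one feature into the window
#'
#' Missing features are imputed via [impute_missing()]; when imputation is
#' impossible (no prior observation) the frame is skipped and the window is
#' returned unchanged with `attr(, "skipped") = TRUE`. The oldest entry is
#' evicted once the window exceeds its capacity.
#'
#' @param window A [watch_window()].
#' @param value Feature value (ignored when `missing = TRUE`).
#' @param missing Whether the frame produced no feature.
#' @return The updated `watch_window`.
#' @export
window_push <- function(window, value, missing = FALSE) {
  imput <- FALSE
  if (isTRUE(missing) || is.na(value)) {
    value <- impute_missing(window)
    if (is.na(value)) {
      attr(window, "skipped") <- TRUE
      return(window)
    }
    imput <- TRUE
  }
  window$values <- c(window$values, value)
  window$imputed <- c(window$imputed, imput)
  if (length(window$values) > window$k) {
    window$values <- window$values[-1]
    window$imputed <- window$imputed[-1]
  }
  attr(window, "skipped") <- FALSE
  window
}

#' Is the window full?
#'
#' @param window A [watch_window()].
#' @return `TRUE` once the window holds `k` features.
#' @export
window_ready <- function(window) {
  length(window$values) >= window$k
}

#' Moving-average smoothing with an unweighted kernel
#'
#' Linear convolution of the series with an all-ones kernel of length `u`
#' normalized by `u`. The output has the same length as the input; boundaries
#' are handled by edge replication so no fabricated zeros enter the window
#' ends. `u = 1` is the identity.
#'
#' @param x Numeric series.
#' @param u Kernel length (>= 1).
#' @return Smoothed series, same length as `x`.
#' @export
smooth_series <- function(x, u) {
  check_scalar(u, "u", lower = 1)
  u <- as.integer(u)
  n <- length(x)
  if (n == 0 || u == 1L) return(x)
  l <- (u - 1L) %/% 2L
  r <- u - 1L - l
  xp <- c(rep(x[1], l), x, rep(x[n], r))
  vapply(seq_len(n), function(i) mean(xp[i:(i + u - 1L)]), numeric(1))
}

#' Least-squares trend slope
#'
#' Fits the linear trend model through the points `(i, x_i)` with abscissae
#' taken as frame offsets `0, 1, ..., n-1` and returns the slope
#' `b = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2)`, in feature-units per
#' frame.
#'
#' @param y Ordered feature series (>= 2 points).
#' @return The slope `b`, or `NA_real_` when fewer than 2 points are supplied
#'   (not ready).
#' @export
fit_trend <- function(y) {
  n <- length(y)
  if (n < 2) return(NA_real_)
  x <- seq_len(n) - 1
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Classify the macroscopic particle motion
#'
#' `|b| <= delta` is labelled `NO_DEP` (inclusive boundary). Otherwise, under
#' the default convention a rising distance feature (`b > 0`) means motion
#' toward the electrode edges, i.e. attraction, labelled `POSITIVE_DEP`, and
#' `b < 0` labelled `NEGATIVE_DEP`. `polarity_flip` swaps the two DEP labels
#' for setups with the opposite feature convention.
#'
#' @param b Trend slope (feature-units per frame).
#' @param delta Decision threshold (>= 0).
#' @param polarity_flip Swap `POSITIVE_DEP` and `NEGATIVE_DEP`.
#' @return One of `"POSITIVE_DEP"`, `"NEGATIVE_DEP"`, `"NO_DEP"`.
#' @export
classify_trend <- function(b, delta, polarity_flip = FALSE) {
  check_scalar(delta, "delta", lower = 0)
  if (is.na(b)) return(NA_character_)
  if (abs(b) <= delta) return("NO_DEP")
  lab <- if (b > 0) "POSITIVE_DEP" else "NEGATIVE_DEP"
  if (isTRUE(polarity_flip)) {
    lab <- if (lab == "POSITIVE_DEP") "NEGATIVE_DEP" else "POSITIVE_DEP"
  }
  lab
}

#' Analyze a watching window
#'
#' Impute-then-smooth-then-fit: the window contents (already imputed on
#' insertion) are smoothed with the unweighted length-`u` kernel, the
#' least-squares slope is fitted, and the motion is classified against
#' `delta`.
#'
#' @param window A [watch_window()].
#' @param params A [trend_params()].
#' @return A one-row tibble with columns `b`, `delta`, `label`,
#'   `smoothed_last` (the smoothed value at the window's newest position).
#' @export
analyze_window <- function(window, params) {
  sm <- smooth_series(window$values, params$u)
  b <- fit_trend(sm)
  tibble::tibble(
    b = b, delta = params$delta,
    label = classify_trend(b, params$delta, params$polarity_flip),
    smoothed_last = if (length(sm)) sm[length(sm)] else NA_real_
  )
}
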