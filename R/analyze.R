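# Offline analysis of a recorded frame sequence: detection + trend, no
# controller in the loop.

#' Analyze a frame sequence offline
#'
#' Runs the detection and trend pipeline over an existing grayscale frame
#' sequence (a directory of numbered PNGs, a TIFF stack, or a list of
#' matrices) without any feedback control: per frame, particles are detected,
#' the distance feature extracted, the watching window maintained (with
#' imputation of missing frames), and — once the window is full — the smoothed
#' least-squares slope and motion label computed.
#'
#' @param frames A path accepted by [read_frames()], or a list of matrices.
#' @param ref_x_px Reference-line x-coordinate in pixels.
#' @param detect A [detector_params()].
#' @param trend A [trend_params()].
#' @param um_per_px Spatial scale; features are reported in microns
#'   (`feature_px * um_per_px`). Use 1 to stay in pixels.
#' @return A tibble (one row per frame) with columns `frame`, `n_detected`,
#'   `x_feature`, `imputed_flag`, `smoothed_feature`, `slope_b`, `label`.
#' @export
analyze_frames <- function(frames, ref_x_px,
                           detect = detector_params(),
                           trend = trend_params(),
                           um_per_px = 1) {
  if (is.character(frames)) frames <- read_frames(frames)
  stopifnot(is.list(frames), length(frames) >= 1)
  win <- watch_window(trend$k, trend$u)
  rows <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    det <- detect_particles(frames[[t]], detect)
    f <- extract_feature(det, ref_x_px)
    val <- f$value * um_per_px
    win <- window_push(win, val, missing = f$missing)
    skipped <- isTRUE(attr(win, "skipped"))
    b <- NA_real_; label <- NA_character_; smoothed <- NA_real_
    if (!skipped && window_ready(win)) {
      res <- analyze_window(win, trend)
      b <- res$b; label <- res$label; smoothed <- res$smoothed_last
    }
    rows[[t]] <- tibble::tibble(
      frame = t, n_detected = f$n, x_feature = val,
      imputed_flag = if (skipped) NA else
        (length(win$imputed) > 0 && win$imputed[length(win$imputed)]),
      smoothed_feature = smoothed, slope_b = b, label = label)
  }
  dplyr::bind_rows(rows)
}
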