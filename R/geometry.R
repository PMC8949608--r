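# Interdigitated electrode array (IDEA) geometry and the imaged field of view.

#' Interdigitated-electrode geometry and imaging scale
#'
#' Describes the electrode array (parallel vertical finger electrodes separated
#' by uniform gaps) and the camera field of view used by the simulator and the
#' renderer. Finger `i` (1-based) spans
#' `[(i-1)*(finger_width_um + gap_um), (i-1)*(...) + finger_width_um]` along x;
#' the field of view is centred on the reference line, a vertical line through
#' the midline of the central gap (the line used by the distance feature).
#'
#' @param n_fingers Number of electrode fingers (default 12).
#' @param gap_um Gap between adjacent fingers (um, default 70).
#' @param finger_width_um Electrode finger width (um, default 30).
#' @param um_per_px Spatial scale of rendered frames (um per pixel, default 1).
#' @param fov_w_um,fov_h_um Field-of-view size (um). Default width covers the
#'   central gap plus one finger width on each side.
#' @param ref_x_um Reference-line x-coordinate (um). Default: midline of the
#'   central gap. Must lie strictly inside a gap.
#' @return An object of class `electrode_geometry`.
#' @examples
#' geo <- electrode_geometry()
#' geo$ref_x_um
#' @export
electrode_geometry <- function(n_fingers = 12, gap_um = 70,
                               finger_width_um = 30, um_per_px = 1,
                               fov_w_um = NULL, fov_h_um = 100,
                               ref_x_um = NULL) {
  check_scalar(n_fingers, "n_fingers", lower = 2)
  if (n_fingers != round(n_fingers)) stop("`n_fingers` must be an integer", call. = FALSE)
  check_scalar(gap_um, "gap_um", lower = 0, strict = TRUE)
  check_scalar(finger_width_um, "finger_width_um", lower = 0, strict = TRUE)
  check_scalar(um_per_px, "um_per_px", lower = 0, strict = TRUE)
  if (is.null(fov_w_um)) fov_w_um <- gap_um + 2 * finger_width_um
  check_scalar(fov_w_um, "fov_w_um", lower = 0, strict = TRUE)
  check_scalar(fov_h_um, "fov_h_um", lower = 0, strict = TRUE)

  pitch <- finger_width_um + gap_um
  fingers <- cbind(xL = (seq_len(n_fingers) - 1) * pitch,
                   xR = (seq_len(n_fingers) - 1) * pitch + finger_width_um)
  gaps <- cbind(xL = fingers[-n_fingers, "xR"], xR = fingers[-1, "xL"])
  ref_gap <- ceiling((n_fingers - 1) / 2)
  if (is.null(ref_x_um)) {
    ref_x_um <- mean(gaps[ref_gap, ])
  }
  check_scalar(ref_x_um, "ref_x_um")
  inside <- ref_x_um > gaps[, "xL"] & ref_x_um < gaps[, "xR"]
  if (!any(inside)) {
    stop("`ref_x_um` must lie strictly inside an electrode gap", call. = FALSE)
  }

  fov_x0 <- ref_x_um - fov_w_um / 2
  structure(
    list(n_fingers = n_fingers, gap_um = gap_um,
         finger_width_um = finger_width_um, um_per_px = um_per_px,
         fov_w_um = fov_w_um, fov_h_um = fov_h_um,
         ref_x_um = ref_x_um, ref_gap = which(inside)[1],
         fingers = fingers, gaps = gaps,
         fov_x0_um = fov_x0,
         frame_w_px = as.integer(round(fov_w_um / um_per_px)),
         frame_h_px = as.integer(round(fov_h_um / um_per_px))),
    class = "electrode_geometry"
  )
}

#' @export
print.electrode_geometry <- function(x, ...) {
  cat("<electrode_geometry>\n")
  cat(sprintf("  %d fingers, width %g um, gaps %g um\n",
              x$n_fingers, x$finger_width_um, x$gap_um))
  cat(sprintf("  reference line at x = %g um (gap %d)\n", x$ref_x_um, x$ref_gap))
  cat(sprintf("  field of view %g x %g um -> %d x %d px (%g um/px)\n",
              x$fov_w_um, x$fov_h_um, x$frame_w_px, x$frame_h_px, x$um_per_px))
  invisible(x)
}

#' Electrode edge x-coordinates
#'
#' @param geometry An [electrode_geometry()].
#' @return Sorted vector of all finger edge x-positions (um).
#' @export
electrode_edges <- function(geometry) {
  sort(as.numeric(geometry$fingers))
}

# Bounds of the gap containing each x (um). Rows of NA where x lies over an
# electrode finger or outside the array.
gap_bounds <- function(geometry, x_um) {
  g <- geometry$gaps
  idx <- findInterval(x_um, as.vector(t(g)))  # interleaved xL1,xR1,xL2,...
  in_gap <- idx %% 2 == 1
  row <- (idx + 1) %/% 2
  xL <- ifelse(in_gap, g[pmax(row, 1), "xL"], NA_real_)
  xR <- ifelse(in_gap, g[pmax(row, 1), "xR"], NA_real_)
  cbind(xL = xL, xR = xR)
}

# pixel-centre <-> micron conversions for the field of view (0-based pixels,
# x rightward, y downward, pixel (0,0) at top-left)
px_to_um_x <- function(geometry, x_px) geometry$fov_x0_um + (x_px + 0.5) * geometry$um_per_px
um_to_px_x <- function(geometry, x_um) (x_um - geometry$fov_x0_um) / geometry$um_per_px - 0.5
px_to_um_y <- function(geometry, y_px) (y_px + 0.5) * geometry$um_per_px
um_to_px_y <- function(geometry, y_um) y_um / geometry$um_per_px - 0.5
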