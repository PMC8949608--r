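# Virtual testbed: phenomenological field model and overdamped bead dynamics.

#' Function-generator drive settings
#'
#' @param freq_hz Applied AC frequency (Hz, > 0).
#' @param vpp Peak-to-peak voltage (V, > 0, default 3).
#' @return An object of class `drive_state`.
#' @export
drive_state <- function(freq_hz, vpp = 3) {
  check_scalar(freq_hz, "freq_hz", lower = 0, strict = TRUE)
  check_scalar(vpp, "vpp", lower = 0, strict = TRUE)
  structure(list(freq_hz = freq_hz, vpp = vpp), class = "drive_state")
}

#' Simulation configuration
#'
#' Physical and numerical settings of the virtual testbed. The field-squared
#' profile decays exponentially away from the electrode edges with length
#' `decay_um` (default half the gap). Brownian noise, when enabled, applies
#' independent Gaussian steps of variance `2 D dt` per axis with
#' `D = kB T / (6 pi eta R)`.
#'
#' @param eta Medium dynamic viscosity (Pa s, default 1e-3, water at ~20 C).
#' @param temp_k Temperature for Brownian noise (K, default 298).
#' @param dt_s Time step, the reciprocal frame rate (s, default 0.1 = 10 fps).
#' @param decay_um Field decay length lambda (um); `NULL` resolves to half the
#'   electrode gap at run time.
#' @param noise_on Enable Brownian noise (default `FALSE`).
#' @param seed Optional RNG seed recorded with the run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(eta = 1e-3, temp_k = 298, dt_s = 0.1,
                       decay_um = NULL, noise_on = FALSE, seed = NULL) {
  check_scalar(eta, "eta", lower = 0, strict = TRUE)
  check_scalar(temp_k, "temp_k", lower = 0, strict = TRUE)
  check_scalar(dt_s, "dt_s", lower = 0, strict = TRUE)
  if (!is.null(decay_um)) check_scalar(decay_um, "decay_um", lower = 0, strict = TRUE)
  if (!is.null(seed)) check_scalar(seed, "seed")
  stopifnot(is.logical(noise_on), length(noise_on) == 1)
  structure(list(eta = eta, temp_k = temp_k, dt_s = dt_s,
                 decay_um = decay_um, noise_on = noise_on, seed = seed),
            class = "sim_config")
}

resolve_decay_um <- function(config, geometry) {
  if (is.null(config$decay_um)) geometry$gap_um / 2 else config$decay_um
}

#' Initial bead population
#'
#' Draws bead centres uniformly inside the reference gap (x) and across the
#' field of view (y), keeping a small margin from the electrode edges. Bead
#' positions are in microns in array coordinates.
#'
#' @param geometry An [electrode_geometry()].
#' @param n Number of beads (default 40).
#' @param radius_um Bead radius (um, default 1.5, i.e. 3-um-diameter beads).
#' @param margin_um Margin kept from gap edges and frame borders (um).
#' @return A tibble with columns `bead_id`, `x_um`, `y_um`, `radius_um`.
#' @export
init_beads <- function(geometry, n = 40, radius_um = 1.5, margin_um = 1) {
  check_scalar(n, "n", lower = 1)
  check_scalar(radius_um, "radius_um", lower = 0, strict = TRUE)
  g <- geometry$gaps[geometry$ref_gap, ]
  tibble::tibble(
    bead_id = seq_len(n),
    x_um = stats::runif(n, g[["xL"]] + margin_um, g[["xR"]] - margin_um),
    y_um = stats::runif(n, margin_um, geometry$fov_h_um - margin_um),
    radius_um = radius_um
  )
}

#' Squared-field profile across the electrode gaps
#'
#' Phenomenological 1-D model of the field between interdigitated fingers:
#' `E^2(x) = (vpp / (2 gap))^2 * exp(-d / lambda)` where `d` is the distance
#' to the nearest electrode edge of the enclosing gap and `lambda` the decay
#' length. `E^2` is maximal at the edges and minimal at the gap midline.
#' Over an electrode finger or outside the array the profile is zero.
#'
#' @param geometry An [electrode_geometry()].
#' @param drive A [drive_state()].
#' @param x_um Positions (um); vectorized.
#' @param decay_um Decay length lambda (um, default half the gap).
#' @return `E^2` in V^2/m^2.
#' @seealso [grad_e2_profile()] for its signed spatial derivative.
#' @export
field_e2_profile <- function(geometry, drive, x_um,
                             decay_um = geometry$gap_um / 2) {
  gb <- gap_bounds(geometry, x_um)
  d_um <- pmin(x_um - gb[, "xL"], gb[, "xR"] - x_um)
  gap_m <- geometry$gap_um * 1e-6
  a2 <- (drive$vpp / (2 * gap_m))^2
  out <- a2 * exp(-d_um / decay_um)
  out[is.na(d_um)] <- 0
  unname(out)
}

#' Signed gradient of the squared field
#'
#' Spatial derivative of [field_e2_profile()] along x, signed so that a
#' positive Clausius-Mossotti factor drives beads toward the nearest electrode
#' edge. Antisymmetric about each gap midline and exactly zero there.
#'
#' @inheritParams field_e2_profile
#' @return Signed gradient in V^2/m^3.
#' @export
grad_e2_profile <- function(geometry, drive, x_um,
                            decay_um = geometry$gap_um / 2) {
  gb <- gap_bounds(geometry, x_um)
  mid <- (gb[, "xL"] + gb[, "xR"]) / 2
  e2 <- field_e2_profile(geometry, drive, x_um, decay_um)
  lambda_m <- decay_um * 1e-6
  out <- sign(x_um - mid) * e2 / lambda_m
  out[is.na(mid)] <- 0
  unname(out)
}

#' Advance the bead population by one frame
#'
#' Overdamped (inertialess) Euler step: each bead moves along x by
#' `F_DEP / (6 pi eta R) * dt`, with the DEP force evaluated at the bead's
#' position from [dep_force()] and [grad_e2_profile()]. The deterministic DEP
#' displacement acts along x only (the force is perpendicular to the fingers);
#' optional Brownian noise perturbs both axes. Beads stop at the electrode
#' edges of their gap (positions clamped) and are reflected at the vertical
#' field-of-view borders.
#'
#' @param pop Bead tibble as returned by [init_beads()].
#' @param materials A [material_set()].
#' @param drive A [drive_state()].
#' @param geometry An [electrode_geometry()].
#' @param config A [sim_config()]. Uses the session RNG when `noise_on`.
#' @return The updated bead tibble.
#' @export
step_beads <- function(pop, materials, drive, geometry, config) {
  stopifnot(is.data.frame(pop), nrow(pop) >= 0)
  if (nrow(pop) == 0) return(pop)
  decay <- resolve_decay_um(config, geometry)
  r_m <- pop$radius_um * 1e-6
  grad <- grad_e2_profile(geometry, drive, pop$x_um, decay)
  f <- dep_force(materials, r_m, grad, drive$freq_hz)
  drag <- 6 * pi * config$eta * r_m
  dx_um <- f / drag * config$dt_s * 1e6
  x <- pop$x_um + dx_um
  y <- pop$y_um
  if (isTRUE(config$noise_on)) {
    d_coef <- KBOLTZ * config$temp_k / drag            # m^2/s
    s_um <- sqrt(2 * d_coef * config$dt_s) * 1e6
    x <- x + stats::rnorm(nrow(pop), 0, s_um)
    y <- y + stats::rnorm(nrow(pop), 0, s_um)
  }
  # beads stop at the electrode edges of their own gap
  gb <- gap_bounds(geometry, pop$x_um)
  ok <- !is.na(gb[, "xL"])
  x[ok] <- pmin(pmax(x[ok], gb[ok, "xL"]), gb[ok, "xR"])
  # reflect at the horizontal field-of-view borders
  y <- reflect_into(y, 0, geometry$fov_h_um)
  pop$x_um <- x
  pop$y_um <- y
  pop
}

reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  v <- ifelse(v > span, 2 * span - v, v)
  v + lo
}

# ground-truth distance feature of a population (um)
true_feature <- function(pop, geometry) {
  if (nrow(pop) == 0) return(NA_real_)
  mean(abs(pop$x_um - geometry$ref_x_um))
}

#' Simulate a frequency schedule
#'
#' Runs the bead dynamics under a fixed schedule of applied frequencies,
#' emitting per-frame bead coordinates, the ground-truth distance feature
#' (mean absolute distance of bead centres to the reference line), and,
#' optionally, rendered grayscale frames.
#'
#' @param initial Initial bead tibble ([init_beads()]).
#' @param schedule Data frame with columns `freq_hz` and `n_frames`.
#' @param materials A [material_set()].
#' @param geometry An [electrode_geometry()].
#' @param config A [sim_config()]; `config$seed` (when set) seeds the run.
#' @param render If `TRUE`, rendered frames are returned as a list of matrices.
#' @param vpp Peak-to-peak drive voltage (V).
#' @return An object of class `dep_simulation`: a list with `trajectory`
#'   (tibble: frame, bead_id, x_um, y_um, freq_hz), `features` (tibble: frame,
#'   freq_hz, n_beads, x_true), `frames` (list of matrices or `NULL`), and the
#'   inputs used.
#' @examples
#' geo <- electrode_geometry()
#' set.seed(1)
#' sim <- simulate_run(init_beads(geo, 10),
#'                     data.frame(freq_hz = 1e4, n_frames = 5),
#'                     material_set(), geo, sim_config())
#' sim$features
#' @export
simulate_run <- function(initial, schedule, materials, geometry,
                         config = sim_config(), render = FALSE, vpp = 3) {
  stopifnot(is.data.frame(schedule), nrow(schedule) >= 1,
            all(c("freq_hz", "n_frames") %in% names(schedule)))
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- initial
  freqs <- rep(schedule$freq_hz, schedule$n_frames)
  n_tot <- length(freqs)
  traj <- vector("list", n_tot)
  feats <- vector("list", n_tot)
  frames <- if (render) vector("list", n_tot) else NULL
  for (t in seq_len(n_tot)) {
    drv <- drive_state(freqs[t], vpp)
    pop <- step_beads(pop, materials, drv, geometry, config)
    traj[[t]] <- tibble::tibble(frame = t, bead_id = pop$bead_id,
                                x_um = pop$x_um, y_um = pop$y_um,
                                freq_hz = freqs[t])
    feats[[t]] <- tibble::tibble(frame = t, freq_hz = freqs[t],
                                 n_beads = nrow(pop),
                                 x_true = true_feature(pop, geometry))
    if (render) frames[[t]] <- render_frame(pop, geometry)
  }
  structure(
    list(trajectory = dplyr::bind_rows(traj),
         features = dplyr::bind_rows(feats),
         frames = frames,
         schedule = tibble::as_tibble(schedule),
         materials = materials, geometry = geometry, config = config,
         vpp = vpp, seed = config$seed),
    class = "dep_simulation"
  )
}

#' @export
print.dep_simulation <- function(x, ...) {
  cat("<dep_simulation>\n")
  cat(sprintf("  %d frames, %d beads, %d scheduled frequencies\n",
              max(x$features$frame), length(unique(x$trajectory$bead_id)),
              nrow(x$schedule)))
  cat(sprintf("  rendered frames: %s\n", if (is.null(x$frames)) "no" else "yes"))
  invisible(x)
}
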