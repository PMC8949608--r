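# Closed-loop feedback controller: consume motion labels, command frequency
# steps on the function generator, manage SETTLE, terminate, and report the
# pDEP/nDEP regimes and the crossover bracket.

#' Controller configuration
#'
#' @param ladder_hz Ordered candidate frequencies (Hz), strictly increasing.
#'   Default mirrors the tested frequencies 10, 50, 100, 500, 1000 kHz.
#' @param not_move_threshold Consecutive `NO_DEP` decisions before the loop
#'   terminates (default 3).
#' @param settle_frames Frames spent in SETTLE after each frequency command;
#'   `NULL` resolves to `k + u` (particle response plus system response, the
#'   latter set by the watching-window length).
#' @param sample_every Decision cadence m: frames consumed per decision once
#'   the window is full (default 5).
#' @param f_min_hz,f_max_hz Clamp bounds; default to the ladder ends.
#' @param step_policy `"toward-crossover"` (default: attraction steps the
#'   frequency up, repulsion steps it down, homing in on the crossover from
#'   either side) or `"algorithm1-literal"` (the reverse mapping; the paper
#'   notes the mapping can be flipped to match the setup).
#' @param start_freq_hz Frequency applied before the first decision. Default:
#'   the highest ladder rung, so the run opens under repulsion, which
#'   disperses beads from the electrode edges into the gap interior — a
#'   well-conditioned state for the subsequent polarity probes.
#' @param max_frames Watchdog cap on total frames; a run that hits it is
#'   reported incomplete.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(ladder_hz = c(10, 50, 100, 500, 1000) * 1e3,
                              not_move_threshold = 3,
                              settle_frames = NULL,
                              sample_every = 5,
                              f_min_hz = min(ladder_hz),
                              f_max_hz = max(ladder_hz),
                              step_policy = c("toward-crossover",
                                              "algorithm1-literal"),
                              start_freq_hz = max(ladder_hz),
                              max_frames = 5000) {
  step_policy <- match.arg(step_policy)
  if (length(ladder_hz) < 1 || any(diff(ladder_hz) <= 0)) {
    stop("`ladder_hz` must be strictly increasing", call. = FALSE)
  }
  if (any(ladder_hz < f_min_hz) || any(ladder_hz > f_max_hz)) {
    stop("`ladder_hz` must lie within [f_min_hz, f_max_hz]", call. = FALSE)
  }
  check_scalar(not_move_threshold, "not_move_threshold", lower = 1)
  check_scalar(sample_every, "sample_every", lower = 1)
  check_scalar(max_frames, "max_frames", lower = 1)
  if (!is.null(settle_frames)) check_scalar(settle_frames, "settle_frames", lower = 1)
  if (!start_freq_hz %in% ladder_hz) {
    stop("`start_freq_hz` must be a ladder frequency", call. = FALSE)
  }
  structure(list(ladder_hz = ladder_hz,
                 not_move_threshold = as.integer(not_move_threshold),
                 settle_frames = settle_frames,
                 sample_every = as.integer(sample_every),
                 f_min_hz = f_min_hz, f_max_hz = f_max_hz,
                 step_policy = step_policy,
                 start_freq_hz = start_freq_hz,
                 max_frames = as.integer(max_frames)),
            class = "controller_config")
}

#' Initial controller state
#'
#' @param config A [controller_config()].
#' @param settle_frames Resolved SETTLE duration (frames).
#' @return An object of class `controller_state` with fields `freq_hz`,
#'   `mode` (`"RUNNING"` or `"SETTLE"`), `settle_remaining`, `not_move_count`.
#' @export
controller_state <- function(config, settle_frames) {
  structure(list(freq_hz = config$start_freq_hz,
                 mode = "SETTLE",
                 settle_remaining = as.integer(settle_frames),
                 not_move_count = 0L),
            class = "controller_state")
}

ladder_neighbor <- function(ladder, freq, dir) {
  i <- match(freq, ladder)
  if (is.na(i)) stop("current frequency is not on the ladder", call. = FALSE)
  j <- i + dir
  if (j < 1 || j > length(ladder)) NA_real_ else ladder[j]
}

#' Decide the next control action from a motion label
#'
#' Implements the control-loop decision rule: `NO_DEP` holds the frequency and
#' increments `not_move_count`, terminating once it reaches the threshold; a
#' DEP label resets the counter and requests a step whose direction is set by
#' the step policy (`toward-crossover`: attraction steps up, repulsion steps
#' down; `algorithm1-literal`: the reverse). Steps that would leave the ladder
#' clamp to a hold. Requesting a decision during SETTLE is a contract
#' violation and errors.
#'
#' @param label Motion label from [classify_trend()].
#' @param b Trend slope (recorded in history; does not alter the action).
#' @param state A [controller_state()].
#' @param config A [controller_config()].
#' @return A list with `action` (one of `"STEP_UP"`, `"STEP_DOWN"`, `"HOLD"`,
#'   `"TERMINATE"`) and the updated `state`.
#' @export
decide <- function(label, b, state, config) {
  if (state$mode != "RUNNING") {
    stop("decision requested during SETTLE: contract violation", call. = FALSE)
  }
  if (label == "NO_DEP") {
    state$not_move_count <- state$not_move_count + 1L
    action <- if (state$not_move_count >= config$not_move_threshold)
      "TERMINATE" else "HOLD"
    return(list(action = action, state = state))
  }
  state$not_move_count <- 0L
  up <- switch(config$step_policy,
               "toward-crossover" = label == "POSITIVE_DEP",
               "algorithm1-literal" = label == "NEGATIVE_DEP")
  target <- ladder_neighbor(config$ladder_hz, state$freq_hz,
                            if (up) 1L else -1L)
  action <- if (is.na(target)) "HOLD" else if (up) "STEP_UP" else "STEP_DOWN"
  list(action = action, state = state)
}

#' Apply a control action
#'
#' `STEP_UP`/`STEP_DOWN` issue exactly one frequency command packet to the
#' instrument and put the controller into SETTLE for `settle_frames` frames;
#' `HOLD` and `TERMINATE` issue no command. An instrument rejection aborts
#' with the instrument's error.
#'
#' @param action Action string from [decide()].
#' @param state A [controller_state()].
#' @param config A [controller_config()].
#' @param instrument A [mock_function_generator()].
#' @param settle_frames Resolved SETTLE duration (frames).
#' @return The updated `controller_state`.
#' @export
apply_action <- function(action, state, config, instrument, settle_frames) {
  if (action %in% c("STEP_UP", "STEP_DOWN")) {
    target <- ladder_neighbor(config$ladder_hz, state$freq_hz,
                              if (action == "STEP_UP") 1L else -1L)
    if (is.na(target)) return(state)  # clamped at a ladder end
    send_command(instrument, sprintf("FREQ %s", format(target, scientific = FALSE)))
    state$freq_hz <- target
    state$mode <- "SETTLE"
    state$settle_remaining <- as.integer(settle_frames)
  }
  state
}

#' Run the closed-loop frequency characterization
#'
#' Orchestrates the full feedback loop against the virtual testbed: per frame,
#' advance the bead dynamics at the instrument's current frequency, extract
#' the distance feature (from true coordinates, or through the renderer and
#' circle detector in `"frames"` mode), maintain the watching window, and —
#' outside SETTLE, at the configured decision cadence — classify the motion
#' and act on the function generator. The run terminates when
#' `not_move_threshold` consecutive `NO_DEP` decisions accumulate (the beads
#' have stopped responding, indicating a near-crossover rung), or when the
#' label table has stabilized with the largest attracting rung adjacent to the
#' smallest repelling rung (the bracket has converged), or at the `max_frames`
#' watchdog (reported incomplete).
#'
#' After each frequency command the watching window is cleared so that frames
#' accumulated under the previous frequency cannot leak into the first
#' post-SETTLE decision; the window refills during SETTLE.
#'
#' @param materials A [material_set()].
#' @param geometry An [electrode_geometry()].
#' @param control A [controller_config()].
#' @param trend A [trend_params()].
#' @param sim A [sim_config()].
#' @param detect A [detector_params()]; default is matched to the rendered
#'   bead size. Only used in `"frames"` mode.
#' @param beads Initial bead tibble; default [init_beads()] with `n_beads`.
#' @param n_beads Bead count when `beads` is `NULL`.
#' @param mode `"coordinates"` (detector bypassed, features from true bead
#'   positions) or `"frames"` (renderer and Hough detector in the loop).
#' @param vpp Drive amplitude (V peak-to-peak).
#' @param seed Seed governing all stochastic elements (bead init, Brownian
#'   noise); `NULL` falls back to `sim$seed`, or leaves the RNG untouched.
#' @param out_dir Optional directory; when given, the run artifacts (trace
#'   CSV, report JSON, instrument log, effective config, seed) are written.
#' @return An object of class `dep_run`; see [tidy.dep_run()],
#'   [glance.dep_run()], [autoplot.dep_run()].
#' @examples
#' \donttest{
#' run <- run_closed_loop(material_set(), seed = 1)
#' glance(run)
#' }
#' @export
run_closed_loop <- function(materials,
                            geometry = electrode_geometry(),
                            control = controller_config(),
                            trend = trend_params(),
                            sim = sim_config(),
                            detect = NULL,
                            beads = NULL, n_beads = 40,
                            mode = c("coordinates", "frames"),
                            vpp = 3, seed = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(materials, "material_set"))
  if (is.null(seed)) seed <- sim$seed
  if (!is.null(seed)) set.seed(seed)
  settle_frames <- if (is.null(control$settle_frames))
    trend$k + trend$u else control$settle_frames
  if (settle_frames < trend$k) {
    stop("`settle_frames` must be at least the window length k", call. = FALSE)
  }
  if (is.null(detect)) {
    radius_um <- if (is.null(beads)) 1.5 else beads$radius_um[1]
    detect <- detector_for_geometry(geometry, radius_um)
  }
  pop <- if (is.null(beads)) init_beads(geometry, n_beads) else beads
  inst <- mock_function_generator(control$start_freq_hz, vpp,
                                  f_min = control$f_min_hz,
                                  f_max = control$f_max_hz)
  state <- controller_state(control, settle_frames)
  win <- watch_window(trend$k, trend$u)
  since_dec <- control$sample_every  # first eligible frame decides
  history <- list()                  # per-decision records
  trace <- list()                    # per-frame records
  reason <- "incomplete"
  stall_freq <- NA_real_
  n_steps <- 0L
  ref_px <- um_to_px_x(geometry, geometry$ref_x_um)

  for (t in seq_len(control$max_frames)) {
    drv <- drive_state(state$freq_hz, vpp)
    pop <- step_beads(pop, materials, drv, geometry, sim)

    if (mode == "coordinates") {
      feat_val <- true_feature(pop, geometry)
      n_det <- nrow(pop)
      feat_missing <- is.na(feat_val)
    } else {
      img <- render_frame(pop, geometry)
      det <- detect_particles(img, detect)
      f <- extract_feature(det, ref_px)
      # report the feature in microns so delta has one unit in both modes
      feat_val <- f$value * geometry$um_per_px
      n_det <- f$n
      feat_missing <- f$missing
    }

    win <- window_push(win, feat_val, missing = feat_missing)
    skipped <- isTRUE(attr(win, "skipped"))

    b <- NA_real_; label <- NA_character_; action <- NA_character_
    smoothed <- NA_real_

    if (state$mode == "SETTLE") {
      state$settle_remaining <- state$settle_remaining - 1L
      if (state$settle_remaining <= 0L) {
        state$mode <- "RUNNING"
        since_dec <- control$sample_every
      }
    } else if (!skipped && window_ready(win) &&
               since_dec >= control$sample_every) {
      res <- analyze_window(win, trend)
      b <- res$b; label <- res$label; smoothed <- res$smoothed_last
      since_dec <- 0L
      dec <- decide(label, b, state, control)
      state <- dec$state
      action <- dec$action
      history[[length(history) + 1]] <- tibble::tibble(
        frame = t, freq_hz = state$freq_hz, b = b, label = label,
        action = action)
      if (label %in% c("POSITIVE_DEP", "NEGATIVE_DEP")) {
        conv <- bracket_converged(dplyr::bind_rows(history), control$ladder_hz)
        if (conv) {
          action <- "TERMINATE"
          history[[length(history)]]$action <- "TERMINATE"
          reason <- "converged"
        }
      }
      if (action == "TERMINATE") {
        if (reason == "incomplete") {
          reason <- "not_move"
          stall_freq <- state$freq_hz
        }
        trace[[length(trace) + 1]] <- trace_row(t, state, n_det, feat_val,
                                                skipped, win, smoothed, b,
                                                label, action)
        break
      }
      if (action %in% c("STEP_UP", "STEP_DOWN")) {
        prev_freq <- state$freq_hz
        state <- apply_action(action, state, control, inst, settle_frames)
        if (state$freq_hz != prev_freq) {
          n_steps <- n_steps + 1L
          win <- watch_window(trend$k, trend$u)  # drop stale-trend frames
        }
      }
    } else {
      since_dec <- since_dec + 1L
    }

    trace[[length(trace) + 1]] <- trace_row(t, state, n_det, feat_val,
                                            skipped, win, smoothed, b, label,
                                            action)
  }

  trace <- dplyr::bind_rows(trace)
  history <- if (length(history)) dplyr::bind_rows(history) else
    tibble::tibble(frame = integer(0), freq_hz = numeric(0), b = numeric(0),
                   label = character(0), action = character(0))
  report <- build_report(history, control$ladder_hz, reason, stall_freq)
  report$frames_total <- nrow(trace)
  report$incomplete <- reason == "incomplete"

  run <- structure(
    list(report = report, trace = trace, history = history,
         instrument_log = instrument_log(inst), n_steps = n_steps,
         config = list(materials = materials, geometry = geometry,
                       control = control, trend = trend, sim = sim,
                       detect = detect, mode = mode, vpp = vpp,
                       n_beads = nrow(pop), settle_frames = settle_frames),
         seed = seed),
    class = "dep_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

trace_row <- function(t, state, n_det, feat_val, skipped, win, smoothed, b,
                      label, action) {
  tibble::tibble(
    frame = t, freq_hz = state$freq_hz, mode = state$mode,
    n_detected = n_det, x_feature = feat_val,
    imputed_flag = if (skipped) NA else
      (length(win$imputed) > 0 && win$imputed[length(win$imputed)]),
    smoothed_feature = smoothed, slope_b = b,
    label = label, action = action)
}

# bracket has converged when the largest attracting rung and the smallest
# repelling rung are adjacent on the ladder
bracket_converged <- function(history, ladder) {
  pos <- history$freq_hz[history$label == "POSITIVE_DEP"]
  neg <- history$freq_hz[history$label == "NEGATIVE_DEP"]
  if (length(pos) == 0 || length(neg) == 0) return(FALSE)
  p <- max(pos); n <- min(neg)
  if (p >= n) return(FALSE)
  identical(ladder_neighbor(ladder, p, 1L), n)
}

build_report <- function(history, ladder, reason, stall_freq) {
  lt <- dplyr::summarise(
    dplyr::group_by(history, .data$freq_hz),
    n_positive = sum(.data$label == "POSITIVE_DEP"),
    n_negative = sum(.data$label == "NEGATIVE_DEP"),
    n_no_dep = sum(.data$label == "NO_DEP"),
    label_final = .data$label[dplyr::n()],
    .groups = "drop")
  lt <- dplyr::arrange(lt, .data$freq_hz)

  pos <- history$freq_hz[history$label == "POSITIVE_DEP"]
  neg <- history$freq_hz[history$label == "NEGATIVE_DEP"]
  pdep_max <- if (length(pos)) max(pos) else NA_real_
  ndep_min <- if (length(neg)) min(neg) else NA_real_
  consistent <- is.na(pdep_max) || is.na(ndep_min) || pdep_max < ndep_min

  # the bracket is exactly what the polarity labels support; a NO_DEP stall
  # rung is reported alongside (it marks weak DEP, near-crossover or
  # saturated) but does not sharpen the bracket
  lo <- pdep_max; hi <- ndep_min
  if (!consistent) { lo <- NA_real_; hi <- NA_real_ }

  list(label_table = lt,
       pdep_max_hz = pdep_max, ndep_min_hz = ndep_min,
       bracket_lo_hz = lo, bracket_hi_hz = hi,
       stall_freq_hz = stall_freq,
       reason = reason, consistent = consistent)
}

#' @export
print.dep_run <- function(x, ...) {
  r <- x$report
  cat("<dep_run>\n")
  cat(sprintf("  %d frames, %d frequency steps, terminated: %s\n",
              r$frames_total, x$n_steps, r$reason))
  cat(sprintf("  pDEP up to:   %s\n", fmt_hz(r$pdep_max_hz)))
  cat(sprintf("  nDEP down to: %s\n", fmt_hz(r$ndep_min_hz)))
  cat(sprintf("  crossover bracket: (%s, %s)\n",
              fmt_hz(r$bracket_lo_hz), fmt_hz(r$bracket_hi_hz)))
  invisible(x)
}

fmt_hz <- function(f) {
  if (is.na(f)) return("open")
  if (f >= 1e6) sprintf("%g MHz", f / 1e6) else sprintf("%g kHz", f / 1e3)
}
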