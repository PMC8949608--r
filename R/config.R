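# Structured run configuration: YAML in, validated objects out, effective
# config echoed back so every run directory is self-describing.

default_config_values <- function() {
  list(
    materials = list(eps_p_rel = 2.5, eps_m_rel = 78,
                     sigma_p = 4.5e-3, sigma_m = 2e-4),
    geometry = list(n_fingers = 12, gap_um = 70, finger_width_um = 30,
                    um_per_px = 1, fov_w_um = NULL, fov_h_um = 100,
                    ref_x_um = NULL),
    sim = list(eta = 1e-3, temp_k = 298, dt_s = 0.1, decay_um = NULL,
               noise_on = FALSE),
    detector = list(param_1 = 50, param_2 = 100, min_radius = NULL,
                    max_radius = NULL, min_dist = NULL),
    trend = list(k = 30, u = 5, delta = 0.05, polarity_flip = FALSE),
    controller = list(ladder_khz = c(10, 50, 100, 500, 1000),
                      not_move_threshold = 3, settle_frames = NULL,
                      sample_every = 5, step_policy = "toward-crossover",
                      start_freq_khz = NULL, max_frames = 5000),
    run = list(mode = "run", source = "coordinates", n_beads = 40,
               radius_um = 1.5, vpp = 3, seed = NULL, out_dir = NULL),
    schedule = list(freq_khz = NULL, n_frames = NULL)
  )
}

# reject unknown keys anywhere in the nesting, naming the offending key
check_unknown_keys <- function(user, defaults, path = "") {
  if (!is.list(user)) return(invisible())
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop(sprintf("unknown config key: %s%s", path, extra[1]), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      check_unknown_keys(user[[nm]], defaults[[nm]],
                         path = paste0(path, nm, "."))
    }
  }
  invisible()
}

# modifyList that treats an explicit NULL as "use the default"
deep_merge <- function(base, user) {
  for (nm in names(user)) {
    v <- user[[nm]]
    if (is.null(v)) next
    if (is.list(v) && is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], v)
    } else {
      base[[nm]] <- v
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with nested sections (`materials`, `geometry`,
#' `sim`, `detector`, `trend`, `controller`, `run`, `schedule`), fills in the
#' documented defaults, rejects unknown keys, and validates every section
#' through its module constructor so invariant violations fail before any run
#' starts, with an error naming the offending key. An empty file yields the
#' full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An object of class `run_config` holding the constructed module
#'   objects (`materials`, `geometry`, `sim`, `detect`, `trend`, `control`)
#'   plus `run` and `schedule` sections and the resolved `values` list that
#'   [echo_config()] writes.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config_values()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  check_unknown_keys(user, defaults)
  v <- deep_merge(defaults, user)

  materials <- do.call(material_set, v$materials)
  geometry <- do.call(electrode_geometry, v$geometry)
  sim <- do.call(sim_config, c(v$sim, list(seed = v$run$seed)))
  trend <- do.call(trend_params, v$trend)
  d <- v$detector
  detect <- if (is.null(d$min_radius) || is.null(d$max_radius)) {
    detector_for_geometry(geometry, v$run$radius_um,
                          param_1 = d$param_1, param_2 = d$param_2)
  } else {
    detector_params(d$param_1, d$param_2, d$min_radius, d$max_radius,
                    d$min_dist)
  }
  cc <- v$controller
  ladder_hz <- cc$ladder_khz * 1e3
  control <- controller_config(
    ladder_hz = ladder_hz,
    not_move_threshold = cc$not_move_threshold,
    settle_frames = cc$settle_frames,
    sample_every = cc$sample_every,
    step_policy = cc$step_policy,
    start_freq_hz = if (is.null(cc$start_freq_khz)) max(ladder_hz) else
      cc$start_freq_khz * 1e3,
    max_frames = cc$max_frames)
  if (!v$run$mode %in% c("simulate", "analyze", "run")) {
    stop("unknown config value for run.mode: ", v$run$mode, call. = FALSE)
  }
  if (!v$run$source %in% c("coordinates", "frames")) {
    stop("unknown config value for run.source: ", v$run$source, call. = FALSE)
  }

  values <- resolved_values(materials, geometry, sim, detect, trend, control,
                            v$run, v$schedule)
  structure(list(materials = materials, geometry = geometry, sim = sim,
                 detect = detect, trend = trend, control = control,
                 run = v$run, schedule = v$schedule, values = values),
            class = "run_config")
}

# effective settings, defaults included, rebuilt from the validated objects
resolved_values <- function(materials, geometry, sim, detect, trend, control,
                            run, schedule) {
  list(
    materials = materials[c("eps_p_rel", "eps_m_rel", "sigma_p", "sigma_m")],
    geometry = geometry[c("n_fingers", "gap_um", "finger_width_um",
                          "um_per_px", "fov_w_um", "fov_h_um", "ref_x_um")],
    sim = list(eta = sim$eta, temp_k = sim$temp_k, dt_s = sim$dt_s,
               decay_um = resolve_decay_um(sim, geometry),
               noise_on = sim$noise_on),
    detector = detect[c("param_1", "param_2", "min_radius", "max_radius",
                        "min_dist")],
    trend = trend[c("k", "u", "delta", "polarity_flip")],
    controller = list(ladder_khz = control$ladder_hz / 1e3,
                      not_move_threshold = control$not_move_threshold,
                      settle_frames = control$settle_frames,
                      sample_every = control$sample_every,
                      step_policy = control$step_policy,
                      start_freq_khz = control$start_freq_hz / 1e3,
                      max_frames = control$max_frames),
    run = run,
    schedule = schedule
  )
}

#' Write the effective configuration
#'
#' Writes the fully resolved settings of a [load_config()] result (or of a
#' finished run) as YAML, so that reloading the echoed file reproduces the
#' identical configuration.
#'
#' @param config A `run_config`, or the resolved values list itself.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
echo_config <- function(config, path) {
  values <- if (inherits(config, "run_config")) config$values else config
  yaml::write_yaml(drop_nulls(values), path)
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}
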