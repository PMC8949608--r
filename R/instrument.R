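# Mock SCPI function generator: the audit surface for command-count checks.

#' Mock function generator
#'
#' A stand-in for a programmable function generator that accepts SCPI-style
#' text command packets (`"FREQ 500000"`, `"VOLT 3 VPP"`) and records every
#' packet in a session log. The initial frequency and amplitude are
#' construction state, not commands, so the log holds exactly one `FREQ`
#' packet per frequency adjustment issued by the controller.
#'
#' @param freq_hz Initial output frequency (Hz, > 0).
#' @param vpp Initial peak-to-peak amplitude (V, > 0).
#' @param f_min,f_max Hard frequency limits the instrument will accept (Hz).
#' @param log_path Optional file; packets are appended to it as they arrive.
#' @return An environment of class `mock_instrument` with fields `freq_hz`,
#'   `vpp` and `log`.
#' @export
mock_function_generator <- function(freq_hz, vpp = 3,
                                    f_min = 1, f_max = 1e9,
                                    log_path = NULL) {
  check_scalar(freq_hz, "freq_hz", lower = 0, strict = TRUE)
  check_scalar(vpp, "vpp", lower = 0, strict = TRUE)
  inst <- new.env(parent = emptyenv())
  inst$freq_hz <- freq_hz
  inst$vpp <- vpp
  inst$f_min <- f_min
  inst$f_max <- f_max
  inst$log <- character(0)
  inst$log_path <- log_path
  class(inst) <- "mock_instrument"
  inst
}

#' Send one SCPI-style command packet to the mock instrument
#'
#' Accepts `"FREQ <hz>"` and `"VOLT <v> VPP"`. Malformed packets or
#' frequencies outside the instrument's limits are rejected with an error
#' (the run is expected to abort and surface it).
#'
#' @param inst A [mock_function_generator()].
#' @param cmd A single command string.
#' @return The instrument, invisibly.
#' @export
send_command <- function(inst, cmd) {
  stopifnot(inherits(inst, "mock_instrument"), is.character(cmd),
            length(cmd) == 1)
  if (grepl("^FREQ [0-9.eE+-]+$", cmd)) {
    f <- as.numeric(sub("^FREQ ", "", cmd))
    if (!is.finite(f) || f < inst$f_min || f > inst$f_max) {
      stop(sprintf("instrument rejected '%s': frequency outside [%g, %g] Hz",
                   cmd, inst$f_min, inst$f_max), call. = FALSE)
    }
    inst$freq_hz <- f
  } else if (grepl("^VOLT [0-9.eE+-]+ VPP$", cmd)) {
    v <- as.numeric(strsplit(cmd, " ")[[1]][2])
    if (!is.finite(v) || v <= 0) {
      stop(sprintf("instrument rejected '%s': non-positive amplitude", cmd),
           call. = FALSE)
    }
    inst$vpp <- v
  } else {
    stop(sprintf("instrument rejected malformed packet '%s'", cmd),
         call. = FALSE)
  }
  inst$log <- c(inst$log, cmd)
  if (!is.null(inst$log_path)) {
    cat(cmd, "\n", file = inst$log_path, append = TRUE, sep = "")
  }
  invisible(inst)
}

#' Session log of the mock instrument
#'
#' @param inst A [mock_function_generator()].
#' @return Character vector of the command packets received, in order.
#' @export
instrument_log <- function(inst) {
  stopifnot(inherits(inst, "mock_instrument"))
  inst$log
}
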