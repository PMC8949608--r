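# broom-style tidiers and ggplot2 views of run results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-frequency label table of a closed-loop run
#'
#' @param x A `dep_run` from [run_closed_loop()].
#' @param ... Unused.
#' @return A tibble with one row per visited frequency: `freq_hz`, decision
#'   counts per label, and the final label at that frequency.
#' @export
tidy.dep_run <- function(x, ...) {
  x$report$label_table
}

#' One-row summary of a closed-loop run
#'
#' @param x A `dep_run` from [run_closed_loop()].
#' @param ... Unused.
#' @return A one-row tibble: `pdep_max_hz` (largest frequency labelled
#'   attracting), `ndep_min_hz` (smallest labelled repelling), the crossover
#'   bracket, termination reason, step and frame counts.
#' @export
glance.dep_run <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    pdep_max_hz = r$pdep_max_hz, ndep_min_hz = r$ndep_min_hz,
    bracket_lo_hz = r$bracket_lo_hz, bracket_hi_hz = r$bracket_hi_hz,
    reason = r$reason, incomplete = r$incomplete,
    n_steps = x$n_steps, frames_total = r$frames_total,
    seed = if (is.null(x$seed)) NA_real_ else x$seed)
}

#' Trace plot of a closed-loop run
#'
#' Distance feature versus frame, coloured by the applied frequency, with
#' dashed lines marking each frequency command — the same view the testbed's
#' trial plots use.
#'
#' @param object A `dep_run` from [run_closed_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dep_run <- function(object, ...) {
  tr <- object$trace
  switches <- tr$frame[c(FALSE, diff(tr$freq_hz) != 0)]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$frame, y = .data$x_feature,
                                   colour = factor(.data$freq_hz / 1e3))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = switches, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "frame", y = "mean |x - ref| (um)",
                  colour = "frequency (kHz)") +
    ggplot2::theme_minimal()
}

#' Clausius-Mossotti spectrum plot
#'
#' `Re[K]` versus frequency on a log axis, with the zero crossing (the
#' crossover frequency) marked when present.
#'
#' @param materials A [material_set()].
#' @param f_lo,f_hi Frequency range (Hz).
#' @param n Number of points.
#' @return A ggplot object.
#' @export
plot_cm_spectrum <- function(materials, f_lo = 1e2, f_hi = 1e9, n = 400) {
  freq <- 10^seq(log10(f_lo), log10(f_hi), length.out = n)
  df <- cm_factor(materials, freq)
  fx <- crossover_frequency(materials, f_lo, f_hi)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$re_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "Re[K]") +
    ggplot2::theme_minimal()
  if (!is.na(fx)) {
    p <- p + ggplot2::geom_vline(xintercept = fx, linetype = "dashed",
                                 colour = "red3")
  }
  p
}
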