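# Frequency-domain DEP physics: complex permittivities, Clausius-Mossotti
# factor, DEP force on a spherical particle, and crossover-frequency solving.

# vacuum permittivity (F/m) and Boltzmann constant (J/K)
EPS0 <- 8.8542e-12
KBOLTZ <- 1.380649e-23

#' Material parameters of particle and suspension medium
#'
#' Bundles the four electrical parameters that determine the Clausius-Mossotti
#' factor: relative permittivities and conductivities of the particle and of
#' the suspension medium. Defaults describe 3-um carboxyl-modified latex beads
#' in deionized water; the bead conductivity is the parameter that cannot be
#' measured directly and is typically back-calculated from an observed
#' crossover frequency, so it is a free input here.
#'
#' @param eps_p_rel Relative permittivity of the particle (dimensionless, >= 1).
#' @param eps_m_rel Relative permittivity of the medium (dimensionless, >= 1).
#' @param sigma_p Particle conductivity (S/m, > 0).
#' @param sigma_m Medium conductivity (S/m, > 0).
#' @return An object of class `material_set`.
#' @examples
#' mat <- material_set()
#' cm_factor(mat, c(1e4, 1e6, 1e8))
#' @export
material_set <- function(eps_p_rel = 2.5, eps_m_rel = 78,
                         sigma_p = 4.5e-3, sigma_m = 2e-4) {
  check_scalar(eps_p_rel, "eps_p_rel", lower = 1)
  check_scalar(eps_m_rel, "eps_m_rel", lower = 1)
  check_scalar(sigma_p, "sigma_p", lower = 0, strict = TRUE)
  check_scalar(sigma_m, "sigma_m", lower = 0, strict = TRUE)
  structure(
    list(eps_p_rel = eps_p_rel, eps_m_rel = eps_m_rel,
         sigma_p = sigma_p, sigma_m = sigma_m),
    class = "material_set"
  )
}

#' @export
print.material_set <- function(x, ...) {
  cat("<material_set>\n")
  cat(sprintf("  particle: eps_rel = %g, sigma = %g S/m\n", x$eps_p_rel, x$sigma_p))
  cat(sprintf("  medium:   eps_rel = %g, sigma = %g S/m\n", x$eps_m_rel, x$sigma_m))
  fx <- crossover_frequency(x)
  if (is.na(fx)) {
    cat("  crossover: none in [1e2, 1e9] Hz\n")
  } else {
    cat(sprintf("  crossover: %.4g Hz\n", fx))
  }
  invisible(x)
}

#' Complex permittivity of a lossy dielectric
#'
#' Uses the convention `eps* = eps_rel * eps0 - j * sigma / omega` with
#' `omega = 2 * pi * freq` and `eps0 = 8.8542e-12` F/m.
#'
#' @param eps_rel Relative permittivity (dimensionless, > 0).
#' @param sigma Conductivity (S/m, >= 0).
#' @param freq Applied frequency (Hz, > 0); vectorized.
#' @return Complex permittivity in F/m (complex vector, same length as `freq`).
#' @export
complex_permittivity <- function(eps_rel, sigma, freq) {
  if (any(!is.finite(freq)) || any(freq <= 0)) {
    stop("`freq` must be positive and finite", call. = FALSE)
  }
  check_scalar(eps_rel, "eps_rel", lower = 0, strict = TRUE)
  check_scalar(sigma, "sigma", lower = 0)
  complex(real = eps_rel * EPS0, imaginary = -sigma / (2 * pi * freq))
}

# complex CM factor, internal fast path (vectorized over freq)
cm_complex <- function(materials, freq) {
  ep <- complex_permittivity(materials$eps_p_rel, materials$sigma_p, freq)
  em <- complex_permittivity(materials$eps_m_rel, materials$sigma_m, freq)
  (ep - em) / (ep + 2 * em)
}

#' Clausius-Mossotti factor
#'
#' Computes `K = (eps_p* - eps_m*) / (eps_p* + 2 eps_m*)` at each requested
#' frequency. The sign of `Re[K]` sets the DEP polarity: positive means
#' attraction toward the high-field electrode edges (pDEP), negative means
#' repulsion (nDEP). For a homogeneous sphere `Re[K]` lies in \[-0.5, 1\].
#'
#' @param materials A [material_set()].
#' @param freq Applied frequencies (Hz, > 0); vectorized.
#' @return A tibble with columns `freq`, `k_complex`, `re_k`.
#' @export
cm_factor <- function(materials, freq) {
  stopifnot(inherits(materials, "material_set"))
  k <- cm_complex(materials, freq)
  tibble::tibble(freq = freq, k_complex = k, re_k = Re(k))
}

# Re[K] as a plain numeric, used by the root finder and the simulator
re_k_at <- function(materials, freq) {
  Re(cm_complex(materials, freq))
}

#' Crossover frequency by bracketed bisection
#'
#' Finds the frequency at which `Re[K]` changes sign on `[f_lo, f_hi]` by
#' bisection on log-frequency (relative tolerance 1e-6 on the bracket). If
#' `Re[K]` has the same sign at both endpoints there is no crossover in the
#' interval and `NA` is returned; that is a valid answer, not an error.
#'
#' @param materials A [material_set()].
#' @param f_lo,f_hi Search interval (Hz), `0 < f_lo < f_hi`. The default
#'   `[1e2, 1e9]` covers typical colloidal DEP crossovers with margin.
#' @return Crossover frequency in Hz, or `NA_real_` if no sign change.
#' @seealso [crossover_frequency_mw()] for the closed form.
#' @export
crossover_frequency <- function(materials, f_lo = 1e2, f_hi = 1e9) {
  stopifnot(inherits(materials, "material_set"))
  if (!(f_lo > 0 && f_hi > f_lo)) {
    stop("require 0 < f_lo < f_hi", call. = FALSE)
  }
  g_lo <- re_k_at(materials, f_lo)
  g_hi <- re_k_at(materials, f_hi)
  if (g_lo == 0) return(f_lo)
  if (g_hi == 0) return(f_hi)
  if (sign(g_lo) == sign(g_hi)) return(NA_real_)
  lo <- log(f_lo); hi <- log(f_hi)
  # ~70 halvings push the bracket far below the 1e-6 relative tolerance
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    gm <- re_k_at(materials, exp(mid))
    if (gm == 0) return(exp(mid))
    if (sign(gm) == sign(g_lo)) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-13) break
  }
  exp((lo + hi) / 2)
}

#' Maxwell-Wagner crossover frequency (closed form)
#'
#' For a homogeneous sphere with a single interfacial relaxation the crossover
#' satisfies `2*pi*f = sqrt((sigma_p - sigma_m)(sigma_p + 2 sigma_m) /
#' ((eps_m - eps_p)(eps_p + 2 eps_m)))` with absolute permittivities. Returns
#' `NA` when the radicand is non-positive (no crossover). Used as an
#' independent cross-check of [crossover_frequency()].
#'
#' @inheritParams crossover_frequency
#' @return Crossover frequency in Hz, or `NA_real_`.
#' @export
crossover_frequency_mw <- function(materials) {
  stopifnot(inherits(materials, "material_set"))
  ep <- materials$eps_p_rel * EPS0
  em <- materials$eps_m_rel * EPS0
  num <- (materials$sigma_p - materials$sigma_m) *
    (materials$sigma_p + 2 * materials$sigma_m)
  den <- (em - ep) * (ep + 2 * em)
  r <- num / den
  if (!is.finite(r) || r <= 0) return(NA_real_)
  sqrt(r) / (2 * pi)
}

#' Time-averaged DEP force on a spherical particle
#'
#' `F = 2 * pi * eps_m * R^3 * Re[K] * grad_e2`, with `eps_m` the absolute
#' (real) medium permittivity. `grad_e2` is the signed 1-D component of the
#' gradient of the squared field, so the returned force is a signed 1-D
#' component as well: its sign is `sign(Re[K] * grad_e2)`.
#'
#' @param materials A [material_set()].
#' @param radius Particle radius R (m, > 0).
#' @param grad_e2 Gradient of the squared electric field (V^2/m^3, signed).
#' @param freq Applied frequency (Hz, > 0).
#' @return Force in newtons (signed); vectorized over `grad_e2` and `freq`.
#' @export
dep_force <- function(materials, radius, grad_e2, freq) {
  stopifnot(inherits(materials, "material_set"))
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("`radius` must be positive", call. = FALSE)
  }
  re_k <- re_k_at(materials, freq)
  2 * pi * (materials$eps_m_rel * EPS0) * radius^3 * re_k * grad_e2
}

# shared argument validation, errors name the offending key
check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  bad <- if (strict) x <= lower else x < lower
  if (bad) {
    cmp <- if (strict) ">" else ">="
    stop(sprintf("`%s` must be %s %g (got %g)", name, cmp, lower, x),
         call. = FALSE)
  }
  invisible(x)
}
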