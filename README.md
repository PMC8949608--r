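# depsweep

Closed-loop characterization of dielectrophoretic (DEP) frequency regimes.

## What it is for

Dielectrophoresis moves polarizable microparticles in a non-uniform AC
field: below the *crossover frequency* a latex microbead in DI water is
pulled toward the electrode edges (positive DEP), above it pushed away
(negative DEP). The crossover is set by the real part of the
Clausius–Mossotti factor,

    K(ω) = (εp* − εm*) / (εp* + 2 εm*),    ε* = ε − jσ/ω,
    F_DEP = 2π εm R³ Re[K] ∇E²,

but it cannot be predicted from tables because the bead conductivity σp
depends on surface functionalization and is never measured directly. In
practice the crossover is found *phenomenologically*: watch the beads,
classify attraction vs repulsion, and adjust the drive frequency until the
sign flip is bracketed.

`depsweep` packages that entire vision-guided feedback loop — circle
detection on grayscale frames, a sliding-window least-squares trend
classifier, and a controller stepping a (mock SCPI) function generator —
together with a physics-grounded virtual testbed (interdigitated-electrode
geometry, overdamped Brownian bead dynamics, synthetic micrograph
rendering), so the whole system runs and is testable on a desk, with the
analytic physics as ground truth. It is aimed at researchers building
automated electrokinetic assembly or particle-characterization rigs who
want to develop and validate the control software before (or without)
touching hardware.

## Worked example

3 µm latex beads (εp_rel = 2.5, σp = 4.5×10⁻³ S/m) in DI water
(εm_rel = 78, σm = 2×10⁻⁴ S/m), 70 µm electrode gaps, 3 V peak-to-peak:

```r
library(depsweep)

mat <- material_set()   # the bead/water defaults above
mat
#> <material_set>
#>   particle: eps_rel = 2.5, sigma = 0.0045 S/m
#>   medium:   eps_rel = 78, sigma = 0.0002 S/m
#>   crossover: 7.542e+05 Hz

run <- run_closed_loop(mat, seed = 1)
run
#> <dep_run>
#>   72 frames, 1 frequency steps, terminated: converged
#>   pDEP up to:   500 kHz
#>   nDEP down to: 1 MHz
#>   crossover bracket: (500 kHz, 1 MHz)

tidy(run)      # per-frequency label table
#> # A tibble: 2 x 5
#>   freq_hz n_positive n_negative n_no_dep label_final
#>     <dbl>      <int>      <int>    <int> <chr>
#> 1  500000          1          0        0 POSITIVE_DEP
#> 2 1000000          0          1        0 NEGATIVE_DEP
```

The analytic crossover for these materials is 754 kHz. The loop opens at
the top of the {10, 50, 100, 500, 1000} kHz ladder, sees repulsion at
1 MHz, steps down, sees attraction at 500 kHz, and terminates with the
bracket (500 kHz, 1 MHz) — attraction at and below 500 kHz, repulsion at
1 MHz, crossover in between. `glance(run)` gives the one-row summary,
`autoplot(run)` the feature-vs-frame trace, `run$instrument_log` the SCPI
packets sent (here a single `"FREQ 500000"`), and
`plot_cm_spectrum(mat)` the Re[K] spectrum. `run_closed_loop(...,
mode = "frames")` puts the renderer and the Hough circle detector inside
the loop instead of reading true coordinates.

The methods vignette (`vignettes/depsweep-methods.Rmd`) documents the
model, every tunable parameter, and the design decisions.

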