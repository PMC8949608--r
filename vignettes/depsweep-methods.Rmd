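---
title: "Methods: a virtual closed loop for DEP crossover characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a virtual closed loop for DEP crossover characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depsweep)
```

## The problem

Dielectrophoresis (DEP) — the force on a polarizable particle in a
non-uniform AC field — switches sign with the applied frequency. Below the
*crossover frequency* a typical latex microbead in deionized water is
attracted to the electrode edges (positive DEP, pDEP); above it, repelled
(negative DEP, nDEP). The crossover cannot be predicted reliably from tabled
constants because the bead's effective conductivity depends on surface
functionalization and is not measured directly; in practice it is found
*phenomenologically*, by watching the beads while sweeping the frequency.

`depsweep` implements, in software, the complete vision-guided feedback loop
that automates this search: a camera view of beads between interdigitated
electrodes, circle detection, a sliding-window trend classifier, and a
controller that steps a function generator until the pDEP/nDEP boundary is
bracketed. Because the physical testbed (chip, microscope, signal generator)
is replaced by a physics-grounded simulator and a mock SCPI instrument, the
entire loop is testable at desk scale, with the physics module supplying
ground truth to test against.

## Physics

For a homogeneous sphere, the polarity is set by the real part of the
Clausius–Mossotti factor

$$K(\omega) = \frac{\varepsilon_p^* - \varepsilon_m^*}
                   {\varepsilon_p^* + 2\varepsilon_m^*},
\qquad
\varepsilon^* = \varepsilon - j\,\sigma/\omega,$$

and the time-averaged force is
$F = 2\pi \varepsilon_m R^3\, \mathrm{Re}[K]\, \nabla E^2$.
We adopt the standard lossy-dielectric convention
$\varepsilon^* = \varepsilon - j\sigma/\omega$ (the force law's source
states the factor without expanding it) and fix
$\varepsilon_0 = 8.8542\times 10^{-12}$ F/m.

Default materials describe 3 µm carboxyl-modified latex beads in DI water:
relative permittivities 2.5 (bead) and 78 (water), medium conductivity
$2\times10^{-4}$ S/m. The bead conductivity is the free, unmeasurable input;
its default, $4.5\times10^{-3}$ S/m, places the crossover at
$\approx 7.54\times10^{5}$ Hz — inside the 500 kHz–1 MHz band that the
physical experiments bracket — and can be changed freely.

`crossover_frequency()` bisects $\mathrm{Re}[K]$ on log-frequency over
$[10^2, 10^9]$ Hz (relative bracket tolerance $10^{-6}$; the returned root
satisfies $|\mathrm{Re}[K]| < 10^{-6}$). `crossover_frequency_mw()` is the
Maxwell–Wagner closed form used as an independent cross-check; the two agree
to well under 0.1 % whenever a crossover exists.

```{r physics}
mat <- material_set()
crossover_frequency(mat)
cm_factor(mat, c(1e5, 5e5, 1e6))
```

## The virtual testbed

The electrode array is a row of parallel finger electrodes (default 12
fingers, 70 µm gaps, 30 µm fingers). No field is solved numerically; instead
a phenomenological one-dimensional profile supplies the $\nabla E^2$ the
force law needs:

$$E^2(x) = \left(\frac{V_{pp}}{2\,\mathrm{gap}}\right)^2
           e^{-d(x)/\lambda},$$

where $d(x)$ is the distance to the nearest electrode edge of the enclosing
gap and $\lambda$ (default gap/2 = 35 µm) the decay length. Any smooth
profile that is strongest at the edges and flat at the gap midline
reproduces the qualitative behaviour the force law needs; the exponential is
the simplest such choice. Its signed derivative is antisymmetric about the
midline and exactly zero there, so a positive $\mathrm{Re}[K]$ always drives
beads toward the nearest edge.

Bead dynamics are overdamped (micron-scale Stokes regime, negligible
inertia): per frame of duration $dt$,
$x \leftarrow x + \frac{F}{6\pi\eta R}\,dt$, with optional Brownian steps of
variance $2 D\, dt$, $D = k_B T / 6\pi\eta R$, on both axes. The
deterministic DEP displacement acts along $x$ only, matching the
analysis convention that only motion perpendicular to the fingers is
informative. Beads stop at the electrode edges of their gap and reflect at
the vertical frame borders. Defaults: $\eta = 10^{-3}$ Pa·s, $T$ = 298 K,
10 fps ($dt$ = 0.1 s), $V_{pp}$ = 3 V (the drive amplitude the bench
experiments used; 1 V is equally accepted as a config value).

The renderer is a deterministic pure view of the bead state — uniform
background, brighter electrode stripes, beads as dark anti-aliased disks
with a mild Gaussian blur — so coordinate-mode and rendered-mode runs share
bit-identical trajectories. With the default 1 µm/px scale a 1.5 µm bead
spans only 3 px, which no gradient-vote circle detector resolves reliably;
rendered-mode studies therefore image at 0.5 µm/px (bead diameter ≈ 6 px,
comparable to the micrographs the method was developed on). Coordinate-mode
runs are scale-free.

What the simulator deliberately omits: electroosmotic flow, bead–bead dipole
chains ("pearl chains"), sedimentation, 3-D motion, and inertial response
lag. Passing tests therefore demonstrate that the *control loop* behaves
correctly given DEP-dominated motion; they do not certify performance under
the confounding forces present in a real cell, where detection rates are
also far lower (20–30 % is typical on real micrographs versus >90 % on
rendered frames).

## Detection and the distance feature

`detect_particles()` is a Hough Gradient circle detector: Sobel gradients on
a lightly smoothed frame; pixels whose gradient magnitude exceeds `param_1`
(on a 0–255 scale) vote along their gradient direction, both ways, at every
radius in `[min_radius, max_radius]`; accumulator peaks above `param_2`
(after a 3×3 vote consolidation) become centres, with greedy non-maximum
suppression and modal-distance radius estimation. The four parameters mirror
the conventional parameterization and, as in the bench practice, are tuned
per imaging setup: the packaged defaults (`param_1 = 50`, `param_2 = 100`,
radius bounds = rendered bead radius ∓/+ 2 px) were tuned once against the
package's own renderer, where rendered disks score well above 150 votes
while electrode-edge line artifacts stay under 60.

Each frame is summarized by the cloud-level feature
$X_t = \frac{1}{N}\sum_n |x_n - r|$: the mean absolute distance of detected
centres to the reference line $r$ at the central gap's midline. Rising
$X_t$ = motion toward the electrodes = attraction. Frames with no detections
yield a flagged missing feature.

## Trend analysis

A FIFO watching window holds the $k$ (default 30) most recent features.
Missing features are imputed as the mean of the $u$ (default 5) most recent
observed ones; the window is then smoothed by linear convolution with an
unweighted (all-ones) kernel of length $u$, with edge replication at the
boundaries so no fabricated zeros bias the window ends (for a linear trend
over 30 points this attenuates the fitted slope by only ~1 %). The span
$u$ serves both imputation and smoothing — the source procedure overloads
one symbol for both and we keep that coupling — and imputation precedes
smoothing, the natural streaming order. Regression abscissae are frame
offsets $0,1,\dots$, not wall-clock times.

The least-squares slope
$b = \sum(x-\bar x)(y - \bar y)/\sum(x-\bar x)^2$ is compared with a
threshold $\delta$ (default 0.05 µm/frame): $|b| \le \delta$ (inclusive) is
`NO_DEP`; otherwise the sign gives `POSITIVE_DEP`/`NEGATIVE_DEP`, with a
`polarity_flip` switch for setups with the opposite feature convention.
$\delta$ is unreported in the source procedure; 0.05 µm/frame sits roughly
four standard deviations below the weakest polarity slope the default
simulated conditions produce (≈ 0.06 µm/frame under nDEP at 1 MHz) while
the at-crossover slope is numerically zero.

One note on window length: the source text both calls $k$ "the length" of
$\{X_{t-k},\dots,X_t\}$ (which has $k+1$ elements) and indexes regression
points $0\dots k$. We resolve the ambiguity as: the window holds at most
$k$ features and abscissae run $0\dots n-1$; slope units are unaffected.

## The control loop

Per frame the loop advances the testbed, extracts the feature (true
coordinates or rendered frame + detector), and pushes it into the window.
Outside SETTLE, once the window is full, a decision is taken every `m`
frames (default 5): `NO_DEP` holds and increments `not_move_count`
(terminating at 3 consecutive); a polarity label resets the counter and
steps the ladder (default rungs 10, 50, 100, 500, 1000 kHz). Under the
default `toward-crossover` policy attraction steps *up* and repulsion
*down*, homing in on the crossover; the literal pseudocode mapping of the
source (attraction → decrease) is preserved as `algorithm1-literal`, since
the source itself notes the mapping flips with the setup. Steps clamp at the
ladder ends.

Each step sends exactly one SCPI packet (`FREQ 500000`) to the mock
instrument and enters SETTLE for `settle_frames` = $k + u$ frames — the
particle response time plus the system response time set by the window
length. During SETTLE frames are still acquired and the window keeps
filling, but no decisions are taken; the window is cleared at the moment of
each frequency change so no stale-trend frames from the previous frequency
leak into the first post-SETTLE decision (the clearing is our addition; the
source pseudocode has no SETTLE step at all, while its prose requires one —
we follow the prose).

Two design choices were genuinely open:

* **Start frequency.** Unstated in the source. We default to the *highest*
  ladder rung: opening under nDEP repels beads from the electrode edges
  into the gap interior, a well-conditioned state for the subsequent
  polarity probes. Starting low does the opposite — under strong pDEP a
  noiseless overdamped cloud collapses onto the electrode edges within a
  few seconds, after which no further attraction is observable and the loop
  would stall at the next rung.
* **Termination and the bracket.** Besides the `not_move_count` guard, the
  loop terminates as *converged* when the largest attracting rung and the
  smallest repelling rung are adjacent on the ladder — the label table has
  stabilized and stepping would only oscillate between them. The reported
  bracket is exactly `(pdep_max, ndep_min)`, i.e. what the polarity labels
  support, with either side open if that polarity was never observed. A
  `NO_DEP` stall rung is reported separately: it marks weak DEP but is
  *not* used to sharpen the bracket, because a stall can equally mean the
  cloud has saturated (collapsed at the midline or pinned at the edges)
  where the field gradient is weak. A watchdog (`max_frames`, default 5000)
  caps every run; runs that hit it are flagged incomplete.

```{r loop}
run <- run_closed_loop(material_set(), seed = 1)
run
tidy(run)
glance(run)
run$instrument_log
```

With the default materials the run opens at 1 MHz, sees repulsion
(slope ≈ −0.06 µm/frame), steps down to 500 kHz, sees attraction
(slope ≈ +0.11 µm/frame), and terminates converged with the bracket
(500 kHz, 1 MHz) after 72 frames and a single frequency command — the same
regime conclusion the physical experiments reach, and consistent with the
physics-module crossover of 754 kHz for these materials.

## Numerical and study-size choices

* Simulated studies use 40 beads initialized uniformly in the central gap
  (1 µm margins); the cloud-mean feature makes slopes essentially
  independent of bead count, while per-frame noise scales as $1/\sqrt N$.
* Property suites use 100 random material sets (crossover cross-check),
  1000 random windows (slope oracle), and 10 seeded noisy closed-loop runs
  with bead conductivity drawn log-uniformly on
  $[3\times10^{-4}, 4.5\times10^{-3}]$ S/m, which maps the true crossover
  to ≈ 43–754 kHz, strictly inside the ladder span.
* Rendered-mode runs at 0.5 µm/px process a 260×200 px frame in a few
  milliseconds; a full rendered closed loop takes a few seconds.
* Ties in the accumulator peak search resolve toward the top-left pixel;
  candidate centres are ordered by votes (then row, then column) before
  suppression, making detection fully deterministic.
* One seed governs every stochastic element of a run (bead initialization
  and Brownian noise) and is recorded in all artifacts.

## Known limitations

The simulator's omissions listed above are the main caveat: on real
micrographs the detector parameters must be re-tuned, detection rates are
lower, electroosmosis can masquerade as attraction near some frequencies,
and response lag (attributed by the bench observations to residual bead
momentum, which an overdamped model cannot reproduce) may delay polarity
changes beyond what the watching-window latency already introduces. The
classifier and controller are agnostic to these effects' origin — they see
only the feature series — but bracket accuracy on real data will depend on
ladder spacing and on choosing $\delta$ against the observed noise floor.
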