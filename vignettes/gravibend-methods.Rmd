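---
title: "Graviproprioceptive bending of growing shoots: models, numerics, and phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graviproprioceptive bending of growing shoots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravibend)
```

## The model

A shoot organ is idealized as an inextensible-in-girth cylinder of radius
$R$ whose midline is described by arclength $s$ (base $s = 0$, apex
$s = L(t)$), local inclination from the vertical $A(s,t)$, and curvature
$C = \partial A / \partial s$. Two sensory feedbacks drive the tropic
movement:

* **graviception** — the organ senses its local inclination and curves
  toward the vertical;
* **proprioception** — the organ senses its own curvature and
  straightens.

In a *non-elongating* organ these combine into the linear law
$\partial C/\partial t = -\beta A - \gamma C$ applied over the sensing
zone (`step_ac()`, "AC-type" dynamics). The steady state is an
exponential decay of inclination, $A(s) = A_0 e^{-s/L_c}$, with
convergence length $L_c$.

In a *growing* organ the motor of curvature change is **differential
growth**. With flank elongation rates $\dot\epsilon_1, \dot\epsilon_2$,
the median relative elongation rate is
$\dot E = (\dot\epsilon_1 + \dot\epsilon_2)/2$ and the dimensionless
differential-growth fraction is
$\Delta = (\dot\epsilon_2 - \dot\epsilon_1)/(\dot\epsilon_1 + \dot\epsilon_2)$.
Following the material element (material derivative $D/Dt$):

$$\frac{DC}{Dt}\,R = \left(1 - C^2R^2\right)\,\dot E\,\Delta
 \;\approx\; \dot E\,\Delta \quad (|CR| \ll 1).$$

Perception is assumed to act on the *distribution* of growth, not on its
amount: $\Delta = -\tilde\beta A - \tilde\gamma C R$ with dimensionless
sensitivities $\tilde\beta = \beta R / \dot E$ and
$\tilde\gamma = \gamma / \dot E$. This closes the growth-explicit
("ACE-type") model

$$\frac{DC}{Dt}R = \dot E\,(-\tilde\beta A - \tilde\gamma C R),$$

implemented by `step_ace()` / `simulate_organ()`. The dimensionless
**bending number**

$$B = \frac{\tilde\beta\,L_\mathrm{eff}}{\tilde\gamma\,R} = \frac{L_\mathrm{eff}}{L_c}$$

controls both transients and steady shape; the effective length
$L_\mathrm{eff}$ is the initial organ length $L_0$ under whole-organ
exponential growth and the growth-zone length $L_{gz}$ under subapical
growth.

### Two destabilizing effects of growth

1. **Passive orientation drift.** Pure elongation ($\Delta = 0$)
   conserves the curvature of a material element exactly, but spreads it
   over a longer arc: the angle difference across the element drifts at
   $dA'/dt = \dot E_0 (\Delta + CR)\,\delta s / R$ (`drift_rate()`).
   Active control requires the proprioceptive term to beat this drift at
   any inclination, which reduces to the strict condition
   $\tilde\gamma > 1$ (`active_control_ok()`).
2. **Fixed curvature.** Tissue convected out of the subapical growth
   zone can never bend again. If the organ has not converged before
   vertical elements exit, transient oscillations are frozen into the
   mature base. Comparing the convergence time
   $T_c = 1/(\dot E_0 \tilde\gamma)$ with the minimal exit time of a
   vertical element, $T_f = \dot E_0^{-1}\sqrt{2R/(\tilde\beta L_{gz})}$,
   gives the measurable criterion $B < \sqrt{2 L_{gz}/R}$
   (`fixation_time()`, `fixation_negligible()`). The source text renders
   these relations without radical signs and without the $\tfrac12$ from
   the integration of the maximal-bending curvature over the fixed zone;
   we implement the dimensionally consistent re-derived forms, under
   which the exit-angle bound reaches zero exactly at $T_f$
   (`fixed_profile_bound()`).

### Steady state under exponential growth

With uniform elongation the steady shape is a real-order Bessel profile
(`ace_profile()`):

$$A(s) = A_0\,\Gamma(\tilde\gamma)\,
  \left(\tilde\beta s/R\right)^{(1-\tilde\gamma)/2}
  J_{\tilde\gamma-1}\!\left(2\sqrt{\tilde\beta s/R}\right).$$

The $s \to 0$ limit is evaluated analytically as $A_0$ (below
$\tilde\beta s/R < 10^{-8}$), avoiding the $0^{a}\cdot\infty$
indeterminacy of naive evaluation on either side of
$\tilde\gamma = 1$. The profile satisfies the stationary balance
$\sigma A'' + \tilde\gamma A' + \tilde\beta A = 0$ (with $\sigma = s/R$),
which the test suite verifies by finite differences, and the
$\tilde\gamma = 1$ case is checked against an independent power-series
Bessel oracle.

### When can growth be neglected?

The discrepancy between the growing and non-growing steady states, in
the dimensionless position $u = B s / L_{gz}$, is

$$\mu(u) = \left|A_0\,\Gamma(\tilde\gamma)(\tilde\gamma u)^{(1-\tilde\gamma)/2}
  J_{\tilde\gamma-1}(2\sqrt{\tilde\gamma u}) - A_0 e^{-u}\right|,$$

(`mu_statistic()`). When $\sup_u \mu$ is below the angular measurement
error (0.05 rad), the two models cannot be distinguished
experimentally. `critical_gamma()` bisects for the smallest
$\tilde\gamma$ achieving this.

**Amplitude convention.** $\mu$ is linear in $A_0$. The supremum sits at
$u \approx 2.2$, so the $u$-domain convention is irrelevant for any
$u_{\max} \gtrsim 3$ (we use 50). With a *unit-amplitude* profile
($A_0 = 1$ rad) the critical gain is $\tilde\gamma^* \approx 6.05$,
matching the reference threshold of 6.2 to 2.5%; with the horizontal
clamp amplitude $A_0 = \pi/2$ the same criterion gives
$\tilde\gamma^* \approx 9.16$. We conclude the published threshold was
computed at unit amplitude and make $A_0 = 1$ the default, exposing
`A0` as an argument and reporting the $\pi/2$ sensitivity here rather
than tuning anything. With $\tilde\beta \sim 1$ (full one-sided growth
inhibition at the start of the response) the criterion becomes the
measurable condition $L_{gz}/R > 6.2\,B$ (`exp_growth_negligible()`).

## Numerics

**Lagrangian grid.** The organ is a chain of material elements carrying
(length $\delta s_i$, curvature $C_i$, latched `frozen` flag). Advecting
the grid itself realizes the convective part of the material derivative
exactly — no convection term is discretized, and the discontinuous step
growth profile suffers no numerical diffusion. Angles are reconstructed
from the clamped base by cumulative sums of $C_i \delta s_i$.

**Time stepping.** Explicit Euler with the stability bound
$dt \le 0.1\,\min\{1/(\dot E_0\tilde\gamma),\; R/(\dot E_0\tilde\beta
L_\mathrm{dyn}),\; 1/\dot E_0\}$, where $L_\mathrm{dyn}$ is the length
of the dynamically coupled region (the whole organ under exponential
growth, at most $L_{gz}$ under subapical growth — frozen tissue
contributes no stiffness). Under exponential growth $L$ grows by factors
of $e^4$–$e^6$ within a run, so a single conservative step would be
ruinously small; when `dt` is not supplied, `simulate_organ()`
re-evaluates the bound each step. A user-supplied `dt` is validated
against the bound at every step and rejected by name. Element lengths
grow by the exact factor $e^{\dot E dt}$, keeping
$L(t) = L_0 e^{\dot E_0 t}$ exact under exponential growth. The
step-halving test keeps the first-order error below 0.1% of the angle
scale.

**Remeshing and freezing.** Elements longer than twice the initial
spacing are split in two equal halves (curvature and frozen flag
inherited; node angles preserved exactly; element count never
decreases). Growth-zone membership is decided by the element midpoint's
distance to the apex — unbiased for the step profile, with half-element
error — and the frozen flag is latched, since a material point's
distance from the apex never decreases in this model.

**Steady-state detection.** A growing organ reaches a *dynamic* steady
state: the Eulerian shape $A(s)$ freezes while material elements keep
flowing through it with $DC/Dt \ne 0$. A material-rate criterion can
therefore never fire; `detect_steady_state()` instead reports the
earliest recorded time from which every later snapshot agrees with the
current shape to within `tol` (default 0.01 rad) everywhere and in tip
angle, with at least one dimensionless time unit observed afterwards.

**Measuring the stability boundary.** From a perfectly straight start,
the undulation instability below $\tilde\gamma = 1$ must grow from
discretization noise ($\sim 10^{-4}$ rad) at rate
$(1-\tilde\gamma)\dot E_0$; resolving the boundary that way would need
$\tau \gtrsim 30$, while the cost of an exponential-growth run scales as
$e^{2\tau}$ — infeasible at any resolution. The package therefore seeds
the undulations at the stated angular measurement error:
`init_tilted_noisy()` adds a 0.05 rad random angle increment per
element, and `undulation_growth_rate()` tracks the total variation of
the angle deviation from the closed-form steady profile, whose fitted
late-time log-slope matches $1-\tilde\gamma$ to a few percent.
`critical_gamma_convergence()` bisects the sign change of that slope;
with $B = 10$, $L_0/R = 100$ it lands at $\tilde\gamma \approx 0.97$.

## Kinematic phenotyping

`phenotype()` replicates the experimental measurement on a time series
of digitized midlines: arclength by cumulative chords, inclination as
the tangent angle from the vertical, resampled to 200 uniform segments
(`midline_geometry()`); the effective length from base-aligned
superposition of the first and last frames (`effective_length()`); the
convergence length from a nonlinear least-squares fit of
$A(s) = A_0 e^{-s/L_c}$ beginning at the curved-zone onset
(`fit_convergence_length()`); and $B = L_\mathrm{eff}/L_c$.

Noise-handling choices, all governed by the single 0.05 rad measurement
error:

* Profiles are smoothed by a short running mean (2.5% of the organ)
  before thresholded comparisons — the numerical analogue of
  superimposing two photographs by eye.
* The curved-zone onset is the *last* position still within tolerance,
  not the first excursion beyond it: with per-point noise comparable to
  the threshold, a first-crossing rule false-triggers at the base and
  biases $L_\mathrm{eff}$ toward the full organ length.
* Both $A_0$ and $L_c$ are fitted (a log-linear fit is undefined where
  noise takes $A$ through zero); `nls` with a log-linear initialization
  and `scaleOffset` for exact data, falling back to direct least
  squares.
* The fit runs from the onset to the apex and reports the range used.
* Steadiness of the final frame is checked by the smoothed RMS
  difference of the last two frames (sup-norm would trigger on noise
  alone); violation is a warning, not an error.

Rotation of all frames about the base shifts the fitted $A_0$ by the
rotation angle and preserves $L_c$ only approximately: rotation also
moves the profile's asymptote, which the pure-exponential model (fixed
zero asymptote) partially absorbs into $(A_0, L_c)$. The test suite
asserts the property at a small angle with a tolerance reflecting this
model misfit. Uniform rescaling of coordinates leaves $B$ unchanged to
machine precision.

## Synthetic data

`fixture_spec()` / `generate_fixture()` produce midline time series with
known ground truth by simulating one of the canonical regimes (all with
$B = 10$, $L_\mathrm{eff}/R = 100$, horizontal clamp — the parameter
sets of the reference simulations):

| scenario | growth | $\tilde\gamma$ | outcome |
|---|---|---|---|
| `exp_divergent` | exponential | 0.1 | undulations grow, no steady state |
| `exp_convergent` | exponential | 10 | dynamic steady state while elongating |
| `subapical_fixing` | subapical | 0.1 | oscillations fixed on the mature base |
| `subapical_clean` | subapical | 10 | converges before fixation |
| `ac_reference` | none (AC) | 10 | exponential steady profile, $B = 3$ |

Digitization error is emulated by perturbing *tangent angles* with
zero-mean Gaussian noise (sd 0.05 rad, the stated measurement error) and
re-integrating the midline — not by i.i.d. point jitter, which has the
wrong spectrum. Frames share an exact clamped base. Generation is
deterministic under a fixed seed and CSV output carries 9 significant
digits.

What a green test does *not* establish: the generator emulates shapes,
growth kinematics and angular noise only. Real kinematic data also
carry bell-shaped (not step) elongation profiles, slow drifts of
$\dot E_0$ and $L_{gz}$ (the third growth phase is out of scope),
out-of-plane motion, nutation, and correlated digitization errors; none
of these are represented, so parameter-recovery results bound only the
procedure's self-consistency, not its field accuracy.

## Default parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `R` | 1 | length | all lengths are naturally in radii |
| `E0` | 1 | 1/time | time in units of $\dot E_0^{-1}$ |
| `A0` | $\pi/2$ | rad | horizontal clamp of the experiments |
| `N` | 200 | — | resolves $L_c \ge 10R$ shapes to sub-0.01 rad |
| `noise_sd` | 0.05 | rad | stated angular measurement error |
| `tol_angle` / onset | 0.05 | rad | same single tolerance everywhere |
| `ss_tol` | 0.01 | rad | shape-settledness, above interpolation noise |
| `mu_max` | 0.05 | rad | indistinguishability tolerance |
| `critical_gamma(A0)` | 1 | rad | unit-amplitude convention (above) |

## Known limitations

* Planar dynamics only; no apical growth, no third (declining) growth
  phase, no secondary-growth motors, no phototropism.
* The subapical steady state has no closed form; it is reached only by
  simulation.
* The Bessel profile for $\tilde\gamma < 1$ is evaluated as a formula
  but is not an attracting state.
* Explicit Euler only; the adaptive step follows the stability bound,
  not an error estimate.
* The `small_curvature` prefactor is a controlled approximation only
  for $|CR| \ll 1$; crossing $|CR| = 1$ emits a warning (once per run)
  and continues, because divergence studies legitimately enter that
  regime.
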