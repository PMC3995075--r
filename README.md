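# gravibend

Simulation and kinematic analysis of **shoot gravitropism** — the slow
growth-mediated reorientation of plant organs (coleoptiles, hypocotyls,
inflorescence stems) toward the vertical — under the combined control of
**graviception** (sensing of local inclination *A*) and
**proprioception** (sensing of local curvature *C*). It is written for
plant biomechanists and phenotypers who need a tested reference
implementation of the growth-explicit graviproprioceptive model, its
closed-form steady states and regime criteria, and the midline-based
measurement of the bending number.

## The model in brief

A non-elongating organ obeys the classical graviproprioceptive law over
its sensing zone,

    ∂C/∂t = −β A − γ C,

whose steady state is an exponential decay of inclination,
A(s) = A₀·e^(−s/L_c). In a *growing* organ the motor of bending is
differential growth: with median relative elongation rate Ė and
differential-growth fraction Δ, the curvature of a material element
evolves as

    DC/Dt · R = Ė · Δ,      Δ = −β̃ A − γ̃ C R,

with dimensionless sensitivities β̃ = βR/Ė, γ̃ = γ/Ė. The dimensionless
**bending number**

    B = β̃ L_eff / (γ̃ R) = L_eff / L_c

controls the whole movement (L_eff = organ length under whole-organ
exponential growth, growth-zone length L_gz under subapical growth).
Growth destabilizes the movement in two ways, both quantified here:
**passive orientation drift** (elongation spreads curvature over a
longer arc; overcome only when γ̃ > 1) and **fixed curvature** (tissue
leaving the growth zone can never bend again; harmless when
B < √(2·L_gz/R)). When γ̃ exceeds ≈ 6.2 the growing organ's Bessel-type
steady state is experimentally indistinguishable (within the 0.05 rad
measurement error) from the non-growing exponential profile.

## Worked example

Simulate a subapically growing organ (B = 4, γ̃ = 25, L_gz = 100 R,
initial length 200 R, clamped horizontal), generate a noisy synthetic
midline series from it, and phenotype it back:

```r
library(gravibend)

p <- model_params(B = 4, gamma_tilde = 25, R = 1, E0 = 1,
                  Lgz = 100, L0 = 200, growth_mode = "subapical_step")
traj <- simulate_organ(p, mode = "ace", t_max = 1.5)
traj
#> Gravitropic trajectory (ace model): 31 snapshots, t in [0, 1.5]
#>   L: 200 -> 350.081 | elements: 200 -> 300 | tip angle: 1.571 -> 0.000 rad
#>   converged at t = 0.25

fx <- generate_fixture(fixture_spec("custom", params = p,
                                    noise_sd = 0.05, seed = 42, t_max = 1.5))
phenotype(fx$series, R = 1)
#> Kinematic phenotype
#>   L_eff = 99.5, L_c = 26.2997, B = L_eff/L_c = 3.783
#>   A0_fit = 1.598 rad, fit rmse = 0.0395 rad over s in [102.399, 349.206]
#> Gravitropic regime diagnostics
#>   gamma_tilde = 26.2997, B = 3.78331, Lgz/R = 99.5
#>   active control (gamma_tilde > 1):        TRUE
#>   exponential growth negligible:           TRUE
#>   curvature fixation negligible:           TRUE
#>   Tc = 0.0380232, Tf = 0.141776, Tc/Tf = 0.268192
```

Reading the output: the organ tripled in length while converging to the
vertical at t = 0.25 (in units of Ė₀⁻¹). From the noisy midlines the
pipeline recovers the effective length (≈ L_gz = 100), the convergence
length L_c ≈ 26 (true value L_gz/B = 25), hence B̂ = 3.78 against a true
B = 4 — within the 0.05 rad angular noise budget. The diagnostics
confirm the organ sits in the well-behaved regime: proprioception beats
passive drift, growth is negligible for steady-shape purposes, and no
transient curvature is fixed at the base (T_c ≪ T_f).

The model-discrimination threshold itself:

```r
critical_gamma(A0 = 1, mu_max = 0.05)
#> [1] 6.054442
```

## Command line

```sh
Rscript inst/cli/gravibend simulate --scenario subapical_clean --out run
Rscript inst/cli/gravibend mu-threshold --A0 1 --mu 0.05
Rscript inst/cli/gravibend generate --scenario exp_convergent --seed 1 --out fix
Rscript inst/cli/gravibend phenotype --in fix.csv --radius 1
Rscript inst/cli/gravibend diagnose --config config.json
```

Subcommands exit 0 on success, 2 on usage/validation errors, 1 on
runtime errors; every file-writing run drops a JSON provenance record.

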