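# canardEAD

Simulation and geometric (fast–slow/canard) analysis of early
afterdepolarizations in a reduced four-variable Luo–Rudy I ventricular
action potential model.

## The problem

Early afterdepolarizations (EADs) are pathological voltage oscillations in
the plateau or repolarizing phase of a cardiac action potential; they
prolong the AP and are implicated in arrhythmias such as Torsades de
pointes. One experimentally established driver is an enlarged *window
region* of the L-type Ca2+ current — the voltage interval where the
steady-state activation curve d∞(V) and inactivation curve f∞(V) overlap
and sustain an inward current at plateau voltages. This package is for
modellers and cardiac electrophysiologists who want to (i) simulate how
translations of d∞/f∞, extracellular K+, the Ca2+ conductance, and gate
time constants create or eliminate EADs, and (ii) *explain* those outcomes
geometrically: the EADs are canard-induced oscillations organized by a
folded-node singularity of the slow flow, and the number of EADs is set by
which rotational sector (between maximal canards γₙ) the pulsed orbit
enters.

## The model

Membrane equation and Hodgkin–Huxley gates (ms, mV, µA/cm², mS/cm²):

    Cm dV/dt = −(ICa-L + IK + IK1 + IKp + Ib) + Istim
    dj/dt    = (j∞(V) − j)/τj(V),   j = d, f, x

    ICa-L = gCa·d·f·(V − VCa)      IK  = gK·x·Xi∞(V)·(V − VK)
    IK1   = gK1·K1∞(V)·(V − VK1)   IKp = gKp·Kp∞(V)·(V − VK1)
    Ib    = gb·(V − Vb)

Rates and K+-dependence follow the 1991 Luo–Rudy formulation;
gCa = 0.112 mS/cm² and a fixed VCa = 80 mV (see the methods vignette for
the calibration of VCa). Window manipulations translate d∞ by `dV_d` and
f∞ by `dV_f` (mV); `alpha`/`beta` scale τd/τf; `Ko` sets [K+]o with
√(Ko/5.4) conductance scaling and Nernst reversal potentials. The standard
protocol is a single mollified 70 µA/cm² × 2 ms pulse from rest,
integrated for 10,000 ms.

## Worked example

Symmetric window broadening by 2.08 mV — the classic two-EAD case:

```r
library(canardEAD)
p     <- ead_params(dV_d = -2.08, dV_f = 2.08)   # broaden the window
traj  <- integrate_model(p, t_end = 10000)       # pulse from rest
feats <- classify_response(traj)
feats
#> AP outcome: EADS (EADs: 2)
#>   peak times (ms): 656, 1044
feats$ead_durations
#> [1] 385.5 340.5
```

Two EADs ride the plateau at ≈656 and ≈1044 ms; the first lasts 385.5 ms.
The late EADs ring near the depolarized equilibrium E2, whose linearized
period matches:

```r
e2 <- Filter(function(e) e$label == "E2", find_equilibria(p))[[1]]
eigen_period(e2)
#> [1] 339.5468   # ms; compare the second EAD duration, 340.5 ms
```

The geometric explanation — maximal canards on the section Σ through the
folded node, and the rotational sector of the pulsed orbit:

```r
mc <- maximal_canards(p, n_max = 3)
mc
#> maximal canards on Sigma (V = -17.341 mV):
#>  index    seed_x         f         x rotations     coord
#>      0 0.4340968 0.3945541 0.5102502         0 0.3424036
#>      1 0.4221371 0.3908628 0.5009587         1 0.3324058
#>      2 0.4149771 0.3886573 0.4954031         2 0.3264284
#>      3 0.4101118 0.3871604 0.4916311         3 0.3223703
sector_of(traj, mc)
#> $flag      "sector"
#> $predicted 2
```

The orbit crosses Σ between γ₁ and γ₂, so canard theory predicts exactly
the two EADs the simulation shows. Sweeps and boundaries:

```r
find_boundary(ead_params(), "dV_d", c(-5, 0), "green")  # EAD onset, ≈ -3.51 mV
curve <- boundary_curve(f_values = seq(-1, 7, by = 1), d_bracket = c(-6, 2.5))
boundary_slope(curve)                                    # ≈ 1.38 (> 1: d-shifts dominate)
canard_delta(magnitude = 3.6)$delta                      # < 0: inside the EAD funnel
```

A command-line driver is installed at `inst/cli/canard-ap`
(`canard-ap simulate --preset fig3_2.08 --out traj.csv`,
`canard-ap reproduce --figure fig5`), with JSON parameter presets under
`inst/presets/`.

## Layout

* `R/`, `src/` — model core (Rcpp), simulation/classification, sweeps,
  fast–slow analysis (critical manifold, folds, folded singularities,
  singular strong canard), slow manifolds/maximal canards/δ, CLI.
* `vignettes/canard-analysis-of-eads.Rmd` — methods: model, conventions,
  numerics, canard algorithm, limitations.
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (fixed-step RK4, brute-force EAD counting, 1-D
  equilibrium scans).
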