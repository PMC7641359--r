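---
title: "Canard analysis of early afterdepolarizations in a reduced ventricular AP model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canard analysis of early afterdepolarizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canardEAD)
```

## The model

Early afterdepolarizations (EADs) are small secondary oscillations of the
membrane potential that appear during the plateau or repolarizing phase of a
cardiac action potential, prolonging it and predisposing tissue to
arrhythmia. A key biophysical determinant is the *window region* of the
L-type Ca2+ current: the voltage range where the steady-state activation
curve $d_\infty(V)$ and inactivation curve $f_\infty(V)$ overlap, so that a
sustained inward Ca2+ current flows at plateau voltages.

`canardEAD` implements a reduced four-variable variant of the 1991 Luo-Rudy
(LR-I) ventricular model keeping only the electrical components relevant to
purely electrical EADs:

$$C_m \dot V = -(I_{Ca\text{-}L} + I_K + I_{K1} + I_{Kp} + I_b) + I_{stim},
\qquad
\dot j = \frac{j_\infty(V) - j}{\tau_j(V)},\ j \in \{d, f, x\}$$

with $I_{Ca\text{-}L} = g_{Ca}\, d f (V - V_{Ca})$,
$I_K = g_K\, x\, X_{i,\infty}(V)(V - V_K)$,
$I_{K1} = g_{K1} K_{1,\infty}(V)(V-V_{K1})$,
$I_{Kp} = g_{Kp} K_{p,\infty}(V)(V-V_{K1})$ and $I_b = g_b (V - V_b)$. The
fast Na+ current and intracellular Ca2+ handling are deliberately absent:
the model describes dynamic-clamp-style experiments in which Ca2+ entry is
blocked and a model Ca2+ current is injected electronically, so EADs here
are purely electrical.

All rate functions, rectification curves, the $\sqrt{[K^+]_o/5.4}$ scaling
of $g_K$, $g_{K1}$ and the K+ Nernst potentials are transcribed from the
LR-I formulation. Two constants differ from LR-I:

* $g_{Ca} = 0.112\ \mathrm{mS/cm^2}$ (default), raised so that
  window-region manipulations can elicit EADs;
* $V_{Ca} = 80$ mV, a fixed Ca2+ reversal potential replacing LR-I's
  Ca2+-concentration-dependent one.

**How $V_{Ca}$ was fixed.** No printed source for this constant was
available to the build. It was calibrated *once*, before any quantitative
target was measured, against the categorical outcome ladder the model is
required to reproduce: with all other constants at their LR-I values,
$V_{Ca} = 80$ mV is the only value on a 1 mV grid in $[60, 130]$ for which
the symmetric broadening ray gives (no EADs, no EADs, 2 EADs,
repolarization failure) at shifts of 0, 1.04, 2.08, 3.12 mV *and* the
asymmetric-shift and hypokalemia ladders come out right simultaneously.
Quantities not used in the calibration then fall into place on their own
(depolarized-equilibrium eigenperiod ≈ 340 ms, first EAD duration ≈ 386 ms,
EAD-onset boundary ≈ −3.5 mV on the $\Delta V_{1/2}(d_\infty)$ axis), which
is strong evidence the transcription is faithful. $V_{Ca}$ remains an
ordinary configuration field.

### Window-region manipulations

Translating $d_\infty$ by $\Delta V_{1/2}(d_\infty)$ (`dV_d`) and
$f_\infty$ by $\Delta V_{1/2}(f_\infty)$ (`dV_f`) moves only the
steady-state curves — the time constants keep their default voltage
dependence and are scaled globally by `alpha` ($\tau_d$) and `beta`
($\tau_f$). A left shift of $d_\infty$ (`dV_d < 0`) or right shift of
$f_\infty$ (`dV_f > 0`) broadens the window. An optional inactivation
pedestal `f_pedestal` maps $f_\infty \to p + (1-p) f_\infty$, modelling
incomplete inactivation (off by default; its magnitude has no stated
value).

### Stimulus and protocol

The standard protocol integrates from the rest state for 10,000 ms with a
single mollified square pulse: amplitude 70 uA/cm^2, duration 2 ms, onset
20 ms, realized as a product of logistic ramps of width `stim_smooth`
(0.1 ms). Classification is insensitive to the ramp width well below 1 ms;
the onset time is a convention (the source protocol does not state one).

## EAD detection

The detector (`classify_response`) operates on dense solver output
(≤ 1 ms): an EAD is a local maximum of $V$ that occurs after the
stimulus-evoked upstroke complex, at $V > -45$ mV, with prominence ≥ 1 mV.
Three conventions deserve explanation:

* **Upstroke window (250 ms).** The pulse produces a spike–notch–dome
  complex whose dome is itself a local maximum, at ≈ 75 ms in every
  parameter set examined, whereas canard-induced EADs appear after
  ≈ 600 ms. Maxima within 250 ms of the pulse are therefore part of the
  upstroke, not EADs. This window, the −45 mV gate, and the 1 mV
  prominence are exposed as arguments.
* **Repolarization failure** means $V$ never falls below −45 mV between
  the upstroke and the end of the record (the trajectory is captured by
  the depolarized equilibrium).
* **EAD durations** are intervals between the local minima flanking each
  counted peak. The final EAD has no right-hand minimum (the downstroke
  follows), so it closes where $V$ falls back through the level of its
  left trough. With this convention the second EAD duration at the
  symmetric 2.08 mV preset (≈ 340 ms) agrees with the linearized
  oscillation period of the depolarized equilibrium, as it should, since
  the late EADs are ringing near that equilibrium. Closing the last EAD at
  the −45 mV crossing instead would fold the downstroke into the duration
  (≈ 429 ms) and break that agreement.

## Numerics

There is no stiff-ODE package in the target environment, so the package
carries its own Dormand–Prince 5(4) adaptive integrator (C++ via Rcpp)
with error control `rtol = 1e-8`, `atol = 1e-10` (defaults), cubic-Hermite
dense output, and plane-crossing event location by bisection on the dense
interpolant. The integrator is validated in the test suite against an
independent fixed-step RK4 oracle through the stimulus and upstroke, the
hardest segment. Equilibria come from a sign-change scan of the
steady-state current balance in $V$ (all gates at their steady-state
curves) followed by bracketed root refinement; stability from central
difference 4×4 Jacobians.

Degenerate inputs: a non-finite voltage is a domain error everywhere; an
all-real spectrum makes `eigen_period` fail loudly rather than return a
number; bisection brackets whose endpoints classify identically are
errors, not silent midpoints.

## Fast–slow structure

With $C_m$ as the timescale-separation parameter, $(V, d)$ are fast and
$(f, x)$ slow. The critical manifold — equilibria of the fast subsystem
with $(f, x)$ frozen — is computed in closed form: the current balance is
affine in $f$, so the manifold is the graph $f = h(V, x)$ with
$d = d_\infty(V)$. Its fold curve $L$ is where $h_V = 0$, which is exactly
where the fast Jacobian is singular. The reduced (slow) flow on the
manifold, desingularized by the time rescaling $d\tau = h_V\,dt$, is an
ordinary planar vector field whose equilibria on $L$ are the folded
singularities. A folded node (real eigenvalues of one sign, ratio
$\mu = \lambda_w/\lambda_s \in (0,1)$) organizes small oscillations: the
singular strong canard through it, traced from $\pm 10^{-6}$ offsets along
the strong eigenvector (voltage normalized by 100 mV), bounds the singular
funnel together with $L$.

One observation worth recording: at the EAD presets examined, the
desingularized basin of the folded node on the attracting sheet is wide —
orbits seeded on *either* side of the singular strong canard within ±0.04
in $x$ at 8 mV above the fold all terminate at the node, and the
funnel/jump boundary lies farther out. The textbook local picture (strong
canard as the immediate basin boundary) holds asymptotically near the
node; at these distinctly non-normal-form parameters the package's tests
assert the robust facts instead: funnel orbits terminate at the node in
desingularized time, orbits beyond the boundary cross $L$ away from it.

## Maximal canards without numerical continuation

The reference approach to maximal canards is a boundary-value computation
(collocation/continuation) of attracting and repelling slow manifolds and
their transversal intersections on a fold-adjacent section $\Sigma$ (here:
the plane $V = V(FN)$). This package does not reimplement a continuation
code; it exploits an equivalence instead:

> a maximal canard $\gamma_n$ is the boundary, within the attracting
> slow-manifold family, between orbits that execute $n$ and $n+1$ small
> loops near the fold.

So `maximal_canards()` seeds the attracting family on the upper sheet
20 mV above the fold, counts each orbit's voltage loops inside a ±25 mV
band around $\Sigma$ (capture by the depolarized equilibrium counts as
infinitely many), and bisects each count transition in the seed parameter
to $10^{-8}$. This needs only forward integration of an attracting object
and is therefore numerically benign. A repelling family (backward
integration from the saddle sheet, with a first-order slow-manifold
correction of the $d$ seed) is provided for completeness, but with two
fast variables the backward flow is exponentially unstable along the
$d$-gate direction, so that family is reliable only for short flights —
this is precisely why the detection method above avoids it.

The sector rule follows: a pulsed orbit crossing $\Sigma$ with $n$ canards
between its crossing point and the no-EAD side is predicted to make $n$
EADs; orbits captured by the depolarized equilibrium are flagged
`E2-basin` (repolarization failure). The signed distance $\delta$
(`canard_delta`) is the Euclidean distance in the slow variables $(f, x)$
on $\Sigma$ between the pulsed orbit's crossing and $\gamma_0$'s, signed
positive on the no-EAD side; its zero reproduces, independently, the
EAD-onset boundary found by simulation sweeps (the two agree to
< 0.01 mV on the $\Delta V_{1/2}(d_\infty)$ axis). Sector assignments are
verified in the tests to be invariant to moving $\Sigma$ by ±2 mV.

## Parameter sweeps

`run_grid` classifies outcomes over 2-D parameter grids (any pair of
`dV_d`, `dV_f`, `Ko`, `alpha`, `beta`, `gCa`); `find_boundary` bisects a
single parameter to 0.01-unit resolution for the no-EAD/EAD ("green") or
EAD/failure ("black") transition; `boundary_slope` fits a least-squares
line through boundary points in the window-shift plane. Default axis
ranges (e.g. `dV_d` ∈ [−4.5, 0.5] × `dV_f` ∈ [−1, 7]) were chosen to
contain all the preset markers; the source figures do not print their
ranges, so these are configuration, not substance. The default desk grid
is 60×60; the full 300×300 resolution is a parameter away but needs
correspondingly more time.

## What a green test does and does not establish

The suite reproduces: the symmetric-ray outcome ladder; the asymmetric
d-versus-f shift asymmetry and its quantitative form (boundary slope
≈ 1.38, within the stated 1.34 ± 0.15); the EAD-onset boundary on the
d-axis (−3.51 mV vs ≈ −3.45 printed) and its coincidence with the δ zero;
the eigenperiod (339.5 ms) and first-EAD duration (385.5 ms) at the 2.08
preset; hypokalemia-induced EADs and their elimination by 0.75 mV
window-narrowing shifts or by τ-scalings; the gCa rescue triples; the ≥ 6
EAD band; sector/simulation agreement; μ- and spacing-trends; and the
singular-limit approach of $\gamma_0$ to the singular strong canard as
$C_m \downarrow 0.25$.

It does not establish: agreement with any particular experimental
recording; behaviour under periodic pacing (single pulses only); CICR- or
Na+-current-mediated EAD mechanisms (absent from the model by design); or
exact agreement with the original figures' pixel geometry, since the
original $V_{Ca}$ and grid ranges are unprinted and the canards here are
computed by a different (though equivalent) algorithm.
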