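---
title: "Methods: 1D pulse-wave hemodynamics of pulmonary arterial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 1D pulse-wave hemodynamics of pulmonary arterial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`pulsetree` simulates pulsatile blood flow in a bifurcating pulmonary
arterial tree and the lumped vasculature beyond it, and inverts such
simulations against sparse clinical-style measurements. The motivating
application is chronic thromboembolic pulmonary hypertension (CTEPH), where
obstruction raises pulmonary pressures, stiffens artery walls, and reshapes
wall shear stress — quantities that are hard or impossible to measure
directly and are therefore estimated through a calibrated model.

Each vessel segment is straight, cylindrical and impermeable, and blood is
incompressible, Newtonian and laminar. On each segment the cross-sectionally
averaged mass and momentum balances are

$$\partial_t A + \partial_x Q = 0, \qquad
\partial_t Q + \frac{\gamma+2}{\gamma+1}\,\partial_x\!\frac{Q^2}{A}
 + \frac{A}{\rho}\,\partial_x P
 = -\frac{2\pi\mu(\gamma+2)}{\rho}\frac{Q}{A},$$

with the power-law axial velocity profile
$u = \bar U\,\frac{\gamma+2}{\gamma}\bigl(1-(r/R)^\gamma\bigr)$. The profile
exponent defaults to $\gamma = 9$, a nearly flat profile appropriate for the
high Womersley numbers of proximal pulmonary arteries; $\gamma = 2$ recovers
the parabolic (Poiseuille) limit, which the test suite uses as an analytic
oracle. Blood density and viscosity default to 1.03 g/mL and 0.03 Poise.

The system is closed by a thin-walled linear-elastic tube law

$$P(A) = \frac{4}{3}\frac{Eh}{r_0}\left(\sqrt{A/A_{dia}} - 1\right) + P_{dia},$$

parameterized only through the composite stiffness $Eh/r_0$ (dyn/cm²), which
bundles structural and load-dependent stiffening and serves as a wall
physiomarker. Given measured systolic/diastolic MPA pressure and area the
stiffness is obtained analytically by inverting this law at systole
(`stiffness_from_systole()`), not by optimization.

## Numerics

Because $Eh/r_0$ and $A_{dia}$ are constant per segment, the pressure
gradient term admits an exact flux potential, so the equations are solved in
full conservation form with the two-step (Richtmyer) Lax–Wendroff scheme.
Choices a reader may want to audit:

* **Grid**: per-segment uniform, at least 5 nodes, `dx <= dx_target`
  (default 0.1 cm).
* **Time step**: `cfl * min(dx / (|u| + c))` with `cfl = 0.5`, re-verified
  every step against the current state; on violation the cycle restarts with
  a halved step. The wave speed is
  $c = \sqrt{\tfrac{2}{3}\tfrac{Eh}{r_0}\tfrac{1}{\rho}}\,(A/A_{dia})^{1/4}$.
* **Boundaries**: the characteristic invariants of this tube-law family are
  $W_\pm = u \pm 4c$ in closed form. Each boundary node couples the outgoing
  invariant (interpolated at the characteristic foot, with the friction
  source integrated along the path) to the physical condition: prescribed
  inlet flow, junction flow conservation plus pressure continuity
  ($Q_p = Q_{d1} + Q_{d2}$, $P_p = P_{d1} = P_{d2}$; no loss model, matching
  the plain-continuity assumption), or the three-element Windkessel relation
  integrated by implicit Euler. The small nonlinear systems are solved by
  damped Newton iteration to a relative residual of 1e-13 (capped at 30
  iterations); the worst junction residual over a whole run is reported and
  asserted below 1e-10 in the tests.
* **Inlet waveform**: resampled to the solver clock by FFT-based Fourier
  interpolation, preserving band-limited waveforms exactly.
* **Initial state and periodicity**: every run cold-starts from the
  diastolic rest state ($A = A_{dia}$, $Q = 0$, capacitor pressures at
  $P_{out}$) and repeats cycles until the end-of-cycle pressure field
  changes by less than `periodicity_tol` (default 1e-3 relative) between
  consecutive cycles, up to `max_cycles` (default 30). Non-convergence
  warns and returns the final cycle.
* **Units**: CGS internally (cm, s, dyn/cm²); mmHg and mL/s at the user
  interface with 1 mmHg = 1333.22 dyn/cm².

## Boundary parameter construction

Each terminal vessel carries a three-element Windkessel (proximal
resistance $R_p$, distal resistance $R_d$, compliance $C$, reference
pressure $P_{out}$ set to the mean wedge pressure, which is also the
downstream pressure in the PVR definition). Nominal values are built from
catheterization summaries:

* total resistance $(\bar P_{PA} - \bar P_{PCW})/\bar Q_{MPA}$ with
  $\bar P_{PA} = (P_{sys} + 2P_{dia})/3$;
* total compliance from the closed-form mono-exponential diastolic decay
  $C = T_d / (R \ln\frac{P_{sys}-\bar P_{PCW}}{P_{dia}-\bar P_{PCW}})$
  (a least-squares fit is used instead when a sampled diastolic trace is
  available — the scalar closed form matches the data situation where only
  systolic/diastolic values are recorded);
* per-terminal distribution by a Poiseuille argument. The distribution key
  is the *cumulative root-to-terminal* path resistance
  $\sum 8\mu L/(\pi r_0^4)$ — this reflects the whole upstream tree and
  reduces to the single-vessel formula for one outlet — uniformly rescaled
  so the parallel combination equals the measured total. $R_p = R_d = R_T/2$
  initially. Compliance is apportioned by terminal conductance $1/R_T$
  (keeping outlet time constants comparable) and sums to the measured total.
* when measured (or reconstructed) branch flows are available, the total
  conductance is first split between the lungs in proportion to mean
  branch flow, then distributed within each lung as above. This is how
  left-dominant obstruction enters the nominal parameters: a three-factor
  global calibration cannot create left/right asymmetry on its own, so the
  asymmetry must be carried by the nominal construction, which is also why
  the reconstructed left-lung flow
  $\tilde Q_{LPA} = Q_{MPA} - Q_{RPA}$ (`recompute_left_flow()`) matters in
  the obstructed state.

## Calibration

The free parameters are three global scaling factors
$\theta = (r_p, r_d, c)$ applied uniformly to every terminal's $R_p$, $R_d$
and $C$. The cost is the literal three-block sum of squares

$$S(\theta) = \sum_{j \in \{sys,dia\}} (P^c_j - P_j)^2
            + \sum_{j} (A^c_j - A_j)^2
            + \frac1N \sum_{k \in \{LPA,RPA\}} \sum_{i=1}^N
              (Q^c_k(t_i) - Q_k(t_i))^2,$$

evaluated in mmHg, cm² and mL/s. The mixed units mean the blocks are
implicitly weighted by their numeric scale; since those scales are
comparable here (tens of mmHg, ~2 cm², tens of mL/s) the literal form is
the default, and a `weighting = "relative"` switch normalizes each block by
its data scale for users who prefer dimensionless residuals. Model systole
and diastole are the extrema of the converged MPA inlet cycle, tracked at
full time resolution inside the solver.

Optimization is box-constrained ($[0.1, 10]^3$) Levenberg–Marquardt on the
residual vector with forward-difference Jacobians, run from ten log-uniform
random starts in $[0.25, 4]^3$ under a fixed seed; the package implements
this small routine itself (~60 lines) since no trust-region least-squares
solver is available in the dependency set. During optimization the
periodicity tolerance is relaxed tenfold for speed, and evaluations can
warm-start from the end state of a single nominal-parameter reference
simulation — the reference is fixed and $\theta$-independent, so the cost
landscape is unchanged while transient cycles are saved. Two stopping
controls are exposed per start: a relative cost-improvement threshold
(`ftol`) and an absolute floor (`min_cost`; with a relaxed periodicity
tolerance the attainable cost bottoms out near the solver's periodicity
error, so costs below that floor mean a solver-precision fit, not a better
model). The winning $\theta$ is re-simulated from the cold start at full
tolerance for reporting. Results are reproducible bit-for-bit for a fixed
seed. Fit quality is reported as $R^2$ per flow
series and a model-vs-data scalar table.

## Shear physiomarkers

The wall shear stress of the power-law profile is
$\tau = \mu\,\partial u/\partial r|_{r=R}$, magnitude
$\mu(\gamma+2)|\bar U|/R$. The stored field carries the sign of the local
flow — an always-positive magnitude would make oscillation undetectable —
while TAWSS integrates $|\tau|$:

$$\mathrm{TAWSS} = \frac1T\int_0^T |\tau|\,dt, \qquad
\mathrm{OSI} = \frac12\left(1 -
  \frac{|\int_0^T \tau\,dt|}{\int_0^T |\tau|\,dt}\right).$$

Per-segment values average the per-node metrics along the axis; extralobar
vessels (MPA/LPA/RPA) are reported singly and intralobar vessels as an
unweighted mean over segments (a length-weighted option exists). The
combined physiomarker $\phi$ is the percentage of network centerline length
whose nodes have both TAWSS < 5 dyn/cm² and OSI > 0.05, with each node
weighted by its local half-cell length; "region" granularity is not
uniquely defined by the source procedure, and node-by-length is this
package's declared choice. Both thresholds are configurable — the OSI
cutoff in particular derives from a cohort mean in the motivating study,
and a synthetic cohort has its own mean.

## The synthetic subject generator

No subject data are deposited with the motivating study, so the package
generates fully specified synthetic subjects; they are first-class, tested
code, not fixtures. A subject comprises a structured tree (MPA root, LPA/RPA
extralobar daughters, then self-similar bifurcations with daughter radius
ratio 0.79 — approximately Murray's law — and length five times the radius),
a half-sine inflow, a uniform wall stiffness, ground-truth Windkessels
(nominal construction perturbed by a known $\theta^*$), and noisy
pseudo-measurements extracted from a forward simulation.

Defaults describe a ~12 kg canine under anesthesia and are stated once,
not tuned: cycle length 0.5 s (HR 120/min), stroke volume 15 mL (mean flow
30 mL/s), ejection over 40% of the cycle, target MPA pressures 30/15 mmHg
(mPAP 20 mmHg, at the hypertension threshold used for the animals), wedge
pressure 5 mmHg, MPA diastolic area 1.75 cm² (the representative baseline
value in the motivating study), three bifurcation generations (15 segments
— the imaging-resolved network depth is not reported, and this keeps desk-
scale runtimes), and $Eh/r_0 = 1.5\times10^5$ dyn/cm² (~112.5 mmHg), which
gives a pulse-wave velocity near 3 m/s and ~20% systolic area distension.
Heart rate, stroke volume and wedge pressure are physiologic placeholders,
declared in configuration rather than claimed from data. Measurement noise
is multiplicative Gaussian (2% default) on the flow series only — the
MRI-derived flows are the noisiest channel in this kind of data set —
with scalar targets left noise-free.

The CTEPH transform multiplies left-lung terminal resistances by `severity`
(default 5), right-lung ones by `1 + (1 - left_fraction) * (severity - 1)`
(default `left_fraction = 0.8`, i.e. left-dominant obstruction as observed
in the animal model), divides the corresponding compliances by the same
factors (the study reports compliance falling as resistance rises, without
a quantitative link; an inverse tie per outlet is this package's choice),
and doubles wall stiffness by default. The inflow is left unchanged, so
unlike the animals — whose cardiac output fell — total flow is preserved
and redistributed; consequences: right-lung flow and RPA shear *rise* in
the synthetic CTEPH state, whereas MPA/LPA and mean intralobar shear fall
as in the study.

What a green test does and does not establish: the generator produces
smooth, noise-controlled, perfectly bifurcating networks whose measurement
model matches the simulator (no segmentation error, no imaging bias, no
respiratory or beat-to-beat variability). Recovery of $\theta^*$ and the
directional CTEPH findings on these subjects validate the machinery —
solver, nominal construction, optimizer, metrics — not the biological
magnitudes of the motivating study, whose subject-specific geometries and
measurements are unavailable.

## Degenerate inputs and edge cases

Collapse (tube-law root $\le 0$) raises an error rather than returning
complex areas; an identically zero shear series has undefined OSI and is
reported as 0 with an `undefined` flag; a constant data series makes $R^2$
undefined (flagged `NA`); simulation failure inside the optimizer returns a
large finite sentinel so the search continues; junction Newton
non-convergence aborts with the junction id.

## Known limitations

Fixed $\gamma$ over the whole tree overestimates shear in small arteries
(their Womersley numbers are lower); vessel taper, curvature, viscoelastic
walls, structured-tree outflows, respiration and 3D effects are out of
scope; the calibration estimates three global factors, not per-terminal
parameters, and provides no uncertainty quantification; cohort statistics
across subjects are left to the user.
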