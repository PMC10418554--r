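# pulsetree

One-dimensional pulse-wave hemodynamics of pulmonary arterial networks:
a nonlinear 1D blood-flow solver on bifurcating vessel trees with
three-element Windkessel outlets, multi-target calibration against sparse
pressure/area/flow measurements, and wall shear physiomarkers (TAWSS, OSI
and the combined low-shear/high-oscillation fraction φ).

## Who this is for

Researchers in computational hemodynamics and pulmonary vascular disease
who want to estimate quantities that catheterization and MRI cannot measure
directly — pressure and shear stress distributions deep in the lung
vasculature, wall stiffness, outlet resistance/compliance — from the
measurements those modalities *do* provide. The motivating disease is
chronic thromboembolic pulmonary hypertension (CTEPH), where obstruction
raises pressure, stiffens arteries and redistributes flow between lungs.

## The model in brief

On each straight cylindrical segment the solver integrates the
cross-sectionally averaged mass and momentum equations

∂A/∂t + ∂Q/∂x = 0,
∂Q/∂t + (γ+2)/(γ+1) ∂(Q²/A)/∂x + (A/ρ) ∂P/∂x = −2πμ(γ+2)/ρ · Q/A,

closed by the linear-elastic tube law
P = (4/3)(Eh/r₀)(√(A/A_dia) − 1) + P_dia
and a power-law velocity profile (γ = 9, near-flat, appropriate for high
Womersley number), using a two-step Lax–Wendroff scheme. Junctions enforce
flow conservation and pressure continuity; terminals carry RCR Windkessels;
the MPA inlet takes a prescribed flow waveform. Windkessel calibration
estimates three global scaling factors θ = (r_p, r_d, c) by ten-start
bounded Levenberg–Marquardt least squares against systolic/diastolic MPA
pressure and area plus LPA/RPA flow time series. Wall stiffness Eh/r₀ is
obtained analytically from measured systole, not fitted. See the methods
vignette (`vignettes/pulsetree-methods.Rmd`) for every numerical choice.

## Worked example

No subject data are deposited with the motivating animal study, so the
package ships a synthetic-subject generator (a stated, documented world —
see the vignette):

```r
library(pulsetree)

sub <- make_baseline_subject(seed = 42)   # ~12 kg canine defaults
m <- sub$measurements
round(c(Psys = m$Psys, Pdia = m$Pdia, Asys = m$Asys, Adia = m$Adia), 2)
#>  Psys  Pdia  Asys  Adia
#> 29.07 11.76  2.09  1.68        # mmHg / cm2; mPAP 17.5 mmHg

ct <- apply_cteph(sub)            # left-dominant obstruction, 2x stiffening
round(c(Psys = ct$measurements$Psys, Pdia = ct$measurements$Pdia), 2)
#>  Psys  Pdia
#> 65.73 26.92                     # pulmonary hypertension

# analytic wall stiffness from each state's own pseudo-measurements
stiffness_from_systole(m$Psys, m$Pdia, m$Asys, m$Adia)          # 110.1 mmHg
mc <- ct$measurements
stiffness_from_systole(mc$Psys, mc$Pdia, mc$Asys, mc$Adia)      # 234.0 mmHg

# shear physiomarkers before/after
sb <- summarize_network(shear_field(sub$solution, sub$props), sub$network)
sc <- summarize_network(shear_field(ct$solution, ct$props), ct$network)
c(sb$extralobar$LPA$tawss, sc$extralobar$LPA$tawss)   # 6.44 -> 3.66 dyn/cm2
c(sb$intralobar$tawss, sc$intralobar$tawss)           # 6.60 -> 5.63 dyn/cm2
c(sb$phi, sc$phi)                                     # 0.0  -> 8.6 %
```

The LPA and mean intralobar TAWSS fall and the fraction of the network with
both low shear (< 5 dyn/cm²) and high oscillation (OSI > 0.05) rises —
the directional signature of CTEPH this framework is designed to expose.

Calibration recovers known ground truth from noisy pseudo-measurements:

```r
sub <- make_baseline_subject(
  config = list(generations = 2, dx_target = 0.2,
                true_theta = c(1.5, 0.7, 1.3)), seed = 3)
ctx <- model_context(sub$network, sub$walls, sub$windkessels_nominal,
                     sub$inflow, sub$props, sub$sim)
calibrate_windkessels(sub$measurements, ctx, n_starts = 10, seed = 11)
#> <calibration_result> theta = (1.4969, 0.7029, 1.2884), cost 0.2389,
#>                      R2 LPA 0.999 / RPA 0.999
```

End-to-end (`run_pipeline()`) and paired comparison (`compare_states()`)
wrap the whole study replica; `inst/cli/pulsetree.R` exposes `synth`,
`simulate`, `calibrate`-style verbs on the command line.

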