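---
title: "Methods: multiscale electromechanics of Kir2.1 gain-of-function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale electromechanics of Kir2.1 gain-of-function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardioem` simulates the electromechanical consequences of gain-of-function
in the Kir2.1 inward-rectifier potassium channel (gene *KCNJ2*), the
substrate of short-QT syndrome type 3 (SQT3). The E299V substitution
increases I~K1~ not by raising the maximal conductance but by impairing
inward rectification, so the channel keeps conducting outward current
throughout the plateau. The pipeline follows that perturbation across four
scales: single-myocyte electrophysiology, desk-scale tissue conduction and
reentry, calcium-driven cross-bridge mechanics, and a closed-loop lumped
circulation. This vignette records the model equations in outline, every
calibrated constant with its rationale, the numerical choices, and the known
limitations — including which reference behaviours the desk-scale build does
*not* reproduce.

## Ionic myocyte model

The membrane follows the standard human ventricular formulation of the ten
Tusscher–Panfilov family:

$$\frac{dV}{dt} = -\frac{I_{ion} + I_{stim}}{C_m},\qquad
I_{ion} = I_{Na} + I_{K1} + I_{to} + I_{Kr} + I_{Ks} + I_{CaL} +
I_{NaCa} + I_{NaK} + I_{pCa} + I_{pK} + I_{bCa} + I_{bNa},$$

with the four-compartment calcium system (cytosol, subspace, SR, and the
ryanodine-receptor release gate) and twelve Hodgkin–Huxley gates of the 2006
model. All parameters keep their published values except:

* `g_Ks` = 0.392 × 1.3 mS/µF for endocardial and epicardial cells and
  0.073 mS/µF for the midmyocardial cell (the study's transmural
  assignment); `g_to` keeps the base model's endo/epi difference.
* I~K1~ is replaced by one of three closed-form current–voltage relations in
  the driving force $u = V - E_K$:
  * **WT**: $0.24731\,u \,/\, (0.86426 + e^{0.0904 u - 0.06519})$ — an
    inward rectifier with an outward hump near $u \approx 14$ mV;
  * **WT/E299V**: $0.11905\,(u + 2.4) \,/\, (0.04092 + e^{0.01732 u -
    0.36212})$ — weakened rectification, sustained outward current through
    the plateau;
  * **E299V**: $0.06634\,(u + 6.5) - 2.44009\times10^{-4} u^2 - 0.51383$ —
    rectification lost, quasi-ohmic.

**I~K1~ conductance calibration.** The printed rational forms under-predict
the reported peak current densities, so each formulation carries one
multiplicative conductance scale, fixed once so that the maximum over a
resting-to-peak voltage sweep equals the reported density: 1.9 pA/pF (WT,
scale ≈ 2.297) and 2.3 pA/pF (WT/E299V, scale ≈ 0.621). The pure-mutant
quadratic is used exactly as printed (scale 1) and *predicts* a peak above
4 pA/pF, which is the reported behaviour. Everything downstream — action
potential durations, restitution, alternans, conduction, force, pumping — is
a prediction, not a fit. The scales are recomputed from the curve at call
time (`ik1_current()`, `mutation_condition()`), not stored numbers.

**Steady-state protocol.** Cells are paced with 1-ms, −52 pA/pF pulses at
BCL 600 ms for 10 beats (6 s), matching the reference sinus protocol, and
measured on the final beat. APD is APD90: from the interpolated upward
crossing of −40 mV to 90 % repolarisation toward the pre-stimulus diastolic
potential. Longer pacing continues to drift the slow intracellular
concentrations (the midmyocardial APD lengthens from 393 ms at beat 10 to
~405 ms at beat 50), so the 6-s protocol is also what the acceptance script
uses.

With this construction the model reproduces the reference APD table to
within ±10 ms in seven of nine entries (both mutants at all cell types, and
the WT midmyocardial cell). The WT endocardial and epicardial APDs come out
~278/280 ms against reported 308/310 ms. This gap is structural: APD is
almost insensitive to the I~K1~ scale (284 → 276 ms across scales 1 → 2.3),
and closing it would require a `g_Ks` near 0.2 mS/µF, contradicting the
printed 0.392 × 1.3. We keep the printed parameters and report the
discrepancy rather than tuning it away.

## Restitution and alternans

The dynamic restitution protocol conditions the cell at BCL 600 ms, then
descends a BCL grid (default 400 → 200 ms in 10-ms steps; the midmyocardial
cell starts at 550 ms because its steady APD of ~390 ms meets immediate 2:1
block on a direct jump to 400 ms). Each BCL gets 30 equilibration beats and
8 measured beats, carrying state between BCLs. Alternans is declared when
the last four inter-beat APD differences all exceed 2 ms with alternating
sign; the onset is the largest flagged BCL, resolved to the 10-ms grid. The
curve truncates at capture loss. Slopes are central differences of APD
against diastolic interval; a local-quadratic fit serves as the independent
slope oracle in the tests.

Wild-type cells develop sustained alternans inside the scanned window
(endo ≈ 230 ms, mid ≈ 360 ms, epi ≈ 220 ms against reported 270/350/260 ms —
the endo/epi onsets are offset low, consistent with the shorter WT APDs
above); under both mutant conditions no alternans occurs in the window and
the maximum restitution slope stays well below 1 (≈ 0.4). Below ~110 ms the
mutants do alternate, outside the scanned range.

## Monodomain tissue

Tissue is an isotropic monodomain on 1D cables, closed rings, and 2D sheets:
explicit finite differences with no-flux (or periodic) boundaries, the
ionic reaction step shared bit-for-bit with the single-cell integrator (a
zero-diffusion grid reproduces the single cell to <10⁻⁶ mV). The diffusion
coefficient was calibrated once on an epicardial cable (dx = 0.025 cm,
dt = 0.02 ms) to the normal conduction velocity of 70 cm/s — `D_NORMAL` =
1.54·10⁻³ cm²/ms — and is held fixed across conditions (measured CVs:
69.9/69.4/71.1 cm/s). A reduced-excitability medium `D_LOW_CV` =
2.5·10⁻⁴ cm²/ms (~22 cm/s) hosts reentry, mirroring the reference protocol
of initiating reentry at low conduction velocity. The explicit stability
bound `dt ≤ dx²/(2·ndim·D)` is asserted before every run. CV(4D)/CV(D) = 2
holds within 5 % on the refined grid (dx = 0.0125 cm); at the production
spacing the ratio is ~2.12 because the baseline CV carries a small
lattice-slowing error.

Activation maps record, per node, the first upward crossing of −40 mV (EAT)
and the 90 %-repolarisation time of that activation (EDT); max EAT − min EAT
is the QRS-width surrogate and max EDT − min EAT the QT surrogate. On the
1.5-cm transmural cable (2 mm endo, 2 mm epi, mid between, endocardial-edge
stimulation standing in for the simultaneous Purkinje delivery) the QT
surrogate orders WT > WT/E299V > E299V (387/161/95 ms); absolute values are
desk-scale, not organ-scale.

**Reentry.** Two geometries:

* *Common ring* (7 cm, low-CV): anatomical reentry started by stimulating
  adjacent to a transiently blocked edge (the block lifts after the
  antidromic side is refractory). All three conditions sustain circulation;
  the wavelength is measured two ways — local CV × local APD at probes, and
  the excited arc length — which agree within 15 % and order
  WT > WT/E299V > E299V (≈ 4.6/2.2/1.5 cm).
* *Tightest sustaining ring* per condition (WT 5 cm, WT/E299V 3.5 cm,
  E299V 2.5 cm): fibrillatory activation is refractoriness-limited, so the
  fastest circuit the substrate supports sets the reentrant drive rate for
  the hemodynamic comparison (periods 279/182/158 ms — faster under the
  mutation, as in the reference).
* *2D spirals*: cross-field S1–S2 on a 3×3-cm low-CV sheet induces sustained
  spirals for the mutant conditions inside a vulnerable S2 window and not
  after full recovery. Spiral rotation periods at this domain size are
  conduction-limited (core-dominated), so period comparisons across
  conditions are made on the rings instead. A wild-type spiral does not fit
  on a desk-scale sheet at normal CV (wavelength ≈ 21 cm).

## Myofilament mechanics

Calcium drives a Rice-type regulatory-unit/cross-bridge cycle: troponin
binding `TCa`, nonpermissive/permissive fractions `N`/`P`, and two strongly
bound cross-bridge states `XB_PreR`/`XB_PostR` with mean distortions; the
four fractions are conservative. Switching rates are
`k_np (TCa/perm50)^{7.5}` forward and `k_pn (TCa/perm50)^{-7.5}` backward
(an equilibrium Hill coefficient of 15), both capped at 5 ms⁻¹ to bound the
ODE stiffness. Normalised force is the overlap-weighted distortion sum over
`x₀` times the maximal post-rotation duty fraction, so optimal conditions
give exactly 1; ATP turnover is the flux through the ATP-consuming
detachment, `g_xbT · XB_PostR`, averaged per beat. Operation is
isosarcometric at SL = 2.2 µm (one-way coupling).

Constants the source models leave open were set once and frozen: troponin
affinity 0.5 µM (the high-affinity regulatory site of the source
formulation) and `perm50` = 0.45, placing the cooperative midpoint between
the heterozygous and wild-type troponin occupancies so that the heterozygote
retains intermediate force — peak normalised forces 0.88/0.19/0.003 for
WT/WT-E299V/E299V, consistent with the reported intermediate heterozygous
pressures. Cross-bridge cycling rates are the source model's (f_app 500,
g_app 70, h_f 2000, h_b 400, g_xb 70 s⁻¹) with the published strain and
overlap modifiers.

## Closed-loop circulation

Eight compartments (LV, LA, RV, RA, systemic and pulmonary arteries and
veins) connected by resistances with diode valves; ventricles are
time-varying elastance chambers driven by the myofilament force,
`E(t) = E_min + (E_max − E_min)·F(t)/F_ref`, with `F_ref` fixed at the
wild-type force peak and reused unchanged for the mutants. Volume moves
strictly pairwise, so total blood volume is conserved to round-off. The
reference supplies no network constants, so a standard parameter set was
adopted and exactly three scalars calibrated once against the wild-type
Table-level values — `E_max_lv` = 2.8 mmHg/mL, `E_min_lv` = 0.17 mmHg/mL,
`R_sys` = 0.85 mmHg·s/mL — giving WT SV 59.2 mL, EF 54.6 %, stroke work
6033 mmHg·mL, peak LVP 125 mmHg at 100 bpm. Everything is then frozen and
only the force drive differs between conditions.

**Acute-onset comparison.** The circulation is settled under the wild-type
drive (30 beats) and every condition then runs 10 beats (6 s — the length
of the reference sinus simulation) from those settled volumes, with metrics
from the final beat. This reproduces the reference's comparison design: a
non-contracting ventricle congests at its pre-failure filling pressures,
shifting the mutant pressure–volume loops rightward. Run instead to each
condition's own steady state, the failing ventricle drains toward the
stagnation (mean-circulatory-pressure) equilibrium and the loops shift
*left* — the right-shift is a congestion transient, which is worth knowing
when interpreting the loops.

**Reentrant drive.** For the fibrillation-like comparison, the calcium of
12 probes spread around the tight ring is run through the myofilament and
the *spatial mean* of the regional forces drives the elastance —
desynchronised regional contraction is what flattens chamber-level force
during fibrillation, and a single-node drive misses it entirely.

## What the desk-scale build does not reproduce

* **WT endo/epi APD and alternans onsets** are ~10 % short of the reported
  values (see above); the mutant electrophysiology and the mid cell match.
* **SW/ATP ordering between WT and heterozygote.** In the 0D elastance
  surrogate both force and ATP flux are proportional to post-rotation
  occupancy: ATP tracks the force–time integral while stroke work tracks
  the force peak, so the short, peak-preserving heterozygous beat yields a
  *higher* SW/ATP than WT (≈ 630 vs ≈ 410) for every parameterisation
  tried. The reference's organ-level ATP falls far more slowly than its
  stroke work, which requires finite-element strain work this surrogate
  cannot represent. The orderings of SV, EF, SW, CO, peak LVP and ATP
  individually are all reproduced.
* **E299V reentry-vs-sinus pressure fluctuation.** The pure mutant's sinus
  drive is already non-contractile (LV pressure excursion < 1 mmHg), while
  any reentrant reactivation at fibrillatory rates reloads the SR and
  produces a few mmHg of tone; the within-condition inequality is
  ill-conditioned at desk scale (WT and heterozygote satisfy it clearly:
  44 < 110 and 25 < 40 mmHg).
* **Heterozygous EDV right-shift** is marginal (−0.7 mL vs WT) although the
  ESV and loop-position shifts are clear and the pure mutant's EDV exceeds
  WT's.
* Absolute organ-scale numbers (QT 480 ms, SV 59 mL, …) belong to the 3D
  anatomy and are targeted only through the one-time WT calibration plus
  cross-condition orderings.

## Numerical choices

* Operator-split fixed-step integration: Rush–Larsen exponential updates
  for the voltage gates (via 0.05-mV lookup tables with linear
  interpolation, rebuilt per run for the active dt), forward Euler for V
  and concentrations. Production dt = 0.02 ms (cell and tissue); a
  step-halving oracle holds the APD error at production dt under 1 ms.
* Equilibrium potentials are recomputed every 10 steps (0.2 ms); the
  underlying concentrations drift by < 10⁻³ mM/ms, so the error is
  ~10⁻⁴ mV while avoiding four log evaluations per node-step.
* Myofilament dt = 0.05 ms (rates capped at 5 ms⁻¹); circulation
  dt = 0.25 ms.
* Degenerate inputs are rejected with named errors: non-finite states,
  out-of-range voltages (naming the offending variable), unstable
  diffusion settings before the run, unknown labels, capture loss with the
  failing beat index.

## Synthetic calcium generator

`synthetic_ca_transient()` produces a periodic double-exponential transient
(exact peak `baseline + amplitude` at the requested time-to-peak) used to
exercise the myofilament stage in isolation: parameter-recovery and
monotonicity tests drive it with amplitude ramps. It emulates the amplitude
and timing of a paced-cell transient but none of the rate-dependent SR
loading, alternans, or beat-to-beat memory of the ionic model — passing
those tests shows the mechanics respond correctly to a known input, not
that the coupled pipeline is calibrated; the coupled tests use the ionic
model's own calcium.

## Problem sizes in the tests

The suite runs single-cell protocols at full production resolution; tissue
tests use the 1.5–4-cm cables, the 7-cm ring at 3 s, and a 3×3-cm sheet for
spiral induction at 1.2 s (the full reentry scenarios run 10 s on the 7-cm
ring; `make_scenario(..., reduced = TRUE)` selects the shorter variants the
tests use). Circulation tests run 6–60 s of simulated time.
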