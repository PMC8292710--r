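---
title: "Methods: ventilation-guided functional avoidance proton planning on a deformable lung phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ventilation-guided functional avoidance proton planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models

Lung cancer patients differ widely in *where* their lungs actually
ventilate. Respiration-correlated CT (4DCT) can map regional ventilation
without extra imaging: after deformable registration of the peak-exhale
and peak-inhale phases, the fractional change in the air content of each
exhale voxel follows from the Hounsfield units of the mapped voxel pair,

$$\frac{V_{in}-V_{ex}}{V_{ex}}
  \;=\; \frac{1000\,(HU_{in}-HU_{ex})}{HU_{ex}\,(1000+HU_{in})},$$

where 0 means no volume change and 1.0 means the voxel's air volume
doubled. Thresholding the ventilation image at 15% of its global maximum
yields a *functional lung* structure; a plan that preferentially spares
it (while holding target coverage and organ-at-risk constraints) is a
*functional avoidance* plan. This package implements that whole chain
for robustly optimized spot-scanning proton therapy — ventilation
imaging, structure derivation, robust spot-weight optimization, 4D
dynamic-delivery (interplay) simulation, and logistic NTCP estimates of
radiation pneumonitis risk — exercised end to end on a synthetic
deformable thorax whose ventilation is known in closed form.

## The phantom: a stated world with analytic ground truth

`build_reference_anatomy()` builds a 96^3, 2.5 mm isotropic thorax
(geometry expressed as fractions of the grid extent, so smaller test
grids carry the same anatomy): an elliptic body, two ellipsoidal lungs,
a central airway, esophagus / heart / spinal cord, a 10 mm radius tumor
in the right lung, and a smooth seeded air-fraction field
$f_{air}\in[0.3,0.8]$ in the parenchyma. The HU model is deliberately
the simplest one that closes the ventilation identity analytically:
$HU = -1000 f_{air}$ with soft tissue at 0 HU. A seeded "vasculature"
speckle (7% of lung volume, dense voxels that keep their HU across
phases) gives the intensity-based registration the anchors that real
lungs provide; like clinical processing, the ventilation domain excludes
vessels (their $f_{air}=0$ makes the identity singular, and the
implementation flags them invalid).

**Breathing deformation.** `synthesize_dvf()` composes, per lung, a
diaphragm-like cranio-caudal stretch — apex fixed, base displaced
inferiorly, so $\partial u_z/\partial z>0$ (expansion) throughout the
lung, with the compensating compression placed in the airless soft
tissue below the base — plus small seeded low-frequency bumps and a
lateral coupling term. The field is zero outside the body, rescaled so
its grid maximum equals the requested amplitude exactly (default 8 mm),
and rejected with the minimum Jacobian reported if it ever folds.
Tissue conservation then fixes the phase-$c$ air fraction:
$f_c = 1-(1-f_{air})/J_c$, hence ground-truth ventilation
$(J-1)/f_{air}$.

**The ventilation defect.** The study population was selected for a
regional ventilation reduction of at least 15%; the phantom therefore
ships with a defect in the middle third of the right lung in which the
*slope* of the axial stretch profile is attenuated to 5% and then
re-integrated. Attenuating the slope (rather than masking the
displacement) scales local expansion exactly without creating boundary
shear, keeping $J>0$. With the default geometry this produces a
regional deficit of ~22 percentage points — clearly eligible — while
`defect_factor = 1` produces an ineligible, homogeneous profile. The
defect sits in the *middle* third because the height-based thirds make
the inferior ellipsoid tip hold only ~14% of the expected share, so
even a total inferior defect could not reach a 15-point deficit; this
is a geometric property of height-based thirds worth knowing when
configuring the phantom.

**Tumor motion** is a rigid cranio-caudal translation (default 6 mm,
the cohort's median maximal amplitude, within the reported
0.2–2.1 cm range) superposed on the parenchymal field; the breathing
waveform is $c(t) = ((1-\cos 2\pi t/T)/2)^2$, dwelling near exhale as
quiet breathing does, with periods 3/5/7 s and max-inhale or max-exhale
start phases in the interplay study. Only periodic traces are
generated; breathing irregularity is out of scope.

## Two rendering paths, and what each one proves

`render_phase(mode = "pair")` returns, for every exhale voxel, the HU
value at its *exactly displaced* position — no resampling. Applying the
ventilation identity to these mapped pairs reproduces $(J-1)/f_{air}$
to ~1e-10 (an algebraic identity of the tissue-conservation model), and
that is what the 1e-6 closure criterion tests: the calculator, the
renderer and the Jacobian agree with each other exactly at
interpolation-free points.

`render_phase(mode = "grid")` resamples the phase onto the fixed grid
(fixed-point inversion of the deformation, trilinear interpolation) —
the realistic path every downstream stage uses. Resampling injects HU
errors of ~8 HU away from vessels (more near them, which is why the
parameter-recovery analyses evaluate ventilation outside a 1-voxel
vessel margin). Because the
ventilation signal itself is small ($J-1\sim0.1$), this interpolation
noise is not negligible: pushing the *true* displacement field through
the grid-resampled pathway yields a Spearman correlation with ground
truth of only ≈0.78 at 5 mm and 3.75 mm voxels and ≈0.85 at 2.5 mm.
That number is the *ceiling* for any registration at that resolution.
A green closure test therefore establishes the correctness of the
formula chain, not that grid-level ventilation imaging is noise-free —
a distinction the tests keep explicit, and the reason the
estimated-field recovery test asserts a clearly-positive correlation
(0.3) rather than the 0.8 reachable only on finer clinical grids.

## Registration

`register_deformable()` is a multiresolution (3 levels, x2) gradient
descent on the classic objective
$\sum(F-M\circ(id+u))^2+\lambda\|\nabla u\|^2$ — the same
SSD-plus-quadratic-penalty family as the study's algorithm, which is
not itself reproduced. Numerical choices that mattered in practice:
each pyramid level is pre-smoothed by a 1-voxel Gaussian (trilinear
interpolation makes the raw objective piecewise-smooth, and descent
stalls on the kinks without it); the per-voxel update is clipped to a
half-voxel trust region so edge voxels with huge intensity gradients
cannot dominate; and a backtracking line search guarantees the
objective trace is non-increasing — a tested invariant. Defaults:
$\lambda=25$, 200 iterations/level, relative-decrease tolerance 1e-6.
On noiseless phantom pairs with ≤8 mm fields the mean endpoint error is
~1 mm (the acceptance bound is one voxel); with 20 HU noise it stays
within twice that. Limitation: because exhale and inhale HU genuinely
differ at corresponding tissue (that difference *is* the ventilation
signal), SSD matching can trade correspondence against intensity
change; the regularizer limits but does not remove this, another reason
estimated-field ventilation is noisier than endpoint error suggests.

## Structures

iGTV = union of the tumor over all phases; CTV = iGTV + 8 mm (the
stated 6–10 mm range; configurable); PTV = CTV + 5 mm; expansions are
Euclidean-distance-transform dilations in physical mm, and the margin
chain's nesting is a tested invariant. Note that on a lattice the
composition of an 8 mm and a 5 mm dilation is a strict *subset* of a
single 13 mm dilation (a discretization fact the tests pin down with a
brute-force distance oracle). Lung-dose structures exclude the iGTV
(RTOG-style "total lung" convention; the study does not state its own). The
functional lung (normalized ventilation ≥ 15% of global max, inclusive)
is decomposed for the optimizer into functional-minus-PTV and
functional rings at 0–1 cm and 1–3 cm from the PTV — the study does not
describe its decomposition, so this ring recipe is this package's
choice, surfaced in `make_structures()`.

## Dose engine and planner

The study's commercial TPS and GPU Monte Carlo engines are out of
scope; the package needs a *linear, physically plausible,
scenario-aware* engine. Machine model: the stated 97 energies
(geometrically spaced over 71.3–228.8 MeV) with in-air sigma log-linear
through 5.7 mm and 2.5 mm at the endpoints; range
$R(E)=0.0022\,E^{1.77}$ cm; an analytic Bragg curve (entrance plateau,
Gaussian peak of range-straggling width, sigmoidal distal falloff,
exactly zero beyond the tail, unit peak); lateral Gaussian with
$\sigma^2(d)=\sigma_{air}^2+(0.03\,d)^2$; calibration fixed so a
reference spot gives 1 Gy[RBE] per 100 MU at its peak, with RBE 1.1
folded in. Beams are restricted to the four cardinal gantry angles so
water-equivalent depth is a cumulative sum along a grid axis (the study
does not report its beam angles; default is a left-lateral plus an
anterior field). Setup scenarios resample the CT by the negated shift
and read dose at the shifted position; range scenarios divide WEPL by
the scale, which provably moves the distal 80% falloff proportionally.
Spot placement covers the CTV's beam's-eye-view projection with one
in-patient sigma *plus* the 5 mm setup margin, and the energy-layer
span with a setup-plus-5%-range depth margin — a lesson learned the
hard way: with a bare one-beam-sigma apron, shifted-scenario CTV edge
voxels have no spots at all, and no re-weighting can ever restore
worst-case coverage.

Optimization is projected gradient descent on non-negative spot MU with
a backtracking line search (objective trace non-increasing, tested).
The robust target term is the *expectation* over the 21-scenario grid
(±5 mm axis shifts × ±5% range — the magnitudes are the study's, the
7×3 grid is common TPS convention) of the squared deviation from
prescription over the CTV; OAR and functional terms are one-sided
quadratics on the nominal dose (the operation contract; the
alternative all-scenario functional mean was considered and rejected
for its 21-fold influence cost at desk scale). If the worst-case
scenario V95 of the CTV falls below 95%, the target weight is doubled
and the plan re-optimized (warm-started), up to 3 rounds — the study's
own escalation rule — and failure to pass is reported, never silent.
Plans are finally rescaled so CTV D99 equals 99% of prescription
exactly (dose linearity makes this a single global factor). Default
OAR levels are RTOG-style placeholders, configurable, because the
protocols' numbers are not printed.

## Interplay

Delivery is simulated as a single fraction (the worst case for
interplay). Max-MU iso-layer repainting delivers each layer
$\lceil\max_j w_j/MU_{max}\rceil$ times at $w_j/N$ per paint, exactly
conserving MU (tested). The timeline advances by MU/rate per spot plus
a 2 ms spot switch and a 2 s layer switch at 100 MU/s — stand-in
values, configurable, because the validated synchrotron parameters are
cited but not printed; synchrotron spill structure is likewise omitted.
Each delivery event is binned to the nearest of the 10 4DCT phases by
the waveform value at its completion time, deposits on that phase's CT,
and each phase dose is pulled back to the exhale grid by trilinear
sampling through the known phase field (no mass-energy correction —
adequate for the smooth phantom fields). Two limits anchor correctness:
zero motion reproduces the nominal dose to 1e-6, and many repaints over
a short period converge to the phase-time-weighted average dose within
2%, both tested. The scenario grid is the stated 2 starts × 3 periods.

## Metrics, statistics, NTCP

DVH metrics use exact voxel counting ($V_x$) and the sorted-voxel rule
($D_x$ = minimum dose to the hottest x%), verified against brute-force
oracles on ≤100-voxel instances. The conformity index is prescription
isodose volume over CTV volume and the homogeneity index D5/D95 —
the study does not report its definitions; these RTOG-style choices are
consistent with the magnitudes it reports and are config-switchable in
the sense that the metric layer computes any Dx/Vx on request.
Statistical comparison mirrors the study: one-way ANOVA at alpha 0.05
(computed both across all plan groups and per modality, since the
study's reported layout is ambiguous) and post-hoc paired t-tests with a
Bonferroni-corrected alpha, 0.05/24 ≈ 0.002 for the Table-2-sized
family of 24 metrics. The pneumonitis NTCP model is logistic in fV20,
fV30 or fMLD; the published coefficients are treated as configuration
and are not reproduced here, so the shipped defaults are synthetic
placeholders (provenance-tagged `synthetic-default`) whose output
magnitudes are merely plausible. Absolute risk reduction is
p(standard) − p(functional) per patient and metric; monotonicity
guarantees the reduction is non-negative whenever the functional plan
dominates the metric and the slope is positive.

## What a green run establishes — and what it does not

The acceptance suite shows that, on this phantom: the ventilation
calculator reproduces its worked values exactly; the rendered phases,
the true Jacobian and the calculator close analytically; an eligible
defect leads to a functional plan that lowers fMLD and fV20 relative
to the standard plan while both hold worst-case V95 ≥ 95% over all 21
scenarios; normalization pins D99 at 99% of prescription to float
tolerance; and the interplay simulator passes its zero-motion and
phase-averaging limits. It does *not* establish clinical dosimetry:
the phantom has no CT texture or noise beyond optional Gaussian HU
noise, no hysteresis or cardiac motion, an analytic pencil-beam rather
than Monte Carlo transport, and synthetic NTCP coefficients — so the
cohort values of the study (its Tables 2–5) are intentionally out of
scope, and the headline is reproduced *directionally*, not
numerically.
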