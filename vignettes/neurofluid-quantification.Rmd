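---
title: "Quantifying neurofluid pulsatility from velocity-encoded cine MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurofluid pulsatility from velocity-encoded cine MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmriflow)
```

## The measurement problem

Phase-contrast MRI (PCMRI) encodes through-plane velocity into pixel
phase: a cine acquisition gated to the cardiac cycle yields, for each
acquisition plane, a movie of velocity maps reconstructed at 32 phases of
one averaged heartbeat. From these maps one can quantify, plane by plane,
the pulsatile flows that couple the intracranial compartments: arterial
inflow through the internal carotid and vertebral arteries, venous
outflow through the internal jugular veins, the oscillation of
cerebrospinal fluid (CSF) at the aqueduct, the foramen magnum and the
cervical canal, the tissue motion of the cerebellar tonsils, and — when a
syringomyelia cavity is present — the fluid oscillation inside the
syrinx. In Chiari malformation type 1 the tonsils crowd the foramen
magnum, restricting the CSF pathway; the quantities above, and how they
change after decompression surgery, are the object of study.

No patient data accompany this package. Its synthetic-phantom module
generates velocity cines with known ground truth under the same
acquisition conventions (32 phases; velocity-encoding limits of 5 cm/s
for CSF and tissue planes, 10 cm/s at the aqueduct, 80 cm/s for the neck
vessels), so every stage of the pipeline can be validated end to end.

## Flow, stroke volume, amplitude

For a region of interest (ROI) with pixel area $dx\,dy$ the volumetric
flow at phase $k$ is

$$Q(t_k) = \sum_{p \in \mathrm{ROI}} v(p, t_k)\, dx\, dy ,$$

with $v$ in cm/s and areas in mm², hence a factor 10 into mm³/s. The
**stroke volume** over the cycle of period $T$ with $n$ phases uses
rectangular quadrature, $\Delta t = T/n$, matching the discrete cine
reconstruction (no spline resampling):

$$V_f = \sum_k \max(Q_k, 0)\,\Delta t,\qquad
  V_b = \sum_k \max(-Q_k, 0)\,\Delta t,\qquad
  SV = \tfrac12 (V_f + V_b),$$

the average of the cranio-caudal and caudo-cranial displaced volumes, in
µL per cardiac cycle. For a zero-mean oscillation the two directional
volumes coincide and $SV$ equals either one. The **peak amplitude** of a
flow curve is taken as peak-to-peak, $\max Q - \min Q$, which makes the
venous amplitude independent of the curve's mean level; the alternative
reading (largest deviation from the mean) is available as
`peak_amplitude(mode = "from_mean")`.

Sign conventions are global and explicit: stored velocity is positive
for cranio-caudal through-plane flow. Arterial inflow at the neck is
therefore stored negative and re-oriented at curve construction
(`direction = "caudocranial"`), decided by the plane's anatomy and never
by the sign of the measured mean, which would silently mask segmentation
errors.

## The cerebral arteriovenous balance

With inflow-positive arterial curves and outflow-positive jugular
curves,

$$\mathrm{CBF}_a = \sum_{\text{2 carotids, 2 vertebrals}} Q, \qquad
  \mathrm{CBJF} = \sum_{\text{2 jugulars}} Q .$$

The jugular veins do not drain all cerebral blood; epidural and other
accessory routes participate. The **venous correction factor**

$$f = \frac{\overline{\mathrm{CBF}_a}}{\overline{\mathrm{CBJF}}}$$

(cycle means) quantifies this: $f = 1$ means exclusively jugular
drainage, $f = 2$ means half of the drainage bypasses the jugulars. The
**corrected venous curve** is $f \cdot \mathrm{CBJF}$; by construction
its mean equals the arterial mean, so the **arteriovenous curve**
$\mathrm{CBF}_a - f\cdot\mathrm{CBJF}$ has zero cycle mean and its
stroke volume ($SV_{vasc}$) measures the intracranial blood-volume
expansion per cardiac cycle. These identities ($f=1 \Rightarrow$
corrected $=$ CBJF; mean of the AV curve $= 0$ to $10^{-9}$ relative;
invariance of $f$ under velocity rescaling) are asserted numerically in
the test suite. Whether the venous amplitude is read off the raw CBJF
curve or the corrected one is a genuine ambiguity; the default is the
raw CBJF (`amp_on = "cbjf"`), switchable per call.

## Semi-automatic delineation

The delineation algorithm is this package's own design (the study used
unpublished in-house software described only as "semi-automatic"):
**correlation-thresholded region growing**. From a single operator seed
the region grows 4-connected; a candidate pixel joins when

* the Pearson correlation of its temporal velocity profile with the
  current region mean profile is at least `r_min` (default 0.7), and
* its peak-to-peak velocity is at least `amp_frac` times the seed's
  (default 0.1 for vessels and CSF, 0.02 for tissue).

Temporal-profile correlation is the velocity-domain analogue of
intensity similarity in classical region growing, and it is what makes
vessel/CSF discrimination testable: adjacent structures with
anticorrelated waveforms are never merged even when both are strongly
pulsatile. The region mean is updated incrementally; the frontier is
breadth-first with a fixed neighbour order (up, down, left, right) and
each pixel is examined once, so the result is order-deterministic.
Flat (zero-variance) profiles can never join — with the thresholds fully
released the region floods exactly the nonflat connected component. One
static mask serves all 32 phases; per-phase lumen re-segmentation is a
deliberate simplification. Manual masks (NIfTI label maps) can be
loaded in place of seed-grown ones.

The tissue default `amp_frac = 0.02` reflects that tonsil velocities are
an order of magnitude below CSF velocities on the same plane; the
separation between tonsil tissue and surrounding CSF then rests on the
correlation criterion, which works because tonsil motion is not in phase
with the CSF flush (the phantom renders it a quarter cycle later).

## Aliasing and offsets

Velocities beyond the encoding limit wrap by multiples of $2\,VENC$ into
the half-open interval $[-VENC, +VENC)$ (half-open so the wrap map is a
bijection). `unwrap_temporal()` resolves aliasing along the cardiac-phase
axis, pixel by pixel: the profile is anchored at its phase of minimal
absolute velocity — the sample most likely unaliased, which also
recovers constant aliased plateaus reached from a quiet baseline — and
walked circularly, shifting each sample by the multiple of $2\,VENC$
nearest to its unwrapped predecessor. This is exact whenever the true
excursion stays below $2\,VENC$ and per-phase steps stay below $VENC$
(property-tested); pixels beyond that are flagged `irrecoverable`, never
silently accepted.

Eddy-current residuals appear as small spatially constant per-phase
velocity offsets. `baseline_correct()` estimates them as the per-phase
mean over a user-identified static region and subtracts them slice-wide.
The estimate's noise scales as $\sigma/\sqrt{n_{\text{static}}}$ and is
subtracted coherently from every ROI, so the static reference should be
large; the synthetic exams use a full-width 4-row band. Whether the
original study applied such a correction is unstated, so the step is
optional in the pipeline (`baseline = FALSE`).

## The synthetic phantom

Waveforms are truncated Fourier series (at most 8 harmonics),
$Q(t) = \bar{Q} + \sum_j A_j \sin(2\pi j t/T + \phi_j)$: cycle means are
exact by construction and stroke volumes are available by exact
quadrature on the reconstruction grid. Harmonic indices that are
multiples of the phase count are rejected (they would alias to a
constant and break the exact-mean invariant). The builders produce:

* **arterial** curves: mean plus a sharp von Mises-shaped systolic pulse
  (harmonic amplitudes $2 I_j(\kappa)/I_0(\kappa)$, $\kappa = 6$),
  peak-to-peak scaled to the pulsatility target;
* **venous** curves: the same family damped ($\kappa = 2$), with the
  summed jugular peak-to-peak calibrated on the 32-phase grid to the
  venous-amplitude target exactly;
* **CSF/tissue** curves: zero-mean biphasic oscillations whose
  amplitudes are scaled so the grid stroke volume hits the target
  exactly — which is what makes the ground truth exact rather than
  approximate. A CSF spec must keep its net flow within 5% of its
  peak-to-peak amplitude.

Rendering puts a spatially uniform velocity $Q(t)/(n_{px}\,dx\,dy)$ in
each ROI (ROIs are disjoint by validation), adds the per-phase offset
and i.i.d. Gaussian noise, and applies the aliasing wrap. Ground truth
(true curves, stroke volumes, amplitudes, pixel sets, per-phase offsets,
and an unwrap-safety flag for ROIs beyond $2\,VENC$) is returned
alongside and serialized with the NIfTI + JSON-sidecar bundle.

A full synthetic exam (`simulate_subject_exam()`) renders five planes
with the acquisition geometry scaled to small grids (24–64 px across,
1 mm pixels, discs of 2–5 px radius) so that a complete
render-and-quantify cycle takes a fraction of a second; the suite's
end-to-end checks run 20 such subjects. Mean arterial inflow defaults to
9000 mm³/s (≈540 mL/min, mid-range for adults) since the study reports
only the venous amplitude and the correction factor, and mean jugular
outflow follows as $\mathrm{CBF}_a/f$. $SV_{vasc}$ in a rendered exam is
emergent from the waveform shapes rather than directly dialled; recovery
is therefore always judged against the generator's own ground truth.

What the phantom deliberately does **not** model: spatially varying
offset fields, partial-volume edges (ROI velocity is uniform),
intra-voxel dephasing, respiratory modulation, heart-rate variability
between acquisitions, or anatomically realistic geometry. Passing the
recovery tests therefore shows the measurement chain is correct and
noise-robust under these idealisations — not that segmentation of real,
partial-volumed anatomy is solved.

## The paired cohort generator

`sample_cohort()` draws per-parameter $(pre, post)$ pairs from a
bivariate normal with the study's marginal means and SDs (its defaults
are the published cohort summaries: e.g. preoperative tonsil stroke
volume 323 ± 175 µL/CC, venous amplitude 5578 ± 2469 mm³/s, correction
factor 1.38 ± 0.3) and within-subject correlation $\rho$. Only marginal
summaries are published, so $\rho$ is a free parameter; the default 0.7
is a typical test–retest correlation for repeated hemodynamic measures.
Truncation (stroke volumes and amplitudes at 0, the factor at 1) is done
by resampling, not clipping, to avoid a point mass at the bound. Syrinx
status (12/21) and surgery type (12/21 duraplasty) are assigned by
sampling fixed group sizes; the syrinx stroke volume exists only in the
syrinx subgroup.

## Cohort statistics

Paired pre/post comparisons use the two-sided Wilcoxon signed-rank test:
zero differences dropped, exact null distribution for up to 25 untied
differences, normal approximation with tie correction otherwise;
all-zero differences yield a degenerate result ($p = 1$, flagged). The
suite checks the exact branch against an exhaustive $2^n$
sign-enumeration oracle. Group comparisons (syrinx vs no-syrinx;
surgery types) use Student's t-test with pooled variance (Welch
optional). Percent change is $100 \times post/pre$ — the convention
under which values below 100% are decreases; the reverse reading is
inconsistent with that decrease rule. No multiple-testing correction is
applied by default, matching the per-row $\alpha = 0.05$ convention of
the original tables.

`build_tables()` assembles the three result tables (preoperative
syrinx/no-syrinx comparison; paired pre/post comparison; percent-change
comparison between surgery groups) from the full cohort. The published
tables imply differing patient subsets for some rows (the preoperative
foramen-magnum stroke volume differs between the stratified and paired
tables); this package computes every table from the full cohort and does
not attempt to reconcile that subset ambiguity.

A note on power: under the published marginals with $\rho = 0.7$ and
$n = 21$, the paired tonsil and foramen-magnum effects are detected in
essentially every simulated cohort, while the venous-amplitude effect
standardizes to ≈0.56 and is detected in only ≈60% of cohorts — the
acceptance suite reports this rate as measured. A higher true
within-subject correlation than 0.7 would be needed for the amplitude
effect to reach the significance observed in the original cohort.

## Numerical choices and degenerate inputs

* Quadrature: rectangular over the reconstructed phases everywhere; no
  interpolation except periodic linear resampling when combining curves
  reconstructed on different phase grids.
* Velocities are physical cm/s in double precision end to end; no
  scanner integer phase units.
* Curves combined by the model must agree in phase count and period
  (relative period tolerance $10^{-6}$); mismatches are errors, not
  silent resampling.
* The correction factor requires a positive mean jugular flow; profiles
  whose stored factor disagrees with the stored means beyond $10^{-6}$
  relative are rejected; factors below 1 are flagged with a warning but
  kept, as they indicate a measurement problem worth seeing.
* Flat seed profiles are invalid seeds; empty masks are invalid masks;
  3D volumes without a phase axis are format errors.

## Problem sizes

The test suite simulates at deliberately small scale — 20 full exams for
recovery, 200 cohorts for the significance sweep, 1000 single-parameter
cohorts for the type-I-error check, property loops of 30–100 draws —
chosen so the whole suite completes in well under a minute while keeping
Monte-Carlo standard errors a few percent at most.
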