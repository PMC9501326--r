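# pcmriflow

Quantification of neurofluid pulsatility from velocity-encoded cine
phase-contrast MRI (PCMRI), built around the hemodynamic picture used to
study Chiari malformation type 1: restricted CSF oscillation at the
foramen magnum, compensatory pulsatility of the cerebellar tonsils, and
altered cerebral venous drainage, before and after decompression
surgery.

For each acquisition plane (aqueduct, foramen magnum CSF + tonsils,
cervical CSF, syrinx, cervical vessels) the package turns a cine
velocity series into flow curves and the standard summary parameters:

- **Stroke volume** of an ROI over the cardiac cycle of period *T* with
  *n* reconstructed phases (rectangular quadrature, Δt = T/n):
  `SV = (V_forward + V_backward) / 2`, the average of the cranio-caudal
  and caudo-cranial displaced volumes, in µL per cardiac cycle (CC).
- **Peak amplitude** of a flow curve: `max(Q) − min(Q)` (mm³/s).
- **Cerebral arterial inflow** `CBFa` (sum of both internal carotid and
  both vertebral artery curves) and **jugular outflow** `CBJF` (sum of
  both internal jugular curves).
- **Venous correction factor** `f = mean(CBFa) / mean(CBJF)`: 1 means
  exclusively jugular drainage, values above 1 measure accessory venous
  drainage routes.
- **Arteriovenous balance** `CBFa − f·CBJF`, a zero-mean curve whose
  stroke volume (`SVvasc`) is the intracranial blood-volume expansion
  per cardiac cycle.

Because no patient data are available, the package ships a synthetic
velocity phantom with exact ground truth: truncated-Fourier pulsatile
waveforms, velocity aliasing beyond the encoding limit (VENC),
eddy-current per-phase offsets, Gaussian noise, and a paired pre/post
cohort sampler whose defaults reproduce the published cohort summary
distributions. The measurement pipeline — temporal phase unwrapping,
static-region baseline correction, correlation-thresholded region
growing from operator seeds, flow quantification, hemodynamic assembly,
and the paired/grouped cohort statistics — is validated end to end
against that ground truth. The methods vignette
(`vignettes/neurofluid-quantification.Rmd`) documents the model, the
algorithmic choices and the phantom's limitations.

## Worked example

Simulate one complete exam (five acquisition planes, 5% velocity noise,
aliasing and offsets included), then quantify it back from the images
alone:

```r
library(pcmriflow)

ex <- simulate_subject_exam(noise_frac = 0.05, seed = 42)
profile <- quantify_exam(ex)
print(profile)
#> <subject_profile> stage pre, syrinx
#>   sv_aqueduct        39.23
#>   sv_foramen         200.3
#>   sv_tonsils         324.5
#>   sv_cervical        434.1
#>   sv_vascular        860.7
#>   sv_syrinx          118
#>   amp_venous         5731
#>   correction_factor  1.378
```

Stroke volumes are in µL/CC, `amp_venous` in mm³/s. The generator's
targets for this subject were 39 / 201 / 323 / 434 / 118 µL/CC, venous
amplitude 5578 mm³/s and correction factor 1.38; every field is
recovered within a few percent despite the noise, and exactly (to
machine precision) when `noise_frac = 0`:

```r
truth <- ground_truth_profile(ex)
sprintf("correction factor: measured %.3f, truth %.3f",
        profile$correction_factor, truth$correction_factor)
#> "correction factor: measured 1.378, truth 1.380"
```

## Analysis workflow

The `analysis/` scripts run the study-style analysis over synthetic
data, writing all outputs under `results/`:

```sh
Rscript analysis/01_simulate.R   # render one exam to NIfTI + sample the n=21 cohort
Rscript analysis/02_quantify.R   # read the images back, quantify, compare with truth
Rscript analysis/03_cohort.R     # the three comparison tables + a 200-seed power sweep
Rscript analysis/04_figures.R    # CSF pulsatility and arteriovenous-balance figures
```

`02_quantify.R` reports the per-parameter recovery error of the
quantified exam; `03_cohort.R` builds the syrinx/no-syrinx, pre/post and
percent-change-by-surgery tables and measures how often the paired
Wilcoxon test detects the simulated postoperative effects across 200
resampled cohorts.

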