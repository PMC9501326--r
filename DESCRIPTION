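Package: pcmriflow
Title: Phase-Contrast MRI Neurofluid Flow Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of cerebrospinal fluid, cerebral blood and
    tonsil-tissue pulsatility from velocity-encoded cine phase-contrast MRI.
    Provides a synthetic velocity-phantom generator with known ground truth
    (truncated-Fourier pulsatile waveforms, velocity aliasing, eddy-current
    offsets, Gaussian noise, paired pre/post cohorts), NIfTI cine series I/O
    with temporal phase unwrapping and static-tissue baseline correction,
    correlation-thresholded region growing for vessel/CSF/tissue delineation,
    flow-curve and stroke-volume quantification, the venous correction factor
    and cerebral arteriovenous balance model, and paired/grouped cohort
    statistics in the style of a pre/post surgical comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
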