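# Cerebral hemodynamic assembly: arterial/jugular sums, the venous
# correction factor, the corrected venous curve, and the arteriovenous
# balance.

check_aligned <- function(curves) {
  n <- vapply(curves, `[[`, 0L, "n_phases")
  if (length(unique(n)) != 1L) {
    stop_pcmri("flow curves have different phase counts (",
               paste(n, collapse = ", "),
               "); resample with resample_flow_curve() first",
               class = "alignment_error")
  }
  Tt <- vapply(curves, `[[`, 0, "cardiac_period")
  if (max(Tt) - min(Tt) > 1e-6 * max(Tt)) {
    stop_pcmri("flow curves have different cardiac periods",
               class = "alignment_error")
  }
  invisible(TRUE)
}

sum_curves <- function(curves, label) {
  check_aligned(curves)
  q <- Reduce(`+`, lapply(curves, `[[`, "flow"))
  flow_curve(q, curves[[1]]$cardiac_period, label = label)
}

#' Cerebral arterial blood flow (CBFa)
#'
#' Sum of the flow curves of the two internal carotid and the two vertebral
#' arteries, all oriented inflow-positive. Curves must share phase count and
#' cardiac period; curves from acquisitions reconstructed on a different
#' grid are aligned with [resample_flow_curve()] first.
#'
#' @param carotid_left,carotid_right,vertebral_left,vertebral_right
#'   inflow-positive [flow_curve()] objects.
#' @return the summed [flow_curve()], labelled `"CBFa"`.
#' @export
arterial_flow <- function(carotid_left, carotid_right,
                          vertebral_left, vertebral_right) {
  sum_curves(list(carotid_left, carotid_right, vertebral_left,
                  vertebral_right), "CBFa")
}

#' Cerebral jugular blood flow (CBJF)
#'
#' Sum of the flow curves of the two internal jugular veins, oriented
#' outflow-positive.
#'
#' @param jugular_left,jugular_right outflow-positive [flow_curve()]
#'   objects.
#' @return the summed [flow_curve()], labelled `"CBJF"`.
#' @export
jugular_flow <- function(jugular_left, jugular_right) {
  sum_curves(list(jugular_left, jugular_right), "CBJF")
}

#' Venous correction factor
#'
#' The jugular veins do not drain all of the cerebral arterial inflow;
#' epidural and other accessory veins take part. The venous correction
#' factor, `mean(CBFa) / mean(CBJF)` over the cycle, quantifies this: a
#' factor of 1 means exclusively jugular drainage, while values above 1
#' measure the magnitude of accessory drainage routes (2 means half the
#' drainage bypasses the jugulars).
#'
#' @param cbfa inflow-positive arterial sum curve.
#' @param cbjf outflow-positive jugular sum curve; its cycle mean must be
#'   positive.
#' @return the dimensionless correction factor.
#' @export
venous_correction_factor <- function(cbfa, cbjf) {
  stopifnot(inherits(cbfa, "flow_curve"), inherits(cbjf, "flow_curve"))
  mj <- cycle_mean(cbjf)
  if (mj <= 0) {
    stop_pcmri("mean jugular flow must be positive to define the venous ",
               "correction factor", class = "degenerate_drainage")
  }
  cycle_mean(cbfa) / mj
}

#' Corrected total venous outflow curve
#'
#' The theoretical total venous outflow, `factor x CBJF`. By construction
#' its cycle mean equals the arterial cycle mean; with a factor of 1 it is
#' the jugular curve itself.
#'
#' @param cbjf outflow-positive jugular sum curve.
#' @param factor venous correction factor (> 0).
#' @return the corrected venous [flow_curve()], labelled `"correctedCBFv"`.
#' @export
corrected_venous_curve <- function(cbjf, factor) {
  stopifnot(inherits(cbjf, "flow_curve"))
  assert_scalar_number(factor, "factor", positive = TRUE)
  flow_curve(factor * cbjf$flow, cbjf$cardiac_period,
             sign_convention = cbjf$sign_convention, label = "correctedCBFv")
}

#' Cerebral arteriovenous flow curve
#'
#' Pointwise difference `CBFa - correctedCBFv`: the instantaneous imbalance
#' between arterial inflow and (corrected) venous outflow, i.e. the rate of
#' change of intracranial blood volume over the cycle. Its cycle mean is
#' zero to numerical precision because the correction factor equalises the
#' two means.
#'
#' @param cbfa inflow-positive arterial sum curve.
#' @param corrected_cbfv the [corrected_venous_curve()].
#' @return the arteriovenous [flow_curve()], labelled `"AV"`.
#' @export
arteriovenous_curve <- function(cbfa, corrected_cbfv) {
  stopifnot(inherits(cbfa, "flow_curve"), inherits(corrected_cbfv, "flow_curve"))
  check_aligned(list(cbfa, corrected_cbfv))
  flow_curve(cbfa$flow - corrected_cbfv$flow, cbfa$cardiac_period,
             sign_convention = "positive = net intracranial blood inflow",
             label = "AV")
}

#' Arteriovenous (vascular) stroke volume
#'
#' Stroke volume of the arteriovenous curve, computed exactly like a CSF
#' stroke volume. Because the arteriovenous curve has zero mean, its
#' forward and backward displaced volumes coincide and the stroke volume
#' equals either one: the intracranial blood-volume expansion per cardiac
#' cycle (uL/CC).
#'
#' @param av_curve the [arteriovenous_curve()].
#' @return stroke volume in uL/CC.
#' @export
vascular_stroke_volume <- function(av_curve) {
  stroke_volume(av_curve)$sv
}

#' Per-exam subject profile
#'
#' The parameter set a single phase-contrast exam yields: CSF stroke
#' volumes at the aqueduct, foramen magnum and cervical levels, tonsil
#' tissue stroke volume, the arteriovenous stroke volume, the venous flow
#' amplitude, the venous correction factor, and (when a syrinx is present)
#' the syrinx stroke volume.
#'
#' The stored factor must agree with `mean_cbfa / mean_cbjf` to 1e-6
#' relative; an inconsistent profile is rejected. Factors below 1 are
#' physiologically suspect (they would mean jugular outflow exceeding
#' arterial inflow) and are flagged via a warning, not rejected.
#'
#' @param sv_aqueduct,sv_foramen,sv_tonsils,sv_cervical stroke volumes,
#'   uL/CC.
#' @param sv_vascular arteriovenous stroke volume, uL/CC.
#' @param sv_syrinx syrinx stroke volume in uL/CC, or `NULL` when no syrinx
#'   series was acquired.
#' @param amp_venous peak-to-peak amplitude of the venous flow curve,
#'   mm^3/s.
#' @param correction_factor venous correction factor.
#' @param mean_cbfa,mean_cbjf cycle-mean arterial and jugular flow, mm^3/s.
#' @param exam_stage `"pre"` or `"post"` (operative).
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(sv_aqueduct, sv_foramen, sv_tonsils, sv_cervical,
                            sv_vascular, amp_venous, correction_factor,
                            mean_cbfa, mean_cbjf, sv_syrinx = NULL,
                            exam_stage = c("pre", "post")) {
  exam_stage <- match.arg(exam_stage)
  req <- list(sv_aqueduct = sv_aqueduct, sv_foramen = sv_foramen,
              sv_tonsils = sv_tonsils, sv_cervical = sv_cervical,
              sv_vascular = sv_vascular, amp_venous = amp_venous,
              correction_factor = correction_factor,
              mean_cbfa = mean_cbfa, mean_cbjf = mean_cbjf)
  for (nm in names(req)) {
    if (is.null(req[[nm]]) || !is.numeric(req[[nm]]) || !is.finite(req[[nm]])) {
      stop_pcmri("missing or non-finite required field: ", nm,
                 class = "incomplete_exam")
    }
  }
  if (rel_diff(correction_factor, mean_cbfa / mean_cbjf) > 1e-6) {
    stop_pcmri("stored correction factor is inconsistent with ",
               "mean_cbfa / mean_cbjf", class = "validation_error")
  }
  if (correction_factor < 1) {
    warning("venous correction factor below 1: jugular outflow exceeds ",
            "arterial inflow, check segmentation", call. = FALSE)
  }
  structure(c(req, list(sv_syrinx = sv_syrinx,
                        has_syrinx = !is.null(sv_syrinx),
                        exam_stage = exam_stage)),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> stage %s%s\n", x$exam_stage,
              if (x$has_syrinx) ", syrinx" else ""))
  flds <- c("sv_aqueduct", "sv_foramen", "sv_tonsils", "sv_cervical",
            "sv_vascular", "sv_syrinx", "amp_venous", "correction_factor")
  for (f in flds) {
    if (!is.null(x[[f]])) cat(sprintf("  %-18s %.4g\n", f, x[[f]]))
  }
  invisible(x)
}

#' @export
as.data.frame.subject_profile <- function(x, ...) {
  data.frame(exam_stage = x$exam_stage, sv_aqueduct = x$sv_aqueduct,
             sv_foramen = x$sv_foramen, sv_tonsils = x$sv_tonsils,
             sv_cervical = x$sv_cervical, sv_vascular = x$sv_vascular,
             sv_syrinx = if (x$has_syrinx) x$sv_syrinx else NA_real_,
             amp_venous = x$amp_venous,
             correction_factor = x$correction_factor,
             mean_cbfa = x$mean_cbfa, mean_cbjf = x$mean_cbjf,
             has_syrinx = x$has_syrinx)
}

#' Assemble a subject profile from an exam's curves
#'
#' Takes the per-plane flow curves of one exam and derives the full
#' hemodynamic/hydrodynamic parameter set: stroke volumes of the CSF and
#' tissue curves, the CBFa/CBJF sums' means, the venous correction factor,
#' the corrected venous and arteriovenous curves and the arteriovenous
#' stroke volume, and the venous flow amplitude.
#'
#' @param aqueduct,foramen,cervical CSF [flow_curve()]s.
#' @param tonsils tissue-motion [flow_curve()].
#' @param cbfa,cbjf the summed arterial and jugular curves (see
#'   [arterial_flow()], [jugular_flow()]).
#' @param syrinx syrinx CSF [flow_curve()] or `NULL`.
#' @param exam_stage `"pre"` or `"post"`.
#' @param amp_on compute the venous amplitude on the raw `"cbjf"` curve
#'   (default) or on the `"corrected"` venous curve.
#' @return a [subject_profile()].
#' @export
build_profile <- function(aqueduct, foramen, tonsils, cervical, cbfa, cbjf,
                          syrinx = NULL, exam_stage = c("pre", "post"),
                          amp_on = c("cbjf", "corrected")) {
  exam_stage <- match.arg(exam_stage)
  amp_on <- match.arg(amp_on)
  for (cv in list(aqueduct, foramen, tonsils, cervical, cbfa, cbjf)) {
    if (!inherits(cv, "flow_curve")) {
      stop_pcmri("all required curves must be flow_curve objects",
                 class = "incomplete_exam")
    }
  }
  factor <- venous_correction_factor(cbfa, cbjf)
  corrected <- corrected_venous_curve(cbjf, factor)
  av <- arteriovenous_curve(cbfa, corrected)
  amp_curve <- if (amp_on == "cbjf") cbjf else corrected
  subject_profile(
    sv_aqueduct = stroke_volume(aqueduct)$sv,
    sv_foramen = stroke_volume(foramen)$sv,
    sv_tonsils = stroke_volume(tonsils)$sv,
    sv_cervical = stroke_volume(cervical)$sv,
    sv_vascular = vascular_stroke_volume(av),
    amp_venous = peak_amplitude(amp_curve),
    correction_factor = factor,
    mean_cbfa = cycle_mean(cbfa), mean_cbjf = cycle_mean(cbjf),
    sv_syrinx = if (!is.null(syrinx)) stroke_volume(syrinx)$sv else NULL,
    exam_stage = exam_stage)
}

#' Write a subject profile as JSON
#'
#' @param profile a [subject_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "subject_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
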