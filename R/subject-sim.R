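# End-to-end synthetic subject: one exam = one rendered scene per
# acquisition plane, quantified back through segmentation, flow
# quantification and the hemodynamic model.

#' Default single-exam simulation parameters
#'
#' Target values used by [simulate_subject_exam()] when none are supplied:
#' the preoperative cohort means of [chiari_cohort_defaults()] plus a total
#' mean arterial inflow of 9000 mm^3/s (about 540 mL/min, a mid-range adult
#' total cerebral blood flow; the mean jugular outflow follows from the
#' correction factor).
#'
#' @return a named list of targets.
#' @export
default_exam_params <- function() {
  d <- chiari_cohort_defaults()
  p <- as.list(stats::setNames(d$pre_mean, d$parameter))
  p$mean_cbfa <- 9000
  p
}

# Per-plane geometry of the synthetic exam. Static reference rectangles sit
# in a corner of every slice for eddy-current baseline correction.
exam_geometry <- function() {
  list(
    aqueduct = list(grid = c(24L, 24L), venc = 10,
                    rois = list(csf = list(center = c(12, 14), radius = 2))),
    foramen  = list(grid = c(36L, 36L), venc = 5,
                    rois = list(csf = list(center = c(13, 18), radius = 4),
                                tissue = list(center = c(26, 18), radius = 4))),
    cervical = list(grid = c(28L, 28L), venc = 5,
                    rois = list(csf = list(center = c(14, 15), radius = 5))),
    syrinx   = list(grid = c(24L, 24L), venc = 5,
                    rois = list(csf = list(center = c(12, 12), radius = 3))),
    vessels  = list(grid = c(64L, 64L), venc = 80,
                    rois = list(carotid_left = list(center = c(18, 16), radius = 3),
                                carotid_right = list(center = c(18, 48), radius = 3),
                                vertebral_left = list(center = c(30, 24), radius = 2),
                                vertebral_right = list(center = c(30, 40), radius = 2),
                                jugular_left = list(center = c(46, 16), radius = 3),
                                jugular_right = list(center = c(46, 48), radius = 3))))
}

#' Simulate a complete synthetic phase-contrast exam
#'
#' Renders one velocity cine series per acquisition plane (aqueduct,
#' foramen magnum CSF + tonsils, cervical CSF, optional syrinx, cervical
#' vessels) with the study's encoding limits (VENC 10 cm/s at the aqueduct,
#' 5 cm/s for CSF and tissue, 80 cm/s for the neck vessels) and known
#' ground truth. CSF and tissue ROIs carry zero-mean oscillatory waveforms
#' calibrated so their grid stroke volumes hit the requested targets
#' exactly; the neck arteries carry pulsatile inflow waveforms (stored
#' negative, cranio-caudal-positive convention) summing to `mean_cbfa`, and
#' the jugulars carry damped outflow waveforms whose summed mean is
#' `mean_cbfa / correction_factor` and whose summed peak-to-peak amplitude
#' is `amp_venous`. Per-phase eddy-current offsets (a fixed sinusoidal
#' pattern scaled to 2% of each plane's VENC) and Gaussian velocity noise
#' (`noise_frac` of each plane's peak true velocity) are added before
#' aliasing wrap.
#'
#' @param params named list of targets (see [default_exam_params()]);
#'   `sv_syrinx = NULL` or `has_syrinx = FALSE` drops the syrinx plane.
#' @param has_syrinx logical; acquire the syrinx plane?
#' @param noise_frac Gaussian velocity noise SD as a fraction of each
#'   plane's peak true velocity (0 = noise-free).
#' @param offsets logical; add the per-phase eddy-current offsets?
#' @param n_phases cardiac phases per cycle.
#' @param cardiac_period cycle duration, s.
#' @param seed RNG seed for the noise, or `NULL`.
#' @return a list of class `pcmri_exam`: per-plane `series`, `truth`, the
#'   seed pixels and static-region masks used downstream, plus the target
#'   `params`.
#' @export
simulate_subject_exam <- function(params = default_exam_params(),
                                  has_syrinx = TRUE, noise_frac = 0,
                                  offsets = TRUE, n_phases = 32L,
                                  cardiac_period = 1, seed = NULL) {
  geo <- exam_geometry()
  if (!has_syrinx || is.null(params$sv_syrinx) ||
      !is.finite(params$sv_syrinx %||% NA_real_)) {
    geo$syrinx <- NULL
  }
  Tt <- cardiac_period

  waves <- list(
    aqueduct = list(csf = csf_waveform(params$sv_aqueduct, Tt,
                                       n_phases = n_phases)),
    foramen = list(csf = csf_waveform(params$sv_foramen, Tt,
                                      n_phases = n_phases),
                   tissue = tissue_waveform(params$sv_tonsils, Tt,
                                            n_phases = n_phases)),
    cervical = list(csf = csf_waveform(params$sv_cervical, Tt,
                                       systolic_fraction = 0.32,
                                       n_phases = n_phases)))
  if ("syrinx" %in% names(geo)) {
    waves$syrinx <- list(csf = csf_waveform(params$sv_syrinx, Tt,
                                            systolic_fraction = 0.35,
                                            n_phases = n_phases))
  }
  mean_cbjf <- params$mean_cbfa / params$correction_factor
  # calibrate the oscillatory part on the reconstruction grid so the summed
  # jugular peak-to-peak equals the amp_venous target exactly
  grid_p2p <- function(spec, target) {
    q <- make_waveform(spec, n_phases)$flow
    spec$harmonics[, 1] <- spec$harmonics[, 1] * target / (max(q) - min(q))
    spec
  }
  waves$vessels <- list(
    carotid_left = arterial_waveform(0.36 * params$mean_cbfa, cycle_period = Tt),
    carotid_right = arterial_waveform(0.35 * params$mean_cbfa, cycle_period = Tt,
                                      systolic_fraction = 0.26),
    vertebral_left = arterial_waveform(0.15 * params$mean_cbfa, cycle_period = Tt),
    vertebral_right = arterial_waveform(0.14 * params$mean_cbfa, cycle_period = Tt),
    jugular_left = grid_p2p(venous_waveform(mean_cbjf / 2,
                                            pulse_p2p = params$amp_venous / 2,
                                            cycle_period = Tt),
                            params$amp_venous / 2),
    jugular_right = grid_p2p(venous_waveform(mean_cbjf / 2,
                                             pulse_p2p = params$amp_venous / 2,
                                             cycle_period = Tt),
                             params$amp_venous / 2))

  categories <- function(plane, roi) {
    if (plane == "vessels") {
      if (grepl("jugular", roi)) "venous" else "arterial"
    } else if (roi == "tissue") "tissue" else "csf"
  }
  planes <- list()
  plane_seed <- if (is.null(seed)) NULL else seed
  for (plane in names(geo)) {
    g <- geo[[plane]]
    rois <- list()
    seeds <- list()
    for (roi in names(g$rois)) {
      cat_ <- categories(plane, roi)
      dir_ <- if (cat_ == "arterial") "caudocranial" else "craniocaudal"
      rois[[roi]] <- scene_roi(roi, cat_,
                               shape_disc(g$rois[[roi]]$center,
                                          g$rois[[roi]]$radius),
                               waves[[plane]][[roi]], flow_dir = dir_)
      seeds[[roi]] <- g$rois[[roi]]$center
    }
    # full-width static band: a large reference keeps the per-phase offset
    # estimate's noise well below the ROI velocities
    static_shape <- shape_rect(1:4, 1:g$grid[2])
    rois$static <- scene_roi("static", "static", static_shape)
    off <- if (offsets) {
      0.02 * g$venc * sin(2 * pi * seq_len(n_phases) / n_phases + 0.8)
    } else 0
    # peak true velocity on this plane, for the noise scale
    sc0 <- scene_spec(g$grid, c(1, 1), rois, venc = g$venc,
                      n_phases = n_phases, cardiac_period = Tt,
                      noise_sd = 0, offset_per_phase = off,
                      plane_label = plane, seed = NULL)
    peak_v <- max(vapply(render_velocity_series(sc0)$truth$rois,
                         `[[`, 0, "peak_velocity_cm_s"))
    sc <- scene_spec(g$grid, c(1, 1), rois, venc = g$venc,
                     n_phases = n_phases, cardiac_period = Tt,
                     noise_sd = noise_frac * peak_v, offset_per_phase = off,
                     plane_label = plane,
                     seed = if (is.null(plane_seed)) NULL else plane_seed)
    if (!is.null(plane_seed)) plane_seed <- plane_seed + 1L
    rendered <- render_velocity_series(sc)
    planes[[plane]] <- list(series = rendered$series, truth = rendered$truth,
                            seeds = seeds,
                            static_pixels = shape_pixels(static_shape, g$grid))
  }
  structure(list(planes = planes, params = params,
                 has_syrinx = !is.null(geo$syrinx)),
            class = "pcmri_exam")
}

exam_preprocess <- function(plane, baseline = TRUE) {
  s <- unwrap_temporal(plane$series)
  if (baseline) {
    s <- baseline_correct(s, roi_mask(plane$static_pixels, "static", "static"))
  }
  s
}

#' Quantify a synthetic exam back into a subject profile
#'
#' Runs the full measurement pipeline on a [simulate_subject_exam()] exam:
#' temporal unwrapping, static-region baseline correction, seed-grown
#' segmentation of every structure, flow-curve and stroke-volume
#' quantification, and assembly of the hemodynamic model
#' ([build_profile()]). Segmentation seeds are the known ROI centres, which
#' is what "semi-automatic" means here: the operator clicks once inside
#' each structure.
#'
#' @param exam a `pcmri_exam`.
#' @param exam_stage `"pre"` or `"post"`.
#' @param r_min correlation threshold for region growing.
#' @param amp_frac amplitude fraction for vessel/CSF ROIs.
#' @param amp_frac_tissue amplitude fraction for the tonsil tissue ROI.
#' @param baseline apply [baseline_correct()] (recommended whenever the
#'   acquisition carries eddy-current offsets).
#' @return a [subject_profile()].
#' @export
quantify_exam <- function(exam, exam_stage = c("pre", "post"), r_min = 0.7,
                          amp_frac = 0.1, amp_frac_tissue = 0.02,
                          baseline = TRUE) {
  stopifnot(inherits(exam, "pcmri_exam"))
  exam_stage <- match.arg(exam_stage)
  curve_of <- function(plane, roi, category, direction, tissue = FALSE) {
    s <- exam_preprocess(exam$planes[[plane]], baseline)
    seg <- if (tissue) {
      segment_tonsils(s, exam$planes[[plane]]$seeds[[roi]], r_min = r_min,
                      amp_frac = amp_frac_tissue)
    } else {
      segment_from_seed(s, exam$planes[[plane]]$seeds[[roi]],
                        category = category, r_min = r_min,
                        amp_frac = amp_frac)
    }
    compute_flow_curve(s, seg, direction = direction)
  }
  aqueduct <- curve_of("aqueduct", "csf", "csf", "craniocaudal")
  foramen <- curve_of("foramen", "csf", "csf", "craniocaudal")
  tonsils <- curve_of("foramen", "tissue", "tissue", "craniocaudal",
                      tissue = TRUE)
  cervical <- curve_of("cervical", "csf", "csf", "craniocaudal")
  syrinx <- if (exam$has_syrinx) {
    curve_of("syrinx", "csf", "csf", "craniocaudal")
  } else NULL
  vs <- exam_preprocess(exam$planes$vessels, baseline)
  vessel_curve <- function(roi, category, direction) {
    seg <- segment_from_seed(vs, exam$planes$vessels$seeds[[roi]],
                             category = category, r_min = r_min,
                             amp_frac = amp_frac)
    compute_flow_curve(vs, seg, direction = direction)
  }
  cbfa <- arterial_flow(vessel_curve("carotid_left", "arterial", "caudocranial"),
                        vessel_curve("carotid_right", "arterial", "caudocranial"),
                        vessel_curve("vertebral_left", "arterial", "caudocranial"),
                        vessel_curve("vertebral_right", "arterial", "caudocranial"))
  cbjf <- jugular_flow(vessel_curve("jugular_left", "venous", "craniocaudal"),
                       vessel_curve("jugular_right", "venous", "craniocaudal"))
  build_profile(aqueduct, foramen, tonsils, cervical, cbfa, cbjf,
                syrinx = syrinx, exam_stage = exam_stage)
}

#' Ground-truth subject profile of a synthetic exam
#'
#' Assembles the same parameter set as [quantify_exam()] directly from the
#' generator's stored truth, bypassing rendering, segmentation and
#' measurement. Used as the reference in end-to-end recovery checks.
#'
#' @param exam a `pcmri_exam`.
#' @param exam_stage `"pre"` or `"post"`.
#' @return a [subject_profile()].
#' @export
ground_truth_profile <- function(exam, exam_stage = c("pre", "post")) {
  stopifnot(inherits(exam, "pcmri_exam"))
  exam_stage <- match.arg(exam_stage)
  tc <- function(plane, roi) {
    r <- exam$planes[[plane]]$truth$rois[[roi]]
    flow_curve(r$flow, exam$planes[[plane]]$truth$cardiac_period,
               label = r$label)
  }
  cbfa <- sum_curves(list(tc("vessels", "carotid_left"),
                          tc("vessels", "carotid_right"),
                          tc("vessels", "vertebral_left"),
                          tc("vessels", "vertebral_right")), "CBFa")
  cbjf <- sum_curves(list(tc("vessels", "jugular_left"),
                          tc("vessels", "jugular_right")), "CBJF")
  build_profile(tc("aqueduct", "csf"), tc("foramen", "csf"),
                tc("foramen", "tissue"), tc("cervical", "csf"),
                cbfa, cbjf,
                syrinx = if (exam$has_syrinx) tc("syrinx", "csf") else NULL,
                exam_stage = exam_stage)
}
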