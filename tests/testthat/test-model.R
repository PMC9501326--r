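sine_curve <- function(mean, amp, n = 32, period = 1, phase = 0) {
  flow_curve(mean + amp * sin(2 * pi * (0:(n - 1)) / n + phase), period)
}

test_that("arterial and jugular sums are pointwise additive", {
  c1 <- sine_curve(2250, 900)
  cbfa <- arterial_flow(c1, c1, c1, c1)
  expect_equal(cycle_mean(cbfa), 9000, tolerance = 1e-9)
  expect_equal(cbfa$flow, 4 * c1$flow)

  z <- flow_curve(rep(0, 32), 1)
  expect_equal(arterial_flow(c1, c1, c1, z)$flow, 3 * c1$flow)

  cbjf <- jugular_flow(sine_curve(3000, 500), sine_curve(3200, 400, phase = 1))
  expect_equal(cycle_mean(cbjf), 6200, tolerance = 1e-9)

  expect_error(arterial_flow(c1, c1, c1, sine_curve(100, 10, n = 16)),
               class = "alignment_error")
  expect_error(jugular_flow(c1, flow_curve(c1$flow, 0.8)),
               class = "alignment_error")
})

test_that("venous correction factor and corrected curve satisfy their identities", {
  cbfa <- sine_curve(9000, 3000)
  cbjf <- sine_curve(6000, 1000, phase = 0.5)
  expect_equal(venous_correction_factor(cbfa, cbjf), 1.5)

  # factor 1: exclusively jugular drainage, corrected curve is CBJF itself
  cbjf_eq <- sine_curve(9000, 1000, phase = 0.5)
  f <- venous_correction_factor(cbfa, cbjf_eq)
  expect_equal(f, 1)
  expect_equal(corrected_venous_curve(cbjf_eq, f)$flow, cbjf_eq$flow)

  # factor 2 doubles every sample
  expect_equal(corrected_venous_curve(cbjf, 2)$flow, 2 * cbjf$flow)

  # corrected mean equals the arterial mean by construction
  f2 <- venous_correction_factor(cbfa, cbjf)
  expect_lt(rel_diff_num(cycle_mean(corrected_venous_curve(cbjf, f2)),
                         cycle_mean(cbfa)), 1e-9)

  expect_error(venous_correction_factor(cbfa, sine_curve(-100, 10)),
               class = "degenerate_drainage")
})

test_that("the arteriovenous curve balances to zero mean", {
  cbfa <- sine_curve(9000, 3000)
  corrected <- corrected_venous_curve(sine_curve(6000, 1500, phase = 1),
                                      venous_correction_factor(
                                        cbfa, sine_curve(6000, 1500, phase = 1)))
  av <- arteriovenous_curve(cbfa, corrected)
  expect_lt(abs(cycle_mean(av)) / cycle_mean(cbfa), 1e-9)

  # identical curves cancel exactly
  expect_equal(arteriovenous_curve(cbfa, cbfa)$flow, rep(0, 32))

  # AV curve = 1000 sin: vascular stroke volume matches the closed form
  av_sin <- sine_curve(0, 1000)
  expect_equal(vascular_stroke_volume(av_sin), 1000 / pi, tolerance = 0.01)
  expect_equal(vascular_stroke_volume(flow_curve(rep(0, 32), 1)), 0)
})

test_that("factor = 1 collapses the identity chain to CBFa - CBJF", {
  cbfa <- sine_curve(8000, 2500)
  cbjf <- sine_curve(8000, 900, phase = 0.7)
  f <- venous_correction_factor(cbfa, cbjf)
  expect_equal(f, 1)
  av <- arteriovenous_curve(cbfa, corrected_venous_curve(cbjf, f))
  expect_equal(av$flow, cbfa$flow - cbjf$flow)
})

test_that("blood velocity rescaling leaves the factor invariant and scales amplitudes", {
  set.seed(61)
  for (i in 1:10) {
    cbfa <- flow_curve(make_waveform(random_waveform("arterial", 9000,
                                                     amp_scale = 2000), 32)$flow, 1)
    cbjf <- flow_curve(make_waveform(random_waveform("venous", 6500,
                                                     amp_scale = 800), 32)$flow, 1)
    f <- venous_correction_factor(cbfa, cbjf)
    cc <- stats::runif(1, 0.5, 3)
    cbfa_s <- flow_curve(cc * cbfa$flow, 1)
    cbjf_s <- flow_curve(cc * cbjf$flow, 1)
    expect_equal(venous_correction_factor(cbfa_s, cbjf_s), f,
                 tolerance = 1e-12)
    expect_equal(peak_amplitude(cbjf_s), cc * peak_amplitude(cbjf),
                 tolerance = 1e-12)
    av <- arteriovenous_curve(cbfa, corrected_venous_curve(cbjf, f))
    av_s <- arteriovenous_curve(cbfa_s, corrected_venous_curve(cbjf_s, f))
    expect_equal(vascular_stroke_volume(av_s),
                 cc * vascular_stroke_volume(av), tolerance = 1e-12)
  }
})

test_that("subject profiles validate their stored invariants", {
  cbfa <- sine_curve(9000, 3000)
  cbjf <- sine_curve(6000, 1200, phase = 0.4)
  csf <- sine_curve(0, 800)
  tis <- sine_curve(0, 900, phase = pi / 2)
  p <- build_profile(csf, csf, tis, csf, cbfa, cbjf, exam_stage = "pre")
  expect_s3_class(p, "subject_profile")
  expect_false(p$has_syrinx)
  expect_null(p$sv_syrinx)
  expect_equal(p$correction_factor, p$mean_cbfa / p$mean_cbjf)
  expect_equal(p$correction_factor, 1.5)

  p2 <- build_profile(csf, csf, tis, csf, cbfa, cbjf, syrinx = sine_curve(0, 300),
                      exam_stage = "post")
  expect_true(p2$has_syrinx)
  expect_gt(p2$sv_syrinx, 0)

  # an inconsistent stored factor is rejected
  expect_error(subject_profile(10, 200, 300, 400, 800, 5000,
                               correction_factor = 2,
                               mean_cbfa = 9000, mean_cbjf = 6000),
               class = "validation_error")
  expect_error(build_profile(csf, NULL, tis, csf, cbfa, cbjf),
               class = "incomplete_exam")
  # factor below 1 is flagged, not rejected
  expect_warning(subject_profile(10, 200, 300, 400, 800, 5000,
                                 correction_factor = 0.9,
                                 mean_cbfa = 5400, mean_cbjf = 6000),
                 "below 1")

  # amplitude can be computed on the corrected venous curve instead
  pc <- build_profile(csf, csf, tis, csf, cbfa, cbjf, amp_on = "corrected")
  expect_equal(pc$amp_venous, 1.5 * p$amp_venous, tolerance = 1e-9)
})

test_that("quantified synthetic exams match their ground truth", {
  ex <- simulate_subject_exam(noise_frac = 0, seed = 5)
  meas <- quantify_exam(ex)
  truth <- ground_truth_profile(ex)
  for (f in c("sv_aqueduct", "sv_foramen", "sv_tonsils", "sv_cervical",
              "sv_vascular", "sv_syrinx", "amp_venous", "correction_factor",
              "mean_cbfa", "mean_cbjf")) {
    expect_lt(rel_diff_num(meas[[f]], truth[[f]]), 1e-9)
  }
  expect_equal(truth$sv_foramen, 201)
  expect_equal(truth$amp_venous, 5578)
  expect_equal(truth$correction_factor, 1.38, tolerance = 1e-12)

  # a subject without syringomyelia has no syrinx series
  ex0 <- simulate_subject_exam(has_syrinx = FALSE)
  p0 <- quantify_exam(ex0)
  expect_false(p0$has_syrinx)
})
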