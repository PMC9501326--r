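test_that("noise-free rendering conserves the ROI flow curve", {
  set.seed(21)
  for (i in 1:10) {
    spec <- random_waveform("csf", amp_scale = 500)
    sc <- simple_scene(spec, venc = Inf)
    out <- render_velocity_series(sc)
    truth <- out$truth$rois$roi
    mask <- roi_mask(truth$pixels, "roi", "csf")
    q <- compute_flow_curve(out$series, mask)
    expect_lt(max(abs(q$flow - truth$flow)) / max(abs(truth$flow)), 1e-9)
  }
})

test_that("velocities beyond VENC wrap into the half-open encoding interval", {
  # 6 cm/s at VENC 5: ((6+5) mod 10) - 5 = -4
  expect_equal(wrap_velocity(6, 5), -4)
  expect_equal(wrap_velocity(-6, 5), 4)
  expect_equal(wrap_velocity(5, 5), -5)   # half-open: +venc maps to -venc
  expect_equal(wrap_velocity(4.9, 5), 4.9)
  expect_equal(wrap_velocity(16, 5), -4)  # double wrap

  # rendering with VENC = Inf then wrapping equals rendering with finite VENC
  set.seed(22)
  spec <- random_waveform("csf", amp_scale = 3000)  # will exceed VENC 5
  sc_inf <- simple_scene(spec, venc = Inf, noise_sd = 0.3, seed = 5)
  sc_fin <- simple_scene(spec, venc = 5, noise_sd = 0.3, seed = 5)
  v_inf <- render_velocity_series(sc_inf)$series$v
  v_fin <- render_velocity_series(sc_fin)$series$v
  expect_equal(wrap_velocity(v_inf, 5), v_fin, tolerance = 1e-12)
})

test_that("rendering is reproducible under a fixed seed", {
  spec <- csf_waveform(200)
  sc <- simple_scene(spec, noise_sd = 0.5, seed = 99)
  a <- render_velocity_series(sc)$series$v
  b <- render_velocity_series(sc)$series$v
  expect_identical(a, b)
  sc2 <- simple_scene(spec, noise_sd = 0.5, seed = 100)
  expect_false(identical(a, render_velocity_series(sc2)$series$v))
})

test_that("an ROI beyond twice VENC is flagged as unwrap-unsafe", {
  # uniform 11 cm/s at VENC 5: excursion exceeds the unwrapping guarantee
  spec <- waveform_spec("arterial", 1, 11 * 10 * 29)  # 29-px disc, 1 mm^2
  sc <- simple_scene(spec, venc = 5, radius = 3, category = "arterial")
  out <- render_velocity_series(sc)
  expect_true(out$truth$rois$roi$wrap_warning)
  sc_ok <- simple_scene(csf_waveform(100), venc = 5)
  expect_false(render_velocity_series(sc_ok)$truth$rois$roi$wrap_warning)
})

test_that("scene specs validate geometry and ROI disjointness", {
  w <- csf_waveform(100)
  overlapping <- list(
    a = scene_roi("a", "csf", shape_disc(c(10, 10), 3), w),
    b = scene_roi("b", "csf", shape_disc(c(11, 10), 3), w))
  expect_error(scene_spec(c(20, 20), c(1, 1), overlapping, venc = 5),
               class = "invalid_spec")
  outside <- list(a = scene_roi("a", "csf", shape_disc(c(1, 1), 3), w))
  expect_error(scene_spec(c(20, 20), c(1, 1), outside, venc = 5),
               class = "invalid_spec")
  expect_error(simple_scene(w, n_phases = 4), class = "invalid_spec")
})

test_that("written scenes round-trip through the readers", {
  spec <- csf_waveform(150)
  sc <- simple_scene(spec, venc = 5, noise_sd = 0.1,
                     offsets = rep(0.05, 32), seed = 3)
  out <- render_velocity_series(sc)
  dir <- withr::local_tempdir()
  paths <- write_scene(out$series, out$truth, dir, prefix = "fixture")
  back <- read_series(file.path(dir, "fixture.nii.gz"))
  expect_equal(back$v, out$series$v, tolerance = 1e-6)
  expect_identical(back$venc, out$series$venc)
  expect_identical(back$cardiac_period, out$series$cardiac_period)
  expect_identical(back$pixel_spacing, out$series$pixel_spacing)
  expect_identical(back$plane_label, "test")

  tr <- read_ground_truth(file.path(dir, "fixture_truth.json"))
  expect_identical(names(tr$rois), names(out$truth$rois))
  expect_equal(tr$rois$roi$flow, out$truth$rois$roi$flow)
  expect_equal(tr$rois$roi$sv$sv, out$truth$rois$roi$sv$sv)
  expect_equal(tr$offsets, out$truth$offsets)
  # sidecar venc equals scene venc
  meta <- jsonlite::read_json(file.path(dir, "fixture.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$venc_cm_s, 5)
})

test_that("cohort sampler reproduces its specification", {
  # degenerate SDs: every subject equals the means exactly
  p <- chiari_cohort_defaults()
  p$pre_sd[] <- 0
  p$post_sd[] <- 0
  ch <- sample_cohort(cohort_spec(10, params = p, seed = 1))
  expect_equal(unique(ch$pre_sv_tonsils), 323)
  expect_equal(unique(ch$post_sv_tonsils), 194)
  expect_equal(mean(ch$pre_sv_foramen) - mean(ch$post_sv_foramen), 201 - 363)

  # near-perfect correlation with equal means: near-zero paired differences
  p2 <- chiari_cohort_defaults()
  p2$post_mean <- p2$pre_mean
  p2$post_sd <- p2$pre_sd
  ch2 <- sample_cohort(cohort_spec(200, params = p2, rho = 0.99, seed = 2))
  d <- ch2$post_sv_cervical - ch2$pre_sv_cervical
  expect_lt(stats::sd(d), 0.2 * stats::sd(ch2$pre_sv_cervical))

  # determinism and truncation
  s <- cohort_spec(50, seed = 7)
  a <- sample_cohort(s)
  expect_identical(a, sample_cohort(s))
  num <- a[grep("^(pre|post)_", names(a))]
  expect_true(all(num >= 0, na.rm = TRUE))
  expect_true(all(a$pre_correction_factor >= 1))
  expect_true(all(a$post_correction_factor >= 1))
  expect_true(all(is.na(a$pre_sv_syrinx[!a$has_syrinx])))
  expect_true(all(is.finite(a$pre_sv_syrinx[a$has_syrinx])))

  expect_error(cohort_spec(1), class = "invalid_spec")
  expect_error(cohort_spec(10, rho = 1), class = "invalid_spec")
})
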