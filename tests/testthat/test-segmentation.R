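# Two adjacent discs with distinct waveforms on a quiet background.
two_roi_scene <- function(w_left, w_right, cat_left = "csf",
                          cat_right = "arterial", noise_sd = 0, seed = NULL,
                          venc = 80) {
  rois <- list(
    left = scene_roi("left", cat_left, shape_disc(c(10, 7), 3), w_left),
    right = scene_roi("right", cat_right, shape_disc(c(10, 14), 3), w_right))
  scene_spec(c(20L, 20L), c(1, 1), rois, venc = venc, noise_sd = noise_sd,
             seed = seed)
}

test_that("noise-free region growing recovers the true ROI exactly", {
  set.seed(41)
  for (i in 1:8) {
    radius <- sample(2:5, 1)
    sc <- simple_scene(random_waveform("csf", amp_scale = 400), venc = Inf,
                       radius = radius)
    out <- render_velocity_series(sc)
    mask <- segment_from_seed(out$series, c(10, 10), "csf")
    expect_equal(mask_jaccard(mask, out$truth$rois$roi$pixels), 1)
  }
})

test_that("a seed on flat background is rejected", {
  sc <- simple_scene(csf_waveform(100), venc = 5)
  out <- render_velocity_series(sc)
  expect_error(segment_from_seed(out$series, c(2, 2), "csf"),
               class = "invalid_seed")
  expect_error(segment_from_seed(out$series, c(50, 50), "csf"),
               class = "invalid_seed")
})

test_that("anticorrelated adjacent structures are not merged", {
  # CSF flush vs arterial pulse in opposite phase: the grown region stops
  # at the boundary because the temporal correlation is strongly negative
  w_csf <- waveform_spec("csf", 1, 0, cbind(2000, 0))
  w_art <- waveform_spec("arterial", 1, 2000, cbind(2000, pi))
  r <- stats::cor(make_waveform(w_csf, 32)$flow, make_waveform(w_art, 32)$flow)
  expect_lt(r, -0.99)
  sc <- two_roi_scene(w_csf, w_art)
  out <- render_velocity_series(sc)
  m_left <- segment_from_seed(out$series, c(10, 7), "csf", r_min = 0.7)
  expect_equal(mask_jaccard(m_left, out$truth$rois$left$pixels), 1)
  m_right <- segment_from_seed(out$series, c(10, 14), "arterial", r_min = 0.7)
  expect_equal(mask_jaccard(m_right, out$truth$rois$right$pixels), 1)
})

test_that("tonsil segmentation separates weak tissue motion from strong CSF", {
  # 0.5 cm/s tissue oscillation adjacent to ~5 cm/s CSF: the amplitude
  # floor alone would admit the CSF; the quarter-cycle phase offset of the
  # tissue waveform keeps the correlation below threshold
  n <- 32L
  w_tis <- tissue_waveform(0.5 * 10 * 29, n_phases = n)   # ~0.5 cm/s, 29 px
  w_csf <- csf_waveform(5 * 10 * 29, n_phases = n)
  sc <- two_roi_scene(w_tis, w_csf, cat_left = "tissue", cat_right = "csf",
                      venc = 80)
  out <- render_velocity_series(sc)
  m <- segment_tonsils(out$series, c(10, 7))
  expect_equal(mask_jaccard(m, out$truth$rois$left$pixels), 1)

  # noise-free tissue disc alone is recovered exactly
  sc1 <- simple_scene(w_tis, venc = 5, category = "tissue")
  out1 <- render_velocity_series(sc1)
  m1 <- segment_tonsils(out1$series, c(10, 10))
  expect_equal(mask_jaccard(m1, out1$truth$rois$roi$pixels), 1)
})

test_that("with thresholds released the region floods all nonflat pixels", {
  w <- csf_waveform(100)
  sc <- two_roi_scene(w, csf_waveform(300), cat_right = "csf", venc = 5)
  out <- render_velocity_series(sc)
  # amp_frac 0, r_min -1: everything pulsatile and 4-connected to the seed
  # joins; the flat background never does (zero-variance profiles)
  m <- segment_from_seed(out$series, c(10, 7), "csf", r_min = -1, amp_frac = 0)
  both <- rbind(out$truth$rois$left$pixels, out$truth$rois$right$pixels)
  expect_equal(mask_jaccard(m, both), 1)
})

test_that("segmentation is deterministic and monotone in the correlation threshold", {
  sc <- simple_scene(csf_waveform(300), venc = 5, noise_sd = 0.05, seed = 12)
  out <- render_velocity_series(sc)
  a <- segment_from_seed(out$series, c(10, 10), "csf")
  b <- segment_from_seed(out$series, c(10, 10), "csf")
  expect_identical(a$pixels, b$pixels)

  sizes <- vapply(c(-1, 0, 0.5, 0.7, 0.9, 0.99), function(r) {
    nrow(segment_from_seed(out$series, c(10, 10), "csf", r_min = r)$pixels)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("noisy recovery keeps Jaccard at or above 0.9", {
  set.seed(43)
  for (i in 1:8) {
    spec <- csf_waveform(stats::runif(1, 150, 400))
    sc0 <- simple_scene(spec, venc = 5)
    peak <- render_velocity_series(sc0)$truth$rois$roi$peak_velocity_cm_s
    sc <- simple_scene(spec, venc = 5, noise_sd = 0.1 * peak, seed = 1000 + i)
    out <- render_velocity_series(sc)
    u <- unwrap_temporal(out$series)   # segmentation expects unaliased data
    m <- segment_from_seed(u, c(10, 10), "csf")
    expect_gte(mask_jaccard(m, out$truth$rois$roi$pixels), 0.9)
  }
})

test_that("manual masks round-trip and are shape-checked", {
  sc <- simple_scene(csf_waveform(100), venc = 5)
  out <- render_velocity_series(sc)
  dir <- withr::local_tempdir()
  truth_mask <- roi_mask(out$truth$rois$roi$pixels, "roi", "csf")
  p <- file.path(dir, "mask.nii.gz")
  write_mask(truth_mask, c(20, 20), p)
  back <- load_manual_mask(p, out$series, label = "roi", category = "csf")
  expect_identical(back$source, "manual")
  expect_equal(mask_jaccard(back, truth_mask), 1)

  empty <- roi_mask(matrix(integer(0), ncol = 2), "e", "csf")
  pe <- file.path(dir, "empty.nii.gz")
  write_mask(empty, c(20, 20), pe)
  expect_error(load_manual_mask(pe, out$series), class = "invalid_mask")

  pw <- file.path(dir, "wrong.nii.gz")
  write_mask(truth_mask, c(64, 64), pw)
  expect_error(load_manual_mask(pw, out$series), class = "format_error")
  expect_error(write_mask(truth_mask, c(5, 5), file.path(dir, "oob.nii.gz")),
               class = "format_error")
})
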