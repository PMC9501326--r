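# Independent oracles and fixture builders used across the suite.

# Stroke volume by direct rectangular quadrature of a sampled flow vector,
# written independently of the package implementation.
oracle_stroke_volume <- function(q, period) {
  dt <- period / length(q)
  fwd <- sum(q[q > 0]) * dt
  bwd <- -sum(q[q < 0]) * dt
  (fwd + bwd) / 2
}

# Exact two-sided Wilcoxon signed-rank p-value by exhaustive enumeration of
# all 2^n sign assignments of the ranked absolute differences. Requires no
# ties and no zeros; independent of stats::wilcox.test.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 15, !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

rel_diff_num <- function(x, ref) abs(x - ref) / max(abs(ref), .Machine$double.eps)

# Random Fourier waveform spec (seed the caller's RNG first).
random_waveform <- function(kind = "arterial", mean_flow = 0, n_harm = 4,
                            amp_scale = 1, period = 1) {
  H <- cbind(amplitude = amp_scale * stats::runif(n_harm, 0.2, 1),
             phase = stats::runif(n_harm, 0, 2 * pi))
  waveform_spec(kind, cycle_period = period, mean_flow = mean_flow,
                harmonics = H)
}

# Minimal one-ROI scene: a disc with a given waveform on a quiet background.
simple_scene <- function(waveform, venc = 5, grid = c(20L, 20L),
                         center = c(10, 10), radius = 3, noise_sd = 0,
                         offsets = NULL, seed = NULL, category = "csf",
                         flow_dir = "craniocaudal", n_phases = 32L,
                         extra_rois = list()) {
  rois <- c(list(roi = scene_roi("roi", category, shape_disc(center, radius),
                                 waveform, flow_dir = flow_dir)),
            extra_rois)
  scene_spec(grid, c(1, 1), rois, venc = venc, n_phases = n_phases,
             noise_sd = noise_sd, offset_per_phase = offsets,
             plane_label = "test", seed = seed)
}
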