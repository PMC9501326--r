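#' Pulsatile flow waveform specification
#'
#' A truncated Fourier series description of a periodic volumetric flow
#' waveform, the parametric family used by the synthetic phantom generator.
#' The waveform is
#' \deqn{Q(t) = \bar{Q} + \sum_{j=1}^{m} A_j \sin(2\pi j t / T + \phi_j)}
#' with cycle period \eqn{T} (s), mean flow \eqn{\bar{Q}} (mm^3/s) and up to
#' eight harmonics. Because every harmonic averages to zero over the cycle,
#' mean flow and stroke volume are available in closed form or by exact
#' quadrature on the reconstruction grid.
#'
#' @param kind waveform class: `"arterial"` (strongly pulsatile inflow),
#'   `"venous"` (damped outflow), `"csf"` (oscillatory, near-zero net flow) or
#'   `"tissue"` (small oscillatory tissue velocity).
#' @param cycle_period cardiac period in seconds; must be positive.
#' @param mean_flow cycle-mean flow in mm^3/s.
#' @param harmonics numeric matrix with columns `amplitude` (mm^3/s) and
#'   `phase` (radians); row `j` is the j-th harmonic. May have zero rows.
#' @param systolic_fraction fraction of the cycle at which the systolic peak
#'   is centred, in (0, 1). Stored for reference; the helper constructors use
#'   it to set the harmonic phases.
#'
#' @details A `kind = "csf"` spec must have `|mean_flow|` no larger than 5% of
#'   the waveform's peak-to-peak amplitude: CSF oscillates with almost no net
#'   flow over one cardiac cycle.
#'
#' @return an object of class `waveform_spec`.
#' @seealso [make_waveform()], [arterial_waveform()], [csf_waveform()]
#' @export
waveform_spec <- function(kind = c("arterial", "venous", "csf", "tissue"),
                          cycle_period = 1,
                          mean_flow = 0,
                          harmonics = NULL,
                          systolic_fraction = 0.3) {
  kind <- match.arg(kind)
  assert_scalar_number(cycle_period, "cycle_period")
  if (cycle_period <= 0) {
    stop_pcmri("cycle_period must be positive", class = "invalid_spec")
  }
  assert_scalar_number(mean_flow, "mean_flow")
  assert_scalar_number(systolic_fraction, "systolic_fraction")
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop_pcmri("systolic_fraction must lie in (0, 1)", class = "invalid_spec")
  }
  if (is.null(harmonics)) {
    harmonics <- matrix(numeric(0), ncol = 2)
  }
  harmonics <- as.matrix(harmonics)
  if (length(harmonics) && ncol(harmonics) != 2) {
    stop_pcmri("harmonics must have two columns (amplitude, phase)",
               class = "invalid_spec")
  }
  colnames(harmonics) <- c("amplitude", "phase")
  if (nrow(harmonics) > 8) {
    stop_pcmri("at most 8 harmonics are supported", class = "invalid_spec")
  }
  if (length(harmonics) && any(!is.finite(harmonics))) {
    stop_pcmri("harmonics must be finite", class = "invalid_spec")
  }
  spec <- structure(
    list(kind = kind, cycle_period = cycle_period, mean_flow = mean_flow,
         harmonics = harmonics, systolic_fraction = systolic_fraction),
    class = "waveform_spec")
  if (kind == "csf") {
    p2p <- waveform_peak_to_peak(spec)
    if (abs(mean_flow) > 0.05 * p2p) {
      stop_pcmri("csf waveform must have |mean_flow| <= 5% of its ",
                 "peak-to-peak amplitude", class = "invalid_spec")
    }
  }
  spec
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf("<waveform_spec> %s: T = %.3g s, mean = %.4g mm^3/s, %d harmonic(s)\n",
              x$kind, x$cycle_period, x$mean_flow, nrow(x$harmonics)))
  invisible(x)
}

# Evaluate the Fourier series at arbitrary times (s).
eval_waveform <- function(spec, t) {
  q <- rep(spec$mean_flow, length(t))
  H <- spec$harmonics
  if (nrow(H)) {
    for (j in seq_len(nrow(H))) {
      q <- q + H[j, 1] * sin(2 * pi * j * t / spec$cycle_period + H[j, 2])
    }
  }
  q
}

# Peak-to-peak amplitude of the continuous waveform, by dense sampling.
waveform_peak_to_peak <- function(spec, n_dense = 2048L) {
  t <- seq(0, spec$cycle_period, length.out = n_dense + 1L)[seq_len(n_dense)]
  q <- eval_waveform(spec, t)
  max(q) - min(q)
}

#' Sample a flow waveform on the cine reconstruction grid
#'
#' Evaluates a [waveform_spec()] at the `n_phases` uniformly spaced cardiac
#' phases of a retrospectively gated cine reconstruction,
#' \eqn{t_k = (k-1) T / n}. Because each harmonic sums to zero over a full
#' period of uniform samples, the sampled cycle mean equals `mean_flow` to
#' floating-point precision.
#'
#' @param spec a [waveform_spec()].
#' @param n_phases number of cardiac phases (>= 8); the study convention is 32.
#' @return a [flow_curve()] in mm^3/s with one sample per phase.
#' @export
make_waveform <- function(spec, n_phases = 32L) {
  stopifnot(inherits(spec, "waveform_spec"))
  assert_scalar_number(n_phases, "n_phases")
  n_phases <- as.integer(n_phases)
  if (n_phases < 8L) {
    stop_pcmri("n_phases must be at least 8", class = "invalid_spec")
  }
  if (spec$cycle_period <= 0) {
    stop_pcmri("cycle_period must be positive", class = "invalid_spec")
  }
  m <- nrow(spec$harmonics)
  if (m && any(seq_len(m) %% n_phases == 0)) {
    stop_pcmri("harmonic index equal to a multiple of n_phases aliases to a ",
               "constant; increase n_phases", class = "invalid_spec")
  }
  t <- (seq_len(n_phases) - 1) * spec$cycle_period / n_phases
  flow_curve(eval_waveform(spec, t), cardiac_period = spec$cycle_period,
             label = spec$kind)
}

# -- physiologic waveform builders --------------------------------------------
#
# Harmonic amplitudes of a von Mises-shaped systolic pulse: exp(k cos(theta))
# has Fourier cosine coefficients 2 I_j(k) / I_0(k), giving a smooth positive
# pulse whose sharpness grows with k. The pulse is centred at
# theta0 = 2 pi systolic_fraction.
vonmises_harmonics <- function(kappa, n_harm, systolic_fraction) {
  j <- seq_len(n_harm)
  amp <- 2 * besselI(kappa, j) / besselI(kappa, 0)
  theta0 <- 2 * pi * systolic_fraction
  # A cos(j(theta - theta0)) == A sin(j theta + (pi/2 - j theta0))
  cbind(amplitude = amp, phase = pi / 2 - j * theta0)
}

# Rescale harmonic amplitudes so the continuous peak-to-peak equals `target`.
scale_to_p2p <- function(spec, target) {
  p2p <- waveform_peak_to_peak(spec)
  if (p2p <= 0) stop_pcmri("waveform is flat", class = "invalid_spec")
  spec$harmonics[, 1] <- spec$harmonics[, 1] * target / p2p
  spec
}

#' Physiologic waveform constructors
#'
#' Convenience builders for the four waveform classes rendered by the
#' synthetic phantom. Arterial and venous waveforms are a mean flow plus a
#' von Mises-shaped systolic pulse (sharp for arteries, damped for veins)
#' scaled to a requested peak-to-peak amplitude. CSF and tissue waveforms are
#' zero-mean biphasic oscillations (systolic cranio-caudal flush, diastolic
#' return) whose harmonic amplitudes are scaled so that the stroke volume
#' measured on the `n_phases` reconstruction grid equals `stroke_volume_ul`
#' exactly, which is what makes them usable as ground truth.
#'
#' @param mean_flow cycle-mean flow, mm^3/s.
#' @param pulse_p2p peak-to-peak amplitude of the pulsatile component, mm^3/s.
#' @param cycle_period cardiac period, s.
#' @param systolic_fraction systolic peak timing as a fraction of the cycle.
#' @param n_harm number of Fourier harmonics used (<= 8).
#' @param stroke_volume_ul target stroke volume in microlitres per cardiac
#'   cycle, as measured by [stroke_volume()] on the `n_phases` grid.
#' @param n_phases reconstruction grid on which the stroke-volume calibration
#'   is carried out.
#' @return a [waveform_spec()].
#' @name physiologic_waveforms
NULL

#' @rdname physiologic_waveforms
#' @export
arterial_waveform <- function(mean_flow, pulse_p2p = mean_flow,
                              cycle_period = 1, systolic_fraction = 0.25,
                              n_harm = 6L) {
  spec <- waveform_spec("arterial", cycle_period, mean_flow,
                        vonmises_harmonics(6, n_harm, systolic_fraction),
                        systolic_fraction)
  scale_to_p2p(spec, pulse_p2p)
}

#' @rdname physiologic_waveforms
#' @export
venous_waveform <- function(mean_flow, pulse_p2p = 0.4 * mean_flow,
                            cycle_period = 1, systolic_fraction = 0.35,
                            n_harm = 4L) {
  spec <- waveform_spec("venous", cycle_period, mean_flow,
                        vonmises_harmonics(2, n_harm, systolic_fraction),
                        systolic_fraction)
  scale_to_p2p(spec, pulse_p2p)
}

# Zero-mean biphasic oscillation scaled so the grid stroke volume hits target.
oscillatory_waveform <- function(kind, stroke_volume_ul, cycle_period,
                                 systolic_fraction, n_phases,
                                 second_harmonic = 0.3) {
  theta0 <- 2 * pi * systolic_fraction
  H <- cbind(amplitude = c(1, second_harmonic),
             phase = c(pi / 2 - theta0, pi / 2 - 2 * theta0 + 0.6))
  spec <- waveform_spec(kind, cycle_period, 0, H, systolic_fraction)
  unit <- stroke_volume(make_waveform(spec, n_phases))$sv
  if (unit <= 0) stop_pcmri("degenerate oscillation", class = "invalid_spec")
  spec$harmonics[, 1] <- spec$harmonics[, 1] * stroke_volume_ul / unit
  spec
}

#' @rdname physiologic_waveforms
#' @export
csf_waveform <- function(stroke_volume_ul, cycle_period = 1,
                         systolic_fraction = 0.3, n_phases = 32L) {
  oscillatory_waveform("csf", stroke_volume_ul, cycle_period,
                       systolic_fraction, n_phases)
}

#' @rdname physiologic_waveforms
#' @export
tissue_waveform <- function(stroke_volume_ul, cycle_period = 1,
                            systolic_fraction = 0.55, n_phases = 32L) {
  # quarter-cycle offset from the CSF flush: tonsil descent is not in phase
  # with the subarachnoid CSF oscillation, which is what lets the correlation
  # criterion separate tissue from adjacent CSF.
  oscillatory_waveform("tissue", stroke_volume_ul, cycle_period,
                       systolic_fraction, n_phases, second_harmonic = 0.15)
}
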