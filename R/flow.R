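#' Per-phase volumetric flow curve
#'
#' Container for a volumetric flow waveform sampled at the cardiac phases of
#' one averaged cycle. Units are mm^3/s throughout. The sign convention is
#' explicit: by default positive flow is "physiological forward" for the
#' structure the curve describes (cranio-caudal for CSF and venous outflow,
#' cephalad for arterial inflow after orientation).
#'
#' @param flow numeric vector, one value per cardiac phase (mm^3/s).
#' @param cardiac_period cycle duration in seconds.
#' @param sign_convention free-text note on what positive flow means.
#' @param label optional structure label.
#' @return an object of class `flow_curve`.
#' @export
flow_curve <- function(flow, cardiac_period,
                       sign_convention = "positive = physiological forward",
                       label = "") {
  flow <- as.numeric(flow)
  if (!length(flow) || any(!is.finite(flow))) {
    stop_pcmri("flow must be a nonempty finite numeric vector",
               class = "invalid_curve")
  }
  assert_scalar_number(cardiac_period, "cardiac_period")
  if (cardiac_period <= 0) {
    stop_pcmri("cardiac_period must be positive", class = "invalid_curve")
  }
  structure(list(flow = flow, cardiac_period = cardiac_period,
                 n_phases = length(flow), sign_convention = sign_convention,
                 label = label),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> %s: %d phases over %.3g s, mean %.4g mm^3/s, p2p %.4g mm^3/s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$n_phases, x$cardiac_period, mean(x$flow),
              max(x$flow) - min(x$flow)))
  invisible(x)
}

#' @export
as.data.frame.flow_curve <- function(x, ...) {
  data.frame(phase_index = seq_len(x$n_phases) - 1L,
             time_s = (seq_len(x$n_phases) - 1L) * x$cardiac_period / x$n_phases,
             flow_mm3_s = x$flow)
}

#' Cycle mean of a flow curve
#'
#' @param curve a [flow_curve()].
#' @return mean flow over the cycle, mm^3/s.
#' @export
cycle_mean <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  mean(curve$flow)
}

#' Flow curve of a region of interest
#'
#' Integrates through-plane velocity over an ROI at each cardiac phase:
#' \eqn{Q(t_k) = \sum_{p \in mask} v(p, t_k)\, dx\, dy}, with velocity in
#' cm/s and pixel area in mm^2, so the conversion to mm^3/s multiplies by 10.
#' The acquisition stores velocity with cranio-caudal flow positive;
#' `direction = "caudocranial"` flips the sign so that a structure whose
#' physiological forward flow is cephalad (the neck arteries) still yields a
#' forward-positive curve. The orientation is decided by the plane's anatomy,
#' never by the sign of the measured mean.
#'
#' @param series a [velocity_series()]; should be unwrapped and
#'   baseline-corrected first when aliasing or eddy-current offsets are
#'   present.
#' @param mask a [roi_mask()] on the same grid; must be nonempty.
#' @param direction `"craniocaudal"` (keep the stored sign) or
#'   `"caudocranial"` (flip it).
#' @return a [flow_curve()] in mm^3/s.
#' @export
compute_flow_curve <- function(series, mask,
                               direction = c("craniocaudal", "caudocranial")) {
  stopifnot(inherits(series, "velocity_series"), inherits(mask, "roi_mask"))
  direction <- match.arg(direction)
  px <- mask$pixels
  if (!nrow(px)) stop_pcmri("mask is empty", class = "invalid_mask")
  check_mask_bounds(mask, series)
  area_mm2 <- prod(series$pixel_spacing)
  # velocity cm/s -> mm/s is *10
  v <- pixel_profiles(series, px)            # n_phases x n_pixels
  q <- rowSums(v) * area_mm2 * 10
  sgn <- if (direction == "caudocranial") -1 else 1
  flow_curve(sgn * q, series$cardiac_period,
             sign_convention = paste0("positive = ", direction, " (forward)"),
             label = mask$label)
}

#' Stroke volume of a flow curve
#'
#' The stroke volume is the average of the cranio-caudal and caudo-cranial
#' volumes displaced through the region of interest during one cardiac cycle.
#' With rectangular quadrature over the `n` reconstructed phases
#' (\eqn{\Delta t = T/n}):
#' \deqn{V_f = \sum_k \max(Q_k, 0)\Delta t, \quad
#'       V_b = \sum_k \max(-Q_k, 0)\Delta t, \quad
#'       SV = (V_f + V_b)/2.}
#' Volumes are in mm^3, reported as microlitres per cardiac cycle
#' (1 mm^3 = 1 uL).
#'
#' @param curve a [flow_curve()] with at least 8 phases.
#' @return a list of class `stroke_volume_result` with elements `sv`,
#'   `volume_forward`, `volume_backward` and `net_volume` (all uL/CC).
#' @export
stroke_volume <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  if (curve$n_phases < 8L) {
    stop_pcmri("stroke volume needs at least 8 phases", class = "invalid_curve")
  }
  if (curve$cardiac_period <= 0) {
    stop_pcmri("cardiac period must be positive", class = "invalid_curve")
  }
  dt <- curve$cardiac_period / curve$n_phases
  vf <- sum(pmax(curve$flow, 0)) * dt
  vb <- sum(pmax(-curve$flow, 0)) * dt
  structure(list(sv = (vf + vb) / 2, volume_forward = vf, volume_backward = vb,
                 net_volume = vf - vb),
            class = "stroke_volume_result")
}

#' @export
print.stroke_volume_result <- function(x, ...) {
  cat(sprintf("<stroke_volume> SV %.4g uL/CC (forward %.4g, backward %.4g, net %.4g)\n",
              x$sv, x$volume_forward, x$volume_backward, x$net_volume))
  invisible(x)
}

#' Peak amplitude of a flow curve
#'
#' @param curve a [flow_curve()].
#' @param mode `"peak_to_peak"` (default) returns `max(Q) - min(Q)`;
#'   `"from_mean"` returns the largest absolute deviation from the cycle
#'   mean. Peak-to-peak is the convention that makes the venous amplitude
#'   independent of the curve's mean level.
#' @return amplitude in mm^3/s.
#' @export
peak_amplitude <- function(curve, mode = c("peak_to_peak", "from_mean")) {
  stopifnot(inherits(curve, "flow_curve"))
  mode <- match.arg(mode)
  if (mode == "peak_to_peak") {
    max(curve$flow) - min(curve$flow)
  } else {
    max(abs(curve$flow - mean(curve$flow)))
  }
}

#' Resample a flow curve to a common phase grid
#'
#' Periodic linear interpolation onto `n_phases` uniform phases, used to
#' align curves from acquisitions reconstructed with different phase counts
#' before they are combined.
#'
#' @param curve a [flow_curve()].
#' @param n_phases target number of phases.
#' @return a [flow_curve()] with `n_phases` samples.
#' @export
resample_flow_curve <- function(curve, n_phases = 32L) {
  stopifnot(inherits(curve, "flow_curve"))
  n_phases <- as.integer(n_phases)
  if (n_phases < 8L) stop_pcmri("n_phases must be >= 8", class = "invalid_curve")
  if (n_phases == curve$n_phases) return(curve)
  n0 <- curve$n_phases
  x0 <- (seq_len(n0 + 1L) - 1L) / n0            # wrap the first sample around
  y0 <- c(curve$flow, curve$flow[1L])
  x1 <- (seq_len(n_phases) - 1L) / n_phases
  flow_curve(stats::approx(x0, y0, xout = x1)$y, curve$cardiac_period,
             sign_convention = curve$sign_convention, label = curve$label)
}

#' Export a flow curve as CSV
#'
#' Writes columns `phase_index`, `time_s`, `flow_mm3_s`.
#'
#' @param curve a [flow_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flow_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
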