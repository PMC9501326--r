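#' Velocity-encoded cine series
#'
#' One acquisition plane's cine phase-contrast data: a `n_phases x rows x
#' cols` array of through-plane velocities in cm/s plus the acquisition
#' metadata needed to quantify flow. Stored velocities lie in the half-open
#' encoding interval `[-venc, +venc)` unless the series has been unwrapped;
#' the half-open convention makes the aliasing wrap map a bijection.
#' Positive velocity is cranio-caudal through-plane flow.
#'
#' @param v numeric array `n_phases x rows x cols`, velocities in cm/s.
#' @param venc velocity-encoding limit in cm/s (may be `Inf` for an ideal,
#'   unaliased acquisition).
#' @param cardiac_period cardiac cycle duration in seconds.
#' @param pixel_spacing in-plane pixel size, `c(dx, dy)` in mm.
#' @param plane_label free-text acquisition plane name.
#' @param unwrapped logical; `TRUE` once [unwrap_temporal()] has run (stored
#'   velocities may then exceed the encoding interval).
#' @param baseline_corrected logical; `TRUE` once [baseline_correct()] has run.
#' @return an object of class `velocity_series`.
#' @export
velocity_series <- function(v, venc, cardiac_period, pixel_spacing,
                            plane_label = "", unwrapped = FALSE,
                            baseline_corrected = FALSE) {
  if (!is.array(v) || length(dim(v)) != 3L) {
    stop_pcmri("v must be a n_phases x rows x cols array", class = "format_error")
  }
  if (dim(v)[1] < 2L) {
    stop_pcmri("series needs at least 2 cardiac phases", class = "format_error")
  }
  if (!is.numeric(venc) || length(venc) != 1L || is.na(venc) || venc <= 0) {
    stop_pcmri("venc must be a single positive number (Inf allowed)",
               class = "invalid_spec")
  }
  assert_scalar_number(cardiac_period, "cardiac_period", positive = TRUE)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0)) {
    stop_pcmri("pixel_spacing must be two positive numbers (mm)",
               class = "invalid_spec")
  }
  structure(list(v = v, venc = venc, cardiac_period = cardiac_period,
                 pixel_spacing = pixel_spacing, n_phases = dim(v)[1],
                 plane_label = plane_label, unwrapped = isTRUE(unwrapped),
                 baseline_corrected = isTRUE(baseline_corrected),
                 irrecoverable = NULL),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("<velocity_series> %s: %dx%d px, %d phases, VENC %g cm/s, T %.3g s%s%s\n",
              if (nzchar(x$plane_label)) x$plane_label else "(unlabelled)",
              d[2], d[3], x$n_phases, x$venc, x$cardiac_period,
              if (x$unwrapped) ", unwrapped" else "",
              if (x$baseline_corrected) ", baseline-corrected" else ""))
  invisible(x)
}

#' Aliasing wrap map
#'
#' Maps a velocity into the half-open encoding interval `[-venc, +venc)`,
#' `v -> ((v + venc) mod 2 venc) - venc`, the phase-wrap a phase-contrast
#' acquisition applies to any velocity beyond the encoding limit. `venc =
#' Inf` is the identity.
#'
#' @param v numeric vector or array of velocities (cm/s).
#' @param venc encoding limit (cm/s).
#' @return wrapped velocities, same shape as `v`.
#' @export
wrap_velocity <- function(v, venc) {
  if (!is.finite(venc)) return(v)
  ((v + venc) %% (2 * venc)) - venc
}

# n_phases x n_pixels matrix of temporal profiles for the given (row, col)
# pixel matrix.
pixel_profiles <- function(series, px) {
  d <- dim(series$v)
  vm <- matrix(series$v, d[1])
  cols <- px[, 1] + (px[, 2] - 1L) * d[2]
  vm[, cols, drop = FALSE]
}

check_mask_bounds <- function(mask, series) {
  d <- dim(series$v)
  px <- mask$pixels
  if (nrow(px) && (any(px[, 1] < 1L) || any(px[, 2] < 1L) ||
                   any(px[, 1] > d[2]) || any(px[, 2] > d[3]))) {
    stop_pcmri("mask pixels fall outside the image", class = "format_error")
  }
  invisible(TRUE)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a velocity series to NIfTI with a JSON sidecar
#'
#' The image is written as a 4D NIfTI volume (`rows x cols x 1 x n_phases`,
#' stored values in cm/s) and the acquisition metadata as a JSON sidecar
#' `{venc_cm_s, cardiac_period_s, pixel_spacing_mm, n_phases, plane_label}`.
#'
#' @param series a [velocity_series()].
#' @param path output path ending in `.nii.gz` (or `.nii`).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "velocity_series"))
  d <- dim(series$v)
  arr <- aperm(series$v, c(2, 3, 1))
  dim(arr) <- c(d[2], d[3], 1L, d[1])
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$pixel_spacing, 1,
                           series$cardiac_period / series$n_phases)
  RNifti::writeNifti(img, path)
  meta <- list(venc_cm_s = series$venc,
               cardiac_period_s = series$cardiac_period,
               pixel_spacing_mm = series$pixel_spacing,
               n_phases = series$n_phases,
               plane_label = series$plane_label,
               unwrapped = series$unwrapped,
               baseline_corrected = series$baseline_corrected)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a velocity series from NIfTI + JSON sidecar
#'
#' @param path path to the `.nii.gz` volume written by [write_series()] (or
#'   any 4D single-slice velocity cine with the same sidecar convention).
#' @return a [velocity_series()].
#' @export
read_series <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(path)) {
    stop_pcmri("series file not found: ", path, class = "io_error")
  }
  if (!file.exists(sc)) {
    stop_pcmri("missing JSON sidecar: ", sc, class = "metadata_error")
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop_pcmri("expected a 4D cine volume (rows x cols x 1 x phases), got ",
               length(d), "D", class = "format_error")
  }
  if (d[4] != meta$n_phases) {
    stop_pcmri("sidecar n_phases (", meta$n_phases,
               ") disagrees with the volume (", d[4], ")",
               class = "format_error")
  }
  arr <- array(as.numeric(img), dim = c(d[1], d[2], d[4]))
  v <- aperm(arr, c(3, 1, 2))
  velocity_series(v, venc = as.numeric(meta$venc_cm_s),
                  cardiac_period = as.numeric(meta$cardiac_period_s),
                  pixel_spacing = as.numeric(meta$pixel_spacing_mm),
                  plane_label = meta$plane_label %||% "",
                  unwrapped = isTRUE(meta$unwrapped),
                  baseline_corrected = isTRUE(meta$baseline_corrected))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Temporal phase unwrapping
#'
#' Resolves velocity aliasing along the cardiac-phase axis, pixel by pixel.
#' Each pixel's temporal profile is re-anchored at its phase of minimal
#' absolute velocity (the sample most likely to be unaliased), then walked
#' circularly: each successive sample is shifted by the multiple of
#' `2 venc` that brings it closest to its unwrapped predecessor, which
#' corrects any step larger than `venc`. Pixels whose unwrapped excursion
#' (max minus min) exceeds `2 venc` cannot be disambiguated and are flagged
#' in the returned series' `irrecoverable` matrix rather than failed.
#'
#' @param series a [velocity_series()] that has not been unwrapped yet.
#' @return a [velocity_series()] flagged `unwrapped`, with an
#'   `irrecoverable` logical `rows x cols` matrix.
#' @export
unwrap_temporal <- function(series) {
  stopifnot(inherits(series, "velocity_series"))
  if (series$unwrapped) {
    stop_pcmri("series is already unwrapped", class = "invalid_spec")
  }
  venc <- series$venc
  d <- dim(series$v)
  n <- d[1]
  npix <- d[2] * d[3]
  out <- series
  if (!is.finite(venc)) {
    out$unwrapped <- TRUE
    out$irrecoverable <- matrix(FALSE, d[2], d[3])
    return(out)
  }
  vm <- matrix(series$v, n)                       # phases x pixels
  anchor <- max.col(t(-abs(vm)), ties.method = "first")
  # circular visiting order per pixel, as a n x npix index matrix
  w <- matrix(0, n, npix)
  step_idx <- function(i) ((anchor + i - 2L) %% n) + 1L
  lin <- function(idx) cbind(idx, seq_len(npix))
  prev <- vm[lin(step_idx(1L))]
  w[lin(step_idx(1L))] <- prev
  if (n > 1L) {
    for (i in 2:n) {
      raw <- vm[lin(step_idx(i))]
      cur <- raw - 2 * venc * round((raw - prev) / (2 * venc))
      w[lin(step_idx(i))] <- cur
      prev <- cur
    }
  }
  excursion <- apply(w, 2, max) - apply(w, 2, min)
  out$v <- array(w, dim = d)
  out$unwrapped <- TRUE
  out$irrecoverable <- matrix(excursion > 2 * venc, d[2], d[3])
  out
}

#' Eddy-current baseline correction from a static-tissue region
#'
#' Phase-contrast velocity maps carry small spatially constant per-phase
#' offsets (eddy-current residuals). Given a region known to be static, the
#' mean velocity over that region at each phase is an estimate of the offset
#' and is subtracted from the whole slice.
#'
#' @param series a [velocity_series()].
#' @param static_mask a nonempty [roi_mask()] with `category = "static"`.
#' @return the corrected [velocity_series()], flagged `baseline_corrected`.
#' @export
baseline_correct <- function(series, static_mask) {
  stopifnot(inherits(series, "velocity_series"), inherits(static_mask, "roi_mask"))
  if (!nrow(static_mask$pixels)) {
    stop_pcmri("static mask is empty", class = "invalid_mask")
  }
  if (static_mask$category != "static") {
    stop_pcmri("baseline correction needs a mask with category 'static'",
               class = "invalid_mask")
  }
  check_mask_bounds(static_mask, series)
  offsets <- rowMeans(pixel_profiles(series, static_mask$pixels))
  out <- series
  out$v <- series$v - array(offsets, dim = dim(series$v))
  out$baseline_corrected <- TRUE
  out
}
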