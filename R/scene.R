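#' Geometric ROI primitives for synthetic scenes
#'
#' @param center `c(row, col)` centre in pixels.
#' @param radius disc radius in pixels.
#' @param rows,cols integer ranges of a rectangle.
#' @return a shape description consumed by [scene_roi()].
#' @name scene_shapes
NULL

#' @rdname scene_shapes
#' @export
shape_disc <- function(center, radius) {
  structure(list(type = "disc", center = center, radius = radius),
            class = "scene_shape")
}

#' @rdname scene_shapes
#' @export
shape_rect <- function(rows, cols) {
  structure(list(type = "rect", rows = range(rows), cols = range(cols)),
            class = "scene_shape")
}

shape_pixels <- function(shape, grid) {
  switch(shape$type,
    disc = {
      rr <- ceiling(shape$radius)
      g <- expand.grid(row = (shape$center[1] - rr):(shape$center[1] + rr),
                       col = (shape$center[2] - rr):(shape$center[2] + rr))
      keep <- (g$row - shape$center[1])^2 + (g$col - shape$center[2])^2 <=
        shape$radius^2
      as.matrix(g[keep, , drop = FALSE])
    },
    rect = as.matrix(expand.grid(row = shape$rows[1]:shape$rows[2],
                                 col = shape$cols[1]:shape$cols[2])),
    stop_pcmri("unknown shape type", class = "invalid_spec"))
}

#' ROI entry of a synthetic scene
#'
#' @param label ROI name, unique within the scene.
#' @param category one of `"arterial"`, `"venous"`, `"csf"`, `"tissue"`,
#'   `"static"`.
#' @param shape a [shape_disc()] or [shape_rect()].
#' @param waveform a [waveform_spec()], or `NULL` for a static (zero-flow)
#'   region.
#' @param flow_dir physical direction of the structure's forward flow
#'   through the slice: `"craniocaudal"` (stored positive) or
#'   `"caudocranial"` (stored negative, e.g. arterial inflow at the neck).
#' @return a scene ROI description.
#' @export
scene_roi <- function(label, category = c("arterial", "venous", "csf",
                                          "tissue", "static"),
                      shape, waveform = NULL,
                      flow_dir = c("craniocaudal", "caudocranial")) {
  category <- match.arg(category)
  flow_dir <- match.arg(flow_dir)
  if (is.null(waveform) && category != "static") {
    stop_pcmri("non-static ROI needs a waveform", class = "invalid_spec")
  }
  if (!is.null(waveform)) stopifnot(inherits(waveform, "waveform_spec"))
  structure(list(label = label, category = category, shape = shape,
                 waveform = waveform, flow_dir = flow_dir),
            class = "scene_roi_spec")
}

#' Synthetic cine scene specification
#'
#' Describes one acquisition plane of the velocity phantom: a pixel grid,
#' a set of disjoint ROIs each carrying a flow waveform, the encoding limit,
#' per-phase eddy-current offsets and Gaussian velocity noise.
#'
#' @param grid `c(rows, cols)` image size in pixels.
#' @param pixel_spacing `c(dx, dy)` in mm.
#' @param rois list of [scene_roi()] entries with disjoint pixel sets.
#' @param venc encoding limit in cm/s (`Inf` disables aliasing).
#' @param n_phases number of reconstructed cardiac phases (>= 8).
#' @param cardiac_period cycle duration in seconds.
#' @param noise_sd Gaussian velocity noise SD in cm/s.
#' @param offset_per_phase spatially constant per-phase offsets in cm/s:
#'   a scalar (replicated), a vector of length `n_phases`, or `NULL` for
#'   none.
#' @param plane_label acquisition plane name.
#' @param seed RNG seed for reproducible noise, or `NULL`.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(grid, pixel_spacing = c(1, 1), rois, venc,
                       n_phases = 32L, cardiac_period = 1, noise_sd = 0,
                       offset_per_phase = NULL, plane_label = "", seed = NULL) {
  n_phases <- as.integer(n_phases)
  if (n_phases < 8L) stop_pcmri("n_phases must be >= 8", class = "invalid_spec")
  if (!is.numeric(venc) || length(venc) != 1L || is.na(venc) || venc <= 0) {
    stop_pcmri("venc must be a single positive number (Inf allowed)",
               class = "invalid_spec")
  }
  assert_scalar_number(cardiac_period, "cardiac_period", positive = TRUE)
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_pcmri("noise_sd must be >= 0", class = "invalid_spec")
  if (is.null(offset_per_phase)) offset_per_phase <- 0
  offset_per_phase <- as.numeric(offset_per_phase)
  if (length(offset_per_phase) == 1L) {
    offset_per_phase <- rep(offset_per_phase, n_phases)
  }
  if (length(offset_per_phase) != n_phases) {
    stop_pcmri("offset_per_phase must have length 1 or n_phases",
               class = "invalid_spec")
  }
  stopifnot(is.list(rois), length(rois) >= 1L,
            all(vapply(rois, inherits, TRUE, "scene_roi_spec")))
  labels <- vapply(rois, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop_pcmri("ROI labels must be unique", class = "invalid_spec")
  }
  # disjointness
  seen <- integer(0)
  for (r in rois) {
    px <- shape_pixels(r$shape, grid)
    if (any(px[, 1] < 1 | px[, 2] < 1 | px[, 1] > grid[1] | px[, 2] > grid[2])) {
      stop_pcmri("ROI '", r$label, "' extends outside the grid",
                 class = "invalid_spec")
    }
    id <- px[, 1] + (px[, 2] - 1L) * grid[1]
    if (length(intersect(id, seen))) {
      stop_pcmri("ROIs must be disjoint (overlap at '", r$label, "')",
                 class = "invalid_spec")
    }
    seen <- c(seen, id)
  }
  structure(list(grid = as.integer(grid), pixel_spacing = pixel_spacing,
                 rois = rois, venc = venc, n_phases = n_phases,
                 cardiac_period = cardiac_period, noise_sd = noise_sd,
                 offset_per_phase = offset_per_phase,
                 plane_label = plane_label, seed = seed),
            class = "scene_spec")
}

#' Render a synthetic velocity cine series with ground truth
#'
#' Renders the through-plane velocity movie of a [scene_spec()]: within each
#' ROI the velocity is spatially uniform, `Q(t) / (n_px * pixel area)`
#' (converted to cm/s), signed by the ROI's flow direction relative to the
#' cranio-caudal-positive convention. The spatially constant per-phase
#' offset and i.i.d. Gaussian noise are added, and the result is wrapped
#' into `[-venc, +venc)` exactly as an aliased acquisition would store it.
#'
#' The returned ground truth records, per ROI: the true forward-positive
#' flow curve, its stroke volume and peak-to-peak amplitude on the same
#' phase grid, the true pixel set, the peak true velocity, and a
#' `wrap_warning` flag when the ROI's velocity magnitude exceeds `2 venc`
#' (beyond which temporal unwrapping is not guaranteed).
#'
#' @param scene a [scene_spec()].
#' @return a list with elements `series` (a [velocity_series()]) and
#'   `truth` (class `pcmri_ground_truth`).
#' @export
render_velocity_series <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  with_seed(scene$seed, {
    n <- scene$n_phases
    nr <- scene$grid[1]; nc <- scene$grid[2]
    area <- prod(scene$pixel_spacing)
    v <- array(0, dim = c(n, nr, nc))
    truth_rois <- list()
    for (r in scene$rois) {
      px <- shape_pixels(r$shape, scene$grid)
      if (is.null(r$waveform)) {
        q <- rep(0, n)
      } else {
        q <- make_waveform(r$waveform, n)$flow
      }
      npx <- nrow(px)
      dir <- if (r$flow_dir == "caudocranial") -1 else 1
      vel <- dir * q / (npx * area) / 10        # mm^3/s -> cm/s per pixel
      cols <- px[, 1] + (px[, 2] - 1L) * nr
      vm <- matrix(v, n)
      vm[, cols] <- vel                          # recycled down each column
      v <- array(vm, dim = c(n, nr, nc))
      curve <- flow_curve(q, scene$cardiac_period, label = r$label)
      peak_v <- max(abs(vel + scene$offset_per_phase))
      truth_rois[[r$label]] <- list(
        label = r$label, category = r$category, flow_dir = r$flow_dir,
        pixels = px, flow = q, sv = stroke_volume(curve),
        amplitude = peak_amplitude(curve), peak_velocity_cm_s = peak_v,
        wrap_warning = is.finite(scene$venc) && peak_v > 2 * scene$venc)
    }
    v <- v + array(scene$offset_per_phase, dim = dim(v))
    if (scene$noise_sd > 0) {
      v <- v + array(stats::rnorm(length(v), sd = scene$noise_sd), dim = dim(v))
    }
    v <- wrap_velocity(v, scene$venc)
    series <- velocity_series(v, venc = scene$venc,
                              cardiac_period = scene$cardiac_period,
                              pixel_spacing = scene$pixel_spacing,
                              plane_label = scene$plane_label)
    truth <- structure(
      list(rois = truth_rois, offsets = scene$offset_per_phase,
           noise_sd = scene$noise_sd, venc = scene$venc,
           cardiac_period = scene$cardiac_period,
           n_phases = n, seed = scene$seed),
      class = "pcmri_ground_truth")
    list(series = series, truth = truth)
  })
}

#' Write a rendered scene to disk
#'
#' Writes the NIfTI volume with its JSON sidecar via [write_series()], plus
#' a ground-truth JSON (`<prefix>_truth.json`) listing every ROI with its
#' true flow curve, stroke volume, amplitude and pixel set.
#'
#' @param series a [velocity_series()].
#' @param truth the matching `pcmri_ground_truth`.
#' @param dir output directory (created if needed).
#' @param prefix file name stem; defaults to the series' plane label.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_scene <- function(series, truth, dir, prefix = NULL) {
  stopifnot(inherits(series, "velocity_series"),
            inherits(truth, "pcmri_ground_truth"))
  if (is.null(prefix)) prefix <- series$plane_label
  if (!nzchar(prefix)) prefix <- "scene"
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nii <- file.path(dir, paste0(prefix, ".nii.gz"))
  write_series(series, nii)
  tj <- file.path(dir, paste0(prefix, "_truth.json"))
  tr <- list(
    offsets = truth$offsets, noise_sd = truth$noise_sd, venc = truth$venc,
    cardiac_period = truth$cardiac_period, n_phases = truth$n_phases,
    seed = truth$seed,
    rois = lapply(truth$rois, function(r) {
      list(label = r$label, category = r$category, flow_dir = r$flow_dir,
           pixels = unname(r$pixels), flow = r$flow,
           sv = unclass(r$sv), amplitude = r$amplitude,
           peak_velocity_cm_s = r$peak_velocity_cm_s,
           wrap_warning = r$wrap_warning)
    }))
  jsonlite::write_json(tr, tj, auto_unbox = TRUE, digits = NA)
  invisible(c(nifti = nii, sidecar = sidecar_path(nii), truth = tj))
}

#' Read a ground-truth JSON written by [write_scene()]
#'
#' @param path path to the `_truth.json` file.
#' @return a `pcmri_ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- lapply(x$rois, function(r) {
    px <- matrix(as.integer(unlist(r$pixels)), ncol = 2,
                 dimnames = list(NULL, c("row", "col")))
    if (is.matrix(r$pixels)) px <- matrix(as.integer(r$pixels), ncol = 2,
                                          dimnames = list(NULL, c("row", "col")))
    list(label = r$label, category = r$category, flow_dir = r$flow_dir,
         pixels = px, flow = as.numeric(r$flow),
         sv = structure(as.list(r$sv), class = "stroke_volume_result"),
         amplitude = r$amplitude, peak_velocity_cm_s = r$peak_velocity_cm_s,
         wrap_warning = isTRUE(r$wrap_warning))
  })
  structure(list(rois = rois, offsets = as.numeric(x$offsets),
                 noise_sd = x$noise_sd, venc = x$venc,
                 cardiac_period = x$cardiac_period, n_phases = x$n_phases,
                 seed = x$seed),
            class = "pcmri_ground_truth")
}
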