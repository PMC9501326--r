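#' Region-of-interest mask on a velocity series
#'
#' @param pixels two-column integer matrix of `(row, col)` pixel
#'   coordinates.
#' @param label ROI name.
#' @param category one of `"arterial"`, `"venous"`, `"csf"`, `"tissue"`,
#'   `"static"`.
#' @param source `"seed-grown"` or `"manual"`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(pixels, label = "",
                     category = c("arterial", "venous", "csf", "tissue",
                                  "static"),
                     source = c("seed-grown", "manual")) {
  category <- match.arg(category)
  source <- match.arg(source)
  pixels <- as.matrix(pixels)
  if (length(pixels) && ncol(pixels) != 2L) {
    stop_pcmri("pixels must be a (row, col) matrix", class = "invalid_mask")
  }
  if (!length(pixels)) pixels <- matrix(integer(0), ncol = 2)
  storage.mode(pixels) <- "integer"
  if (length(pixels) && any(pixels < 1L)) {
    stop_pcmri("pixel coordinates must be >= 1", class = "format_error")
  }
  colnames(pixels) <- c("row", "col")
  structure(list(pixels = pixels, label = label, category = category,
                 source = source),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s (%s, %s): %d pixel(s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$category, x$source, nrow(x$pixels)))
  invisible(x)
}

#' Jaccard overlap of two masks
#'
#' @param a,b [roi_mask()] objects (or two-column pixel matrices).
#' @return intersection over union of the two pixel sets.
#' @export
mask_jaccard <- function(a, b) {
  key <- function(m) {
    px <- if (inherits(m, "roi_mask")) m$pixels else as.matrix(m)
    paste(px[, 1], px[, 2])
  }
  ka <- key(a); kb <- key(b)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Semi-automatic ROI delineation by correlation-thresholded region growing
#'
#' Grows a 4-connected region from a seed pixel on a cine velocity series.
#' A candidate pixel joins the region if
#' (a) the Pearson correlation of its temporal velocity profile with the
#' current region's mean profile is at least `r_min`, and
#' (b) its peak-to-peak velocity is at least `amp_frac` times the seed's
#' peak-to-peak velocity.
#' The region mean profile is updated incrementally as pixels join. The
#' frontier is explored breadth-first from the seed with a fixed neighbour
#' order (up, down, left, right), and every examined pixel is visited at
#' most once, making the result order-deterministic. In the velocity
#' domain, temporal-profile correlation plays the role that intensity
#' similarity plays in conventional region growing: adjacent structures
#' with unlike or anticorrelated waveforms (CSF against blood) are not
#' merged even when both are strongly pulsatile.
#'
#' @param series a [velocity_series()]; unwrap and baseline-correct first
#'   when the acquisition is aliased or offset.
#' @param seed `c(row, col)` seed pixel inside the target structure; its
#'   profile must not be flat.
#' @param category ROI category recorded in the mask.
#' @param r_min minimum Pearson correlation with the region mean profile
#'   (default 0.7). Pixels with a flat (zero-variance) profile never join.
#' @param amp_frac minimum peak-to-peak velocity as a fraction of the
#'   seed's (default 0.1 for vessels/CSF).
#' @param max_pixels safety cap on the region size.
#' @return a [roi_mask()] with `source = "seed-grown"`.
#' @export
segment_from_seed <- function(series, seed,
                              category = c("arterial", "venous", "csf",
                                           "tissue", "static"),
                              r_min = 0.7, amp_frac = 0.1,
                              max_pixels = Inf) {
  stopifnot(inherits(series, "velocity_series"))
  category <- match.arg(category)
  d <- dim(series$v)
  nr <- d[2]; nc <- d[3]
  seed <- as.integer(seed)
  if (length(seed) != 2L || seed[1] < 1L || seed[2] < 1L ||
      seed[1] > nr || seed[2] > nc) {
    stop_pcmri("seed pixel outside the image", class = "invalid_seed")
  }
  vm <- matrix(series$v, d[1])                  # phases x pixels
  idx <- function(r, c) r + (c - 1L) * nr
  seed_prof <- vm[, idx(seed[1], seed[2])]
  seed_p2p <- max(seed_prof) - min(seed_prof)
  if (seed_p2p <= 0) {
    stop_pcmri("seed pixel has a flat velocity profile", class = "invalid_seed")
  }
  amp_min <- amp_frac * seed_p2p

  visited <- matrix(FALSE, nr, nc)
  in_mask <- matrix(FALSE, nr, nc)
  queue_r <- integer(0); queue_c <- integer(0)
  region_sum <- seed_prof
  region_n <- 1L
  visited[seed[1], seed[2]] <- TRUE
  in_mask[seed[1], seed[2]] <- TRUE
  queue_r <- seed[1]; queue_c <- seed[2]
  head <- 1L
  # neighbour order: up, down, left, right (row-major tie-breaking)
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  while (head <= length(queue_r) && region_n < max_pixels) {
    r0 <- queue_r[head]; c0 <- queue_c[head]; head <- head + 1L
    mean_prof <- region_sum / region_n
    for (k in 1:4) {
      r1 <- r0 + dr[k]; c1 <- c0 + dc[k]
      if (r1 < 1L || c1 < 1L || r1 > nr || c1 > nc) next
      if (visited[r1, c1]) next
      visited[r1, c1] <- TRUE
      prof <- vm[, idx(r1, c1)]
      p2p <- max(prof) - min(prof)
      if (p2p < amp_min) next
      r <- suppressWarnings(stats::cor(prof, mean_prof))
      if (is.na(r) || r < r_min) next
      in_mask[r1, c1] <- TRUE
      region_sum <- region_sum + prof
      region_n <- region_n + 1L
      queue_r <- c(queue_r, r1); queue_c <- c(queue_c, c1)
      mean_prof <- region_sum / region_n
    }
  }
  px <- which(in_mask, arr.ind = TRUE)
  colnames(px) <- c("row", "col")
  px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
  roi_mask(px, label = paste0(category, "_seed_", seed[1], "_", seed[2]),
           category = category, source = "seed-grown")
}

#' Tonsil / tissue-motion delineation
#'
#' Same correlation-thresholded region growing as [segment_from_seed()],
#' with tissue-scale defaults: tissue velocities are an order of magnitude
#' below CSF velocities on the same plane, so the amplitude floor is
#' lowered to `amp_frac = 0.02` while the correlation criterion still
#' excludes the surrounding CSF.
#'
#' @inheritParams segment_from_seed
#' @return a [roi_mask()] with `category = "tissue"`.
#' @export
segment_tonsils <- function(series, seed, r_min = 0.7, amp_frac = 0.02,
                            max_pixels = Inf) {
  segment_from_seed(series, seed, category = "tissue", r_min = r_min,
                    amp_frac = amp_frac, max_pixels = max_pixels)
}

#' Write a mask as a NIfTI label map
#'
#' @param mask a [roi_mask()].
#' @param dim image size `c(rows, cols)`.
#' @param path output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, dim, path) {
  stopifnot(inherits(mask, "roi_mask"))
  check_px <- mask$pixels
  if (nrow(check_px) && (any(check_px[, 1] > dim[1]) ||
                         any(check_px[, 2] > dim[2]))) {
    stop_pcmri("mask pixels exceed the image bounds", class = "format_error")
  }
  lab <- matrix(0L, dim[1], dim[2])
  lab[mask$pixels] <- 1L
  RNifti::writeNifti(RNifti::asNifti(lab), path)
  invisible(path)
}

#' Load a manually drawn mask from a NIfTI label map
#'
#' @param path path to a 2D integer label map; nonzero pixels form the mask.
#' @param series the [velocity_series()] the mask belongs to (shape check).
#' @param label,category stored on the returned mask.
#' @return a [roi_mask()] with `source = "manual"`.
#' @export
load_manual_mask <- function(path, series, label = "manual",
                             category = c("arterial", "venous", "csf",
                                          "tissue", "static")) {
  stopifnot(inherits(series, "velocity_series"))
  category <- match.arg(category)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  d <- d[d > 1]                               # drop singleton dims
  sd_ <- dim(series$v)[2:3]
  if (length(d) != 2L || any(d != sd_)) {
    stop_pcmri("mask shape (", paste(dim(img), collapse = "x"),
               ") does not match the series (", sd_[1], "x", sd_[2], ")",
               class = "format_error")
  }
  lab <- matrix(as.numeric(img), sd_[1], sd_[2])
  px <- which(lab != 0, arr.ind = TRUE)
  if (!nrow(px)) {
    stop_pcmri("mask file contains no labelled pixels", class = "invalid_mask")
  }
  colnames(px) <- c("row", "col")
  roi_mask(px, label = label, category = category, source = "manual")
}
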