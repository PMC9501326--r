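#' Default pre/post cohort parameter distributions
#'
#' Marginal means and standard deviations of the eight hemodynamic and
#' hydrodynamic parameters in a pre/post decompression-surgery cohort of 21
#' adult Chiari I patients, used as the defaults of [cohort_spec()]. Stroke
#' volumes in uL/CC, the venous amplitude in mm^3/s, the correction factor
#' dimensionless; `lower` is the truncation bound enforced by the sampler
#' (stroke volumes and amplitudes are nonnegative, the correction factor is
#' at least 1).
#'
#' @return a data frame with columns `parameter`, `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`, `lower`.
#' @export
chiari_cohort_defaults <- function() {
  data.frame(
    parameter = c("sv_aqueduct", "sv_foramen", "sv_tonsils", "sv_cervical",
                  "sv_vascular", "amp_venous", "correction_factor",
                  "sv_syrinx"),
    pre_mean  = c(39, 201, 323, 434, 1661, 5578, 1.38, 118),
    pre_sd    = c(33, 124, 175, 309, 433, 2469, 0.3, 86),
    post_mean = c(30, 363, 194, 398, 1490, 4576, 1.20, 26),
    post_sd   = c(26, 231, 130, 241, 532, 2084, 0.3, 28),
    lower     = c(0, 0, 0, 0, 0, 0, 1, 0))
}

#' Paired pre/post cohort specification
#'
#' Defines the sampling distribution of a paired pre/post cohort: per
#' parameter, `(pre, post)` are drawn from a bivariate normal with the
#' given marginal means/SDs and within-subject correlation `rho`, then
#' truncated at the parameter's lower bound by resampling (never by
#' clipping, which would pile mass on the bound).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param params parameter table in the format of
#'   [chiari_cohort_defaults()].
#' @param rho within-subject pre/post correlation, in `[0, 1)`. The study
#'   design reports only marginal summaries, so this is a free simulation
#'   parameter; 0.7 is the default.
#' @param syrinx_fraction fraction of subjects with a syringomyelia cavity
#'   (only they carry `sv_syrinx`).
#' @param duraplasty_fraction fraction treated by duraplasty (the rest by
#'   extradural bone decompression).
#' @param seed RNG seed, or `NULL`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 21L, params = chiari_cohort_defaults(),
                        rho = 0.7, syrinx_fraction = 12 / 21,
                        duraplasty_fraction = 12 / 21, seed = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) {
    stop_pcmri("n_subjects must be at least 2", class = "invalid_spec")
  }
  assert_scalar_number(rho, "rho")
  if (rho < 0 || rho >= 1) {
    stop_pcmri("rho must lie in [0, 1)", class = "invalid_spec")
  }
  need <- c("parameter", "pre_mean", "pre_sd", "post_mean", "post_sd", "lower")
  if (!all(need %in% names(params))) {
    stop_pcmri("params must have columns ", paste(need, collapse = ", "),
               class = "invalid_spec")
  }
  if (any(params$pre_sd < 0) || any(params$post_sd < 0)) {
    stop_pcmri("SDs must be nonnegative", class = "invalid_spec")
  }
  if (any(params$pre_mean < params$lower) ||
      any(params$post_mean < params$lower)) {
    stop_pcmri("parameter means must respect their lower bounds",
               class = "invalid_spec")
  }
  structure(list(n_subjects = n_subjects, params = params, rho = rho,
                 syrinx_fraction = syrinx_fraction,
                 duraplasty_fraction = duraplasty_fraction, seed = seed),
            class = "cohort_spec")
}

# Truncated bivariate-normal pair sampler (resampling truncation).
draw_pair <- function(n, m1, s1, m2, s2, rho, lower) {
  pre <- post <- numeric(n)
  need <- rep(TRUE, n)
  while (any(need)) {
    k <- sum(need)
    z1 <- stats::rnorm(k)
    z2 <- stats::rnorm(k)
    p1 <- m1 + s1 * z1
    p2 <- m2 + s2 * (rho * z1 + sqrt(1 - rho^2) * z2)
    ok <- p1 >= lower & p2 >= lower
    hit <- which(need)[ok]
    pre[hit] <- p1[ok]
    post[hit] <- p2[ok]
    need[hit] <- FALSE
  }
  list(pre = pre, post = post)
}

#' Sample a paired pre/post cohort
#'
#' Draws `n_subjects` paired subject parameter sets from a [cohort_spec()].
#' `sv_syrinx` is sampled only for the syrinx subgroup and is `NA`
#' elsewhere. Surgery type and syrinx status are assigned by sampling the
#' specified fractions without replacement, so group sizes are fixed given
#' the spec. With the seed fixed the output is reproducible bit for bit.
#'
#' @param spec a [cohort_spec()].
#' @return a data frame with one row per subject: `subject`, `has_syrinx`,
#'   `surgery_type`, and `pre_`/`post_`-prefixed parameter columns.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    p <- spec$params
    out <- data.frame(subject = seq_len(n))
    n_syrinx <- round(spec$syrinx_fraction * n)
    has_syrinx <- rep(FALSE, n)
    has_syrinx[sample.int(n, n_syrinx)] <- TRUE
    n_dura <- round(spec$duraplasty_fraction * n)
    surgery <- rep("extradural", n)
    surgery[sample.int(n, n_dura)] <- "duraplasty"
    out$has_syrinx <- has_syrinx
    out$surgery_type <- surgery
    for (i in seq_len(nrow(p))) {
      pair <- draw_pair(n, p$pre_mean[i], p$pre_sd[i],
                        p$post_mean[i], p$post_sd[i], spec$rho, p$lower[i])
      if (p$parameter[i] == "sv_syrinx") {
        pair$pre[!has_syrinx] <- NA_real_
        pair$post[!has_syrinx] <- NA_real_
      }
      out[[paste0("pre_", p$parameter[i])]] <- pair$pre
      out[[paste0("post_", p$parameter[i])]] <- pair$post
    }
    out
  })
}

#' Write a sampled cohort to CSV
#'
#' @param cohort the data frame from [sample_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
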