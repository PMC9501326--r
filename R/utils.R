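# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_pcmri <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "pcmriflow_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pcmri(name, " must be a single finite number", class = "invalid_spec")
  }
  if (positive && x <= 0) {
    stop_pcmri(name, " must be positive", class = "invalid_spec")
  }
  invisible(x)
}

# Relative difference with a guard against a zero reference.
rel_diff <- function(x, ref) abs(x - ref) / max(abs(ref), .Machine$double.eps)
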