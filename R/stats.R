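# Cohort statistics: group summaries, paired and two-group comparisons,
# percent change, and the three study-style result tables.

#' Mean and sample SD summary
#'
#' @param values numeric vector with at least 2 finite values.
#' @return a list with `mean`, `sd` (n-1 denominator), `n` and a formatted
#'   `label` of the form `"323 +/- 175"`.
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop_pcmri("need at least 2 values to summarize", class = "insufficient_data")
  }
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, sd = s, n = length(values),
       label = sprintf("%.3g ± %.3g", m, s))
}

comparison_row <- function(parameter, a, b, statistic, p, test, n_a, n_b,
                           degenerate = FALSE, computable = TRUE) {
  data.frame(parameter = parameter,
             mean_a = a[1], sd_a = a[2], mean_b = b[1], sd_b = b[2],
             n_a = n_a, n_b = n_b, statistic = statistic, p = p,
             test = test, degenerate = degenerate, computable = computable,
             stringsAsFactors = FALSE)
}

#' Paired pre/post comparison (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences. Zero
#' differences are dropped before ranking (the standard signed-rank
#' handling). The exact null distribution is used for up to 25 nonzero
#' untied differences; larger samples or tied absolute differences fall
#' back to the normal approximation with tie correction. If every
#' difference is zero the comparison is degenerate: `p = 1` with the
#' `degenerate` flag set.
#'
#' @param pre,post paired numeric vectors of equal length (`NA` pairs are
#'   dropped).
#' @param parameter row label.
#' @return a one-row data frame (see `ComparisonRow`): group summaries,
#'   test statistic, two-sided p-value, test name, group sizes and flags.
#' @export
paired_compare <- function(pre, post, parameter = "") {
  if (length(pre) != length(post)) {
    stop_pcmri("pre and post must have equal length", class = "invalid_spec")
  }
  keep <- is.finite(pre) & is.finite(post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 2L) {
    stop_pcmri("need at least 2 complete pairs", class = "insufficient_data")
  }
  a <- c(mean(pre), stats::sd(pre))
  b <- c(mean(post), stats::sd(post))
  d <- post - pre
  d <- d[d != 0]
  if (!length(d)) {
    return(comparison_row(parameter, a, b, statistic = NA_real_, p = 1,
                          test = "wilcoxon_signed_rank", n, n,
                          degenerate = TRUE))
  }
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = !exact))
  comparison_row(parameter, a, b, statistic = unname(wt$statistic),
                 p = wt$p.value, test = "wilcoxon_signed_rank", n, n)
}

#' Two-group comparison (Student's t-test)
#'
#' Two-sided two-sample t-test, pooled variance by default (`welch = TRUE`
#' switches to the Welch unequal-variance form). When both groups are
#' constant the test is degenerate: `p = 1` if the means agree, `p = 0`
#' otherwise, with the `degenerate` flag set.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 finite
#'   values.
#' @param parameter row label.
#' @param welch use the Welch test instead of pooled variance.
#' @return a one-row comparison data frame.
#' @export
group_compare <- function(group_a, group_b, parameter = "", welch = FALSE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_pcmri("each group needs at least 2 values", class = "insufficient_data")
  }
  a <- c(mean(group_a), stats::sd(group_a))
  b <- c(mean(group_b), stats::sd(group_b))
  res <- tryCatch(
    stats::t.test(group_a, group_b, var.equal = !welch),
    error = function(e) NULL)
  if (is.null(res)) {
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(comparison_row(parameter, a, b, statistic = NA_real_,
                          p = if (same) 1 else 0,
                          test = if (welch) "welch_t" else "student_t",
                          length(group_a), length(group_b),
                          degenerate = TRUE))
  }
  comparison_row(parameter, a, b, statistic = unname(res$statistic),
                 p = res$p.value, test = if (welch) "welch_t" else "student_t",
                 length(group_a), length(group_b))
}

#' Post-over-pre percent change
#'
#' `100 x post / pre`: a value below 100% is a decrease, above 100% an
#' increase.
#'
#' @param pre,post numeric vectors (recycled); `pre` must be positive.
#' @return percent change, same length as the longer input.
#' @export
percent_change <- function(pre, post) {
  if (any(is.finite(pre) & pre <= 0)) {
    stop_pcmri("percent change is undefined for pre <= 0",
               class = "undefined_change")
  }
  100 * post / pre
}

#' Percentage of a count
#'
#' @param count,total nonnegative counts with `count <= total`,
#'   `total > 0`.
#' @return `100 x count / total`.
#' @export
count_percent <- function(count, total) {
  if (any(total <= 0) || any(count < 0) || any(count > total)) {
    stop_pcmri("need 0 <= count <= total and total > 0",
               class = "invalid_spec")
  }
  100 * count / total
}

cohort_parameters <- function(cohort) {
  pre_cols <- grep("^pre_", names(cohort), value = TRUE)
  sub("^pre_", "", pre_cols)
}

#' Build the three study-style result tables from a paired cohort
#'
#' Produces, from a cohort data frame in the [sample_cohort()] layout
#' (`pre_`/`post_`-prefixed parameter columns plus `has_syrinx` and
#' `surgery_type`):
#' \describe{
#'   \item{`syrinx_comparison`}{preoperative parameters, syrinx vs
#'     no-syrinx groups, Student's t-test per parameter (the syrinx stroke
#'     volume itself is excluded since only one group carries it).}
#'   \item{`prepost_comparison`}{paired pre vs post comparison per
#'     parameter, Wilcoxon signed-rank test; pairs with a missing stage are
#'     excluded and logged in the `exclusions` attribute.}
#'   \item{`surgery_comparison`}{per-subject post-over-pre percent change
#'     per parameter, compared between the extradural and duraplasty groups
#'     with Student's t-test.}
#' }
#' A parameter whose groups cannot be formed (fewer than 2 usable values on
#' either side) yields a row flagged `computable = FALSE` instead of an
#' error.
#'
#' @param cohort cohort data frame (see [sample_cohort()]).
#' @param welch use Welch's t-test in the group comparisons.
#' @return a named list of three data frames, class `pcmri_tables`.
#' @export
build_tables <- function(cohort, welch = FALSE) {
  pars <- cohort_parameters(cohort)
  if (!length(pars)) {
    stop_pcmri("cohort has no pre_/post_ parameter columns",
               class = "invalid_spec")
  }
  safe_group <- function(a, b, parameter, transform = identity) {
    tryCatch(group_compare(a, b, parameter, welch = welch),
             pcmriflow_error = function(e)
               comparison_row(parameter, c(NA, NA), c(NA, NA), NA_real_,
                              NA_real_, if (welch) "welch_t" else "student_t",
                              sum(is.finite(a)), sum(is.finite(b)),
                              computable = FALSE))
  }
  safe_paired <- function(pre, post, parameter) {
    tryCatch(paired_compare(pre, post, parameter),
             pcmriflow_error = function(e)
               comparison_row(parameter, c(NA, NA), c(NA, NA), NA_real_,
                              NA_real_, "wilcoxon_signed_rank",
                              sum(is.finite(pre) & is.finite(post)),
                              sum(is.finite(pre) & is.finite(post)),
                              computable = FALSE))
  }

  syrinx_rows <- lapply(setdiff(pars, "sv_syrinx"), function(pp) {
    x <- cohort[[paste0("pre_", pp)]]
    safe_group(x[cohort$has_syrinx], x[!cohort$has_syrinx], pp)
  })

  prepost_rows <- lapply(pars, function(pp) {
    safe_paired(cohort[[paste0("pre_", pp)]], cohort[[paste0("post_", pp)]], pp)
  })
  complete <- rep(TRUE, nrow(cohort))
  for (pp in setdiff(pars, "sv_syrinx")) {
    complete <- complete & is.finite(cohort[[paste0("pre_", pp)]]) &
      is.finite(cohort[[paste0("post_", pp)]])
  }
  exclusions <- cohort$subject[!complete]

  surgery_rows <- lapply(pars, function(pp) {
    pre <- cohort[[paste0("pre_", pp)]]
    post <- cohort[[paste0("post_", pp)]]
    pc <- suppressWarnings(percent_change(pre, post))
    dura <- cohort$surgery_type == "duraplasty"
    safe_group(pc[!dura], pc[dura], pp)
  })

  tables <- list(
    syrinx_comparison = do.call(rbind, syrinx_rows),
    prepost_comparison = do.call(rbind, prepost_rows),
    surgery_comparison = do.call(rbind, surgery_rows))
  attr(tables, "exclusions") <- exclusions
  class(tables) <- "pcmri_tables"
  tables
}

#' Write the result tables as CSV files
#'
#' @param tables a `pcmri_tables` list from [build_tables()].
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "pcmri_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
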