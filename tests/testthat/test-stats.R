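test_that("summaries use the sample SD and reject tiny samples", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3)
  expect_equal(summarize_values(rep(7, 5))$sd, 0)
  expect_error(summarize_values(5), class = "insufficient_data")
})

test_that("paired comparison reproduces the exact signed-rank distribution", {
  # identical stages: degenerate, p = 1
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  r <- paired_compare(x, x)
  expect_true(r$degenerate)
  expect_equal(r$p, 1)

  # all 8 differences positive: exact two-sided p = 2 / 2^8
  pre <- c(10, 12, 9, 14, 11, 13, 10.5, 12.5)
  post <- pre + c(1, 2, 0.5, 3, 1.5, 2.5, 0.7, 1.2)
  r8 <- paired_compare(pre, post)
  expect_equal(r8$p, 2 / 2^8)
  expect_equal(r8$p, oracle_signed_rank_p(post - pre))

  # property: exact p agrees with exhaustive sign enumeration for n <= 10
  set.seed(71)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    d <- stats::rnorm(n)
    p_pkg <- paired_compare(rep(0, n), d)$p
    expect_equal(p_pkg, oracle_signed_rank_p(d), tolerance = 1e-12)
  }

  expect_error(paired_compare(1:3, 1:4), class = "invalid_spec")
  expect_error(paired_compare(1, 2), class = "insufficient_data")
})

test_that("group comparison handles separation and degeneracy", {
  r <- group_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$p, 1, tolerance = 1e-12)

  set.seed(72)
  a <- c(0, 0, 0, 0) + stats::rnorm(4, sd = 1e-6)
  b <- c(1, 1, 1, 1) + stats::rnorm(4, sd = 1e-6)
  expect_lt(group_compare(a, b)$p, 1e-10)

  dg <- group_compare(rep(2, 3), rep(2, 4))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)

  # pooled-variance default agrees with stats::t.test
  x <- stats::rnorm(10); y <- stats::rnorm(12, mean = 0.5)
  expect_equal(group_compare(x, y)$p,
               stats::t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(group_compare(x, y, welch = TRUE)$p,
               stats::t.test(x, y)$p.value)
  expect_error(group_compare(1, c(1, 2)), class = "insufficient_data")
})

test_that("percent change follows the post-over-pre decrease convention", {
  expect_equal(percent_change(200, 100), 50)   # a decrease: below 100%
  expect_equal(percent_change(100, 150), 150)  # an increase: above 100%
  expect_equal(percent_change(c(5, 10), c(5, 10)), c(100, 100))
  # monotone in post
  expect_true(all(diff(percent_change(50, c(10, 20, 40, 80))) > 0))
  expect_error(percent_change(0, 10), class = "undefined_change")
  expect_error(percent_change(-3, 10), class = "undefined_change")
})

test_that("count percentages validate their inputs", {
  expect_equal(count_percent(14, 21), 200 / 3)
  expect_equal(count_percent(0, 10), 0)
  expect_error(count_percent(5, 0), class = "invalid_spec")
  expect_error(count_percent(11, 10), class = "invalid_spec")
})

test_that("the three cohort tables assemble with the study's row sets", {
  ch <- sample_cohort(cohort_spec(21, seed = 13))
  tb <- build_tables(ch)
  expect_named(tb, c("syrinx_comparison", "prepost_comparison",
                     "surgery_comparison"))
  pars <- c("sv_aqueduct", "sv_foramen", "sv_tonsils", "sv_cervical",
            "sv_vascular", "amp_venous", "correction_factor", "sv_syrinx")
  expect_setequal(tb$prepost_comparison$parameter, pars)
  expect_setequal(tb$surgery_comparison$parameter, pars)
  expect_setequal(tb$syrinx_comparison$parameter, setdiff(pars, "sv_syrinx"))
  expect_true(all(tb$prepost_comparison$p >= 0 & tb$prepost_comparison$p <= 1))
  # deterministic under a fixed cohort
  expect_identical(tb, build_tables(ch))
  # sv_syrinx rows only use the syrinx subgroup
  expect_equal(tb$prepost_comparison$n_a[
    tb$prepost_comparison$parameter == "sv_syrinx"], sum(ch$has_syrinx))

  # a cohort of identical subjects degenerates every paired row
  p0 <- chiari_cohort_defaults()
  p0$pre_sd[] <- 0; p0$post_sd[] <- 0; p0$post_mean <- p0$pre_mean
  ch0 <- sample_cohort(cohort_spec(6, params = p0, seed = 1))
  tb0 <- build_tables(ch0)
  expect_true(all(tb0$prepost_comparison$degenerate))
  expect_true(all(tb0$prepost_comparison$p == 1))
})

test_that("paired test holds its nominal type-I error on null cohorts", {
  # equal pre/post means, rho = 0.7: rejections at 5% should occur in
  # about 5% of simulated cohorts
  p <- chiari_cohort_defaults()[3, ]   # one parameter is enough
  p$post_mean <- p$pre_mean
  p$post_sd <- p$pre_sd
  set.seed(73)
  rej <- vapply(seq_len(1000), function(i) {
    ch <- sample_cohort(cohort_spec(21, params = p, rho = 0.7))
    paired_compare(ch$pre_sv_tonsils, ch$post_sv_tonsils)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})
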