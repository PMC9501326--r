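#!/usr/bin/env Rscript

# Step 3: cohort statistics.
#
# Builds the three study-style result tables from the sampled cohort
# (syrinx vs no-syrinx preoperative comparison, paired pre/post
# comparison, percent-change-by-surgery comparison) and then asks how
# reliably the cohort generator reproduces the significant pre/post
# effects across 200 resampled cohorts.

suppressPackageStartupMessages(library(pcmriflow))

path <- "results/cohort.csv"
if (!file.exists(path)) stop("run analysis/01_simulate.R first")
cohort <- utils::read.csv(path)

tables <- build_tables(cohort)
write_tables(tables, "results/tables")
for (nm in names(tables)) {
  message("== ", nm, " ==")
  tb <- tables[[nm]]
  tb$summary_a <- sprintf("%.3g +/- %.3g", tb$mean_a, tb$sd_a)
  tb$summary_b <- sprintf("%.3g +/- %.3g", tb$mean_b, tb$sd_b)
  print(tb[, c("parameter", "summary_a", "summary_b", "p", "test")],
        row.names = FALSE, digits = 3)
}

message("Seed sweep: Wilcoxon rejection rates over 200 cohorts (n = 21, rho = 0.7)")
params <- c("sv_aqueduct", "sv_foramen", "sv_tonsils", "sv_cervical",
            "sv_vascular", "amp_venous", "correction_factor", "sv_syrinx")
hits <- vapply(1:200, function(s) {
  ch <- sample_cohort(cohort_spec(21, rho = 0.7, seed = s))
  vapply(params, function(pp) {
    paired_compare(ch[[paste0("pre_", pp)]], ch[[paste0("post_", pp)]])$p < 0.05
  }, TRUE)
}, stats::setNames(logical(length(params)), params))
rates <- data.frame(parameter = params, rejection_rate = rowMeans(hits))
print(rates, row.names = FALSE)
utils::write.csv(rates, "results/rejection_rates.csv", row.names = FALSE)
message("Wrote results/tables/ and results/rejection_rates.csv")
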