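#!/usr/bin/env Rscript

# Step 4: figures.
#
# Flow curves of one synthetic subject: the CSF oscillations at each
# level, the arterial/jugular/corrected-venous curves, and the
# arteriovenous balance whose stroke volume is SVvasc.

suppressPackageStartupMessages({
  library(pcmriflow)
  library(ggplot2)
})

fig_dir <- "results/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

exam <- simulate_subject_exam(noise_frac = 0, seed = 20260104)
tc <- function(plane, roi) {
  r <- exam$planes[[plane]]$truth$rois[[roi]]
  cbind(as.data.frame(flow_curve(r$flow, 1)), structure = r$label,
        plane = plane)
}

csf <- rbind(tc("aqueduct", "csf"), tc("foramen", "csf"),
             tc("cervical", "csf"), tc("syrinx", "csf"),
             tc("foramen", "tissue"))
csf$where <- paste(csf$plane, csf$structure)
p1 <- ggplot(csf, aes(time_s, flow_mm3_s, colour = where)) +
  geom_line() +
  geom_hline(yintercept = 0, linetype = 3) +
  labs(x = "time in cardiac cycle (s)", y = expression(flow~(mm^3/s)),
       colour = NULL,
       title = "CSF and tonsil-tissue pulsatility over one cardiac cycle") +
  theme_minimal()
ggsave(file.path(fig_dir, "csf_curves.png"), p1, width = 8, height = 4.5,
       dpi = 130)

curves <- lapply(exam$planes$vessels$truth$rois, function(r)
  flow_curve(r$flow, 1, label = r$label))
cbfa <- arterial_flow(curves$carotid_left, curves$carotid_right,
                      curves$vertebral_left, curves$vertebral_right)
cbjf <- jugular_flow(curves$jugular_left, curves$jugular_right)
fct <- venous_correction_factor(cbfa, cbjf)
corrected <- corrected_venous_curve(cbjf, fct)
av <- arteriovenous_curve(cbfa, corrected)

blood <- do.call(rbind, lapply(list(cbfa, cbjf, corrected, av), function(cv)
  cbind(as.data.frame(cv), curve = cv$label)))
p2 <- ggplot(blood, aes(time_s, flow_mm3_s, colour = curve)) +
  geom_line() +
  geom_hline(yintercept = 0, linetype = 3) +
  labs(x = "time in cardiac cycle (s)", y = expression(flow~(mm^3/s)),
       colour = NULL,
       title = sprintf("Cerebral arteriovenous balance (correction factor %.2f)",
                       fct),
       subtitle = sprintf("AV stroke volume %.0f uL/CC; venous amplitude %.0f mm^3/s",
                          vascular_stroke_volume(av), peak_amplitude(cbjf))) +
  theme_minimal()
ggsave(file.path(fig_dir, "arteriovenous_balance.png"), p2, width = 8,
       height = 4.5, dpi = 130)

message("Wrote ", fig_dir)
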