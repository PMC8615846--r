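#!/usr/bin/env Rscript
# Person-specific HRF estimation: smoothed-FIR (16 TRs = 32 s window,
# GCV-selected roughness penalty) per subject per task input, against each
# ROI it may target. Writes the peak-delay table and compares it with the
# generating HRFs. Requires results/cohort/ from 01_simulate_cohort.R.

suppressPackageStartupMessages(library(pitconnect))

cohort <- "results/cohort"
out <- "results/hrf"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- read_true_network(file.path(cohort, "truth.json"))
rows <- list()
for (s in 1:11) {
  m <- read_subject_matrix(file.path(cohort, sprintf("matrix_sub%02d.tsv", s)),
                           tr_s = 2, subject_id = sprintf("sub%02d", s))
  h <- estimate_subject_hrfs(m, mode = "target")
  for (u in names(h)) {
    if (is.null(h[[u]])) next
    peaks <- vapply(h[[u]], hrf_peak_time, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      subject = s, input = u, roi = names(peaks), peak_s = unname(peaks),
      true_peak_s = truth$hrf_params$peak_delay[s])
  }
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "hrf_peaks.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# the informative estimate is the one from the ROI carrying the direct
# effect (left putamen, specific input)
lp <- tab[tab$input == "specific" & tab$roi == "putamen_L", ]
cat("specific-input HRF peak at left putamen, per subject:\n")
print(lp[, c("subject", "peak_s", "true_peak_s")], row.names = FALSE)
err <- abs(lp$peak_s - lp$true_peak_s)
cat(sprintf("peak error: median %.2f s, mean %.2f s (TR = 2 s)\n",
            median(err), mean(err)))
cat("At the generating effect size (direct weight 0.5 against unit dynamic\n")
cat("noise) single-ROI peak estimates are noisy; the connectivity search\n")
cat("uses the full estimated impulse-response shape only as a regressor,\n")
cat("which is far more forgiving than the peak summary.\n")
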