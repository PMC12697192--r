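#!/usr/bin/env Rscript
# Stage 1 — simulate the virtual follow-up cohort.
#
# Generates the default study: 26 THA patients (12 right / 14 left hips),
# CT scans at 0, 3, 12 and 24 months, 9 tantalum markers per bone segment,
# a duplicated 3-month visit with repositioning, two measurement methods
# (CT-based RSA and model-based RSA) with Table-2-scale noise, and
# piecewise-linear ground-truth migration. Writes the truth and plan
# tables under results/, and the full geometric scene bundle (marker CSVs,
# implant point clouds as PLY) under scratch/study/.

suppressPackageStartupMessages(library(ctrsa))

seed <- 20260928L
cfg <- study_config(seed = seed)
st <- generate_study(cfg)

dir.create("results", showWarnings = FALSE)
utils::write.csv(st$truth, "results/truth.csv", row.names = FALSE)
utils::write.csv(st$plan_table, "results/plan_table.csv", row.names = FALSE)
write_study(st, "scratch/study")

n_exams <- length(st$exams)
sides <- table(vapply(st$exams[!duplicated(vapply(st$exams,
  function(e) e$subject, ""))], function(e) e$side, ""))
cat(sprintf(
  "Simulated %d subjects (%d left, %d right), %d examinations (seed %d).\n",
  cfg$n_subjects, sides[["left"]], sides[["right"]], n_exams, seed))
cat("True 24-month medians (right-hip convention):\n")
t24 <- st$truth[st$truth$timepoint == 24, ]
print(round(tapply(t24$value, list(t24$segment, t24$dof), median), 3))
cat("Wrote results/truth.csv, results/plan_table.csv, scratch/study/.\n")
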