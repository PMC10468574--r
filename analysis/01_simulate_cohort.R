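#!/usr/bin/env Rscript

# Stage 1: build the simulated study cohort.
#
# Writes (a) the full 259-scan manifest mirroring the study structure
# (20 controls x 3 language tasks, 130 static-lesion scans, 69
# progressive-lesion scans), (b) the 30-scan analysis cohort used by the
# later stages, and (c) one fully materialised example scan (NIfTI run,
# BIDS-style events table, motion parameters, ground-truth sidecar) so the
# on-disk formats can be inspected with standard tools.

suppressPackageStartupMessages(library(fmridual))
seed <- 1L
dir.create("results", showWarnings = FALSE)

man_full <- make_cohort_manifest(20, 3, 130, 69, seed = seed)
write.table(man_full, "results/manifest_full.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("full manifest: %d scans (%d control, %d group1, %d group2)\n",
            nrow(man_full), sum(man_full$group == "control"),
            sum(man_full$group == "group1"), sum(man_full$group == "group2")))

# desk-scale analysis cohort: 10 controls, 10 + 10 patients, with 30% of
# patient scans carrying task-correlated motion
man <- make_cohort_manifest(5, 2, 10, 10, seed = seed,
                            p_task_motion = c(0, 0.3, 0.3))
write.table(man, "results/manifest_cohort.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("analysis cohort: %d scans, %d with task-correlated motion, %d lesioned\n",
            nrow(man), sum(man$task_motion), sum(man$lesion)))

# materialise the first control scan
p <- make_block_paradigm(6, 24, 24, 1.7, 3, 4)
truth <- truth_from_manifest_row(man[1, ], p)
sim <- simulate_scan(p, truth)
dir.create("results/example_scan", showWarnings = FALSE)
write_bold_nifti(sim$run, "results/example_scan/bold.nii.gz")
write_events_tsv(p, "results/example_scan/events.tsv")
write_motion_par(truth$motion_trace, "results/example_scan/motion.par")
write_truth_sidecar(truth, "results/example_scan/truth")
cat("example scan written under results/example_scan/ (",
    paste(dim(sim$run$data), collapse = " x "), ")\n")
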