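#!/usr/bin/env Rscript
# Stage 1: simulate the study material.
# Writes a paired imaging + outcome fixture (NIfTI phantoms with tumor
# masks, cohort CSV, ground-truth JSON) under results/pipeline/, plus a
# larger imaging-free cohort used by the statistical stages.

suppressPackageStartupMessages(library(meningrisk))

seed <- 20260926L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- run_config(output_dir = file.path(out, "pipeline"),
                  n_patients = 20L, seed = seed)
fix <- run_simulate(cfg)
cat(sprintf("wrote %d phantom pairs to %s\n", nrow(fix$cohort),
            cfg$image_dir))
cat(sprintf("  cystic: %d, high cluster prominence: %d, relapses: %d\n",
            sum(fix$cohort$cystic_component), sum(fix$cohort$high_cp_true),
            sum(fix$cohort$relapse)))

big <- simulate_cohort(cohort_sim_spec(n_patients = 500L, seed = seed))
write.csv(big, file.path(out, "cohort_large.csv"), row.names = FALSE)
s <- cohort_summary(big)
print(s)
cat(sprintf("large cohort written to %s (relapse %.1f%%)\n",
            file.path(out, "cohort_large.csv"), s$relapse_pct))
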