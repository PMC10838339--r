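#!/usr/bin/env Rscript
# Simulate the paired week-0/week-14 bulk RNA-seq cohort (34 etrolizumab,
# 8 placebo patients) with a latent T cell activation level and a planted
# week-14 cytotoxic reduction in etrolizumab-treated low-activation
# patients, and write counts, design sheet and ground truth.

library(itgact)

seed <- 1L
out <- "results/bulk"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_bulk_cohort(bulk_sim_params(seed = seed))
write_counts(sim$counts, file.path(out, "counts.tsv"))
write_design(sim$design, file.path(out, "design.csv"))
data.table::fwrite(sim$truth, file.path(out, "truth.tsv"), sep = "\t")

cat("Simulated", nrow(sim$truth), "patients (",
    sum(sim$truth$arm == "etrolizumab"), "etrolizumab /",
    sum(sim$truth$arm == "placebo"), "placebo ),",
    nrow(sim$design), "samples,", nrow(sim$counts), "genes\n")
cat("Latent activation: ", sum(sim$truth$activation == "high"), "high /",
    sum(sim$truth$activation == "low"), "low\n")
cat("Wrote", file.path(out, c("counts.tsv", "design.csv", "truth.tsv")), "\n")
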