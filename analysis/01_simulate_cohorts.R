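#!/usr/bin/env Rscript
# Stage 1: build the synthetic study cohorts.
#
# Three dairy-breed-like populations (71 + 71 + 77 individuals, drift F of
# 4-6%) genotyped on a chip-like map (4 autosomes x 400 SNPs, ~60 kb
# spacing), plus one Wright-Fisher cohort with known Ne = 100 for the
# LD-based effective-population-size analysis.  Everything is written as
# PLINK text files with the generating truth alongside, so the later stages
# run from files exactly as a real chip study would.

suppressPackageStartupMessages(library(popgenpipe))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

breeds <- simulate_balding_nichols(
  n_pops = 3, f = c(0.04, 0.05, 0.06),
  n_loci_per_chrom = 400, n_ind_per_pop = c(71, 71, 77),
  chromosomes = 1:4, seed = 2024)
write_plink(breeds$dataset, "results/data/breeds", "text")
write_plink(breeds$dataset, "results/data/breeds_bin", "binary")
write_sim_truth(breeds$truth, "results/data/breeds_truth.json")
print(breeds$dataset)
cat("expected pairwise FST (truth):\n")
print(round(breeds$truth$expected_theta, 3))

wf <- simulate_wright_fisher_ld(
  ne = 100, n_generations = 400, chrom_length_morgans = 1,
  n_loci = 600, sample_size = 70, n_chrom = 8, seed = 2025)
write_plink(wf$dataset, "results/data/wf_ne100", "text")
write_sim_truth(wf$truth, "results/data/wf_ne100_truth.json")
print(wf$dataset)
cat("true Ne:", wf$truth$ne, "over", wf$truth$n_generations, "generations\n")
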