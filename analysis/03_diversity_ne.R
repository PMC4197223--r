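#!/usr/bin/env Rscript
# Stage 3: diversity indices and LD-based effective population size.
#
# Diversity indices (MAF, Ho, He, individual F) are computed per breed on
# the 50/10/1.5 VIF-pruned marker set.  Ne comes from the Wright-Fisher
# cohort with known truth: sliding 1 Mb / 50 kb LD bins are inverted
# through Sved's relation Ne = (1/4c)(1/r2 - 1), read at the bin probing 50
# generations ago (1 cM = 1 Mb), with the 1/(2n) sample-size correction.

suppressPackageStartupMessages(library(popgenpipe))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

ds <- read_plink("results/data/breeds", "text")
rows <- list()
for (pop in unique(ds$samples$population)) {
  sub <- subset_dataset(ds, samples = ds$samples$population == pop)
  q <- apply_qc(sub, qc_thresholds())
  keep <- vif_prune(q$dataset, 50, 10, 1.5)
  pruned <- subset_dataset(q$dataset, variants = match(keep, q$dataset$variants$id))
  dv <- snp_diversity(pruned)$summary
  fi <- individual_inbreeding(pruned)
  rows[[pop]] <- data.frame(population = pop, n_snps = length(keep),
                            maf = dv$mean_maf, maf_sd = dv$sd_maf,
                            ho = dv$mean_ho, ho_sd = dv$sd_ho,
                            he = dv$mean_he, he_sd = dv$sd_he,
                            f = mean(fi$f), f_sd = sd(fi$f))
}
tab <- do.call(rbind, rows)
print(tab, digits = 3, row.names = FALSE)
write.table(format(tab, digits = 6), "results/tables/diversity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

wf <- read_plink("results/data/wf_ne100", "text")
truth <- jsonlite::read_json("results/data/wf_ne100_truth.json")
q <- apply_qc(wf, qc_thresholds(min_call = 1, min_maf = 0.05, min_hwe_p = 0))
pw <- pairwise_ld(q$dataset, 5e7)
sl <- sliding_ld_bins(pw, width_bp = 1e6, step_bp = 5e4)
traj <- ne_trajectory(sl, bp_per_morgan = truth$bp_per_morgan,
                      sample_size = nrow(wf$dosage), correct_sample_size = TRUE)
write.table(traj, "results/tables/ne_trajectory.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
i50 <- which.min(abs(traj$generations_ago - 50))
cat(sprintf("\nNe at t = %d generations ago: %.1f (truth %d, %d pairs in bin)\n",
            traj$generations_ago[i50], traj$ne[i50], truth$ne, sl$n_pairs[i50]))
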