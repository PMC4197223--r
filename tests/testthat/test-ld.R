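test_that("EM haplotype frequencies resolve unambiguous and factorising tables exactly", {
  cnt <- matrix(0, 3, 3)            # rows: dosage locus 1; cols: dosage locus 2
  cnt[3, 3] <- 2; cnt[1, 1] <- 2    # 2x (hom B, hom B), 2x (hom A, hom A)
  h <- em_haplotype_frequencies(cnt)
  expect_equal(c(h$pAB, h$pAb, h$paB, h$pab), c(0.5, 0, 0, 0.5))
  expect_equal(r_squared(h)$r2, 1)
  cnt2 <- matrix(0, 3, 3)
  cnt2[3, 3] <- 1; cnt2[3, 1] <- 1; cnt2[1, 3] <- 1; cnt2[1, 1] <- 1
  h2 <- em_haplotype_frequencies(cnt2)
  expect_equal(c(h2$pAB, h2$pAb, h2$paB, h2$pab), rep(0.25, 4))
  expect_equal(r_squared(h2)$r2, 0)
})

test_that("EM agrees with the likelihood grid-search oracle and its trace is monotone", {
  # the mixed table with double heterozygotes and hom-het rows
  cnt <- matrix(c(1, 0, 0, 0, 2, 2, 0, 0, 3), 3, 3)  # includes 2x (het, het)
  h <- em_haplotype_frequencies(cnt)
  expect_true(all(diff(h$trace) >= -1e-9))
  r2_oracle <- grid_r2_oracle(as.numeric(t(cnt)))
  expect_lt(abs(r_squared(h)$r2 - r2_oracle), 1e-3)
  set.seed(21)
  for (i in 1:25) {
    N <- random_count_table(sample(8:40, 1))
    h <- em_haplotype_frequencies(N)
    expect_true(all(diff(h$trace) >= -1e-9))
    expect_lt(abs(r_squared(h)$r2 - grid_r2_oracle(N)), 1e-3)
  }
})

test_that("r2 follows the definitional arithmetic and flags fixed alleles as undefined", {
  expect_equal(r_squared(list(pAB = .4, pAb = .1, paB = .1, pab = .4))$r2, 0.36)
  expect_true(is.na(r_squared(list(pAB = .5, pAb = .5, paB = 0, pab = 0))$r2))
  # invariance to allele-label swaps at either locus and to locus swap
  set.seed(3)
  for (i in 1:20) {
    N <- matrix(random_count_table(30), 3, 3, byrow = TRUE)
    r <- r_squared(em_haplotype_frequencies(N))$r2
    r_flip1 <- r_squared(em_haplotype_frequencies(N[3:1, ]))$r2
    r_flip2 <- r_squared(em_haplotype_frequencies(N[, 3:1]))$r2
    r_swap <- r_squared(em_haplotype_frequencies(t(N)))$r2
    expect_lt(abs(r_flip1 - r), 1e-6)
    expect_lt(abs(r_flip2 - r), 1e-6)
    expect_lt(abs(r_swap - r), 1e-6)
  }
})

test_that("adjacent-pair summaries reproduce spacing, perfect LD, and a brute-force loop", {
  # spacing: 3 SNPs 60 kb apart
  set.seed(2)
  dosage <- matrix(rbinom(60, 2, 0.5), 20, 3)
  ds <- make_ds(dosage, bp = c(0, 6e4, 12e4))
  adj <- adjacent_ld_summary(ds)
  expect_equal(adj$genome$mean_spacing_bp, 6e4)
  # perfect-LD chromosome: duplicated column
  base <- rbinom(30, 2, 0.5)
  dsp <- make_ds(matrix(base, 30, 4), bp = (1:4) * 1e4)
  adj2 <- adjacent_ld_summary(dsp)
  expect_equal(adj2$genome$mean_r2, 1)
  expect_equal(adj2$genome$sd_r2, 0)
  # 200-SNP chromosome equals an independent per-pair loop
  sim <- simulate_wright_fisher_ld(ne = 50, n_generations = 60, n_loci = 220,
                                   sample_size = 40, seed = 12)
  q <- apply_qc(sim$dataset, qc_thresholds(min_call = 1, min_maf = 0.05, min_hwe_p = 0))
  adj3 <- adjacent_ld_summary(q$dataset)
  d <- q$dataset$dosage
  loop_r2 <- vapply(seq_len(ncol(d) - 1), function(j) {
    cnt <- table(factor(d[, j], 0:2), factor(d[, j + 1], 0:2))
    r_squared(em_haplotype_frequencies(unclass(cnt)))$r2
  }, numeric(1))
  # per-pair agreement up to EM convergence-path differences
  expect_lt(max(abs(adj3$pairs$r2 - loop_r2), na.rm = TRUE), 1e-4)
  expect_lt(abs(adj3$genome$mean_r2 - mean(loop_r2, na.rm = TRUE)), 1e-5)
})

test_that("pairwise scans respect the distance cap and chromosome boundaries", {
  set.seed(9)
  dosage <- matrix(rbinom(90, 2, 0.5), 30, 3)
  ds <- make_ds(dosage, bp = c(1, 30e6, 80e6))
  rec <- pairwise_ld(ds, 5e7)
  expect_equal(nrow(rec), 2)                      # the 79 Mb pair is excluded
  expect_setequal(rec$distance_bp, c(30e6 - 1, 50e6))
  # n SNPs, no cap: n(n-1)/2 records, none crossing chromosomes
  n <- 12
  ds2 <- make_ds(matrix(rbinom(20 * 2 * n, 2, 0.5), 20, 2 * n),
                 chrom = rep(c("1", "2"), each = n))
  rec2 <- pairwise_ld(ds2, Inf)
  expect_equal(nrow(rec2), 2 * n * (n - 1) / 2)
  expect_true(all(rec2$chrom %in% c("1", "2")))
})

test_that("decay bins average r2 arithmetically and LD decays on recombining data", {
  rec <- data.frame(chrom = "1", id_a = c("a", "b"), id_b = c("b", "c"),
                    distance_bp = c(1e4, 4e4), r2 = c(0.4, 0.2), dprime = NA)
  dec <- ld_decay_profile(rec)
  expect_equal(dec$mean_r2[1], 0.3)
  expect_equal(dec$n_pairs[1], 2)
  expect_true(all(dec$n_pairs[-1] == 0))
  expect_error(ld_decay_profile(rec, c(0, 0, 1)), "strictly increasing")
  # a single global bin reduces to the overall mean
  one <- ld_decay_profile(rec, c(0, Inf))
  expect_equal(one$mean_r2, 0.3)
  # short-distance LD exceeds long-distance LD on Wright-Fisher data
  sim <- simulate_wright_fisher_ld(ne = 60, n_generations = 150, n_loci = 250,
                                   chrom_length_morgans = 0.5,
                                   sample_size = 50, seed = 14)
  q <- apply_qc(sim$dataset, qc_thresholds(min_call = 1, min_maf = 0.05, min_hwe_p = 0))
  pw <- pairwise_ld(q$dataset, Inf)
  dec2 <- ld_decay_profile(pw, c(0, 2e6, 2e7, Inf))
  expect_gt(dec2$mean_r2[1], dec2$mean_r2[3])
})

test_that("sliding bins match a brute-force window loop and track membership", {
  rec1 <- data.frame(distance_bp = 5e5, r2 = 0.3)
  sl1 <- sliding_ld_bins(rec1, width_bp = 1e6, step_bp = 5e4)
  covered <- abs(sl1$center_bp - 5e5) <= 5e5
  expect_true(all(sl1$n_pairs[covered] == 1))
  expect_true(all(is.na(sl1$mean_r2[!covered])))
  set.seed(17)
  rec <- data.frame(distance_bp = runif(1000, 0, 5e6), r2 = runif(1000))
  sl <- sliding_ld_bins(rec, 1e6, 5e4)
  for (i in sample(nrow(sl), 25)) {
    inw <- abs(rec$distance_bp - sl$center_bp[i]) <= 5e5
    expect_equal(sl$n_pairs[i], sum(inw))
    if (any(inw)) expect_equal(sl$mean_r2[i], mean(rec$r2[inw]), tolerance = 1e-12)
  }
})

test_that("VIF pruning removes collinear SNPs, keeps independent ones, and matches a greedy oracle", {
  set.seed(23)
  base <- rbinom(40, 2, 0.5)
  dup <- make_ds(matrix(base, 40, 5), bp = (1:5) * 1e3)
  expect_length(vif_prune(dup, 6, 2, 2), 1)       # one window: perfect collinearity
  indep <- make_ds(matrix(rbinom(100 * 10, 2, 0.5), 100, 10))
  expect_length(vif_prune(indep, 5, 2, 2), 10)
  # 20-SNP correlated structure vs an independent single-window greedy oracle
  sim <- simulate_wright_fisher_ld(ne = 50, n_generations = 50, n_loci = 24,
                                   chrom_length_morgans = 0.05,
                                   sample_size = 40, seed = 19)
  q <- apply_qc(sim$dataset, qc_thresholds(min_call = 1, min_maf = 0.05, min_hwe_p = 0))
  ds <- q$dataset
  L <- ncol(ds$dosage)
  got <- vif_prune(ds, window_snps = L + 1, shift_snps = 1, vif_threshold = 1.5)
  X <- scale(ds$dosage, scale = FALSE)
  keep <- rep(TRUE, L)
  repeat {
    act <- which(keep)
    if (length(act) < 2) break
    vifs <- vapply(act, function(j) {
      fit <- stats::lm(X[, j] ~ X[, setdiff(act, j), drop = FALSE] - 1)
      r2 <- 1 - sum(residuals(fit)^2) / sum(X[, j]^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    if (max(vifs) <= 1.5) break
    worst <- act[vifs == max(vifs)]
    keep[worst[length(worst)]] <- FALSE
  }
  expect_identical(got, ds$variants$id[keep])
})
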