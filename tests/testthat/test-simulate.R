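test_that("generators are seed-reproducible and serialize their truth", {
  a <- simulate_balding_nichols(2, 0.05, 40, 20, 1:2, seed = 7)
  b <- simulate_balding_nichols(2, 0.05, 40, 20, 1:2, seed = 7)
  expect_identical(a$dataset$dosage, b$dataset$dosage)
  expect_identical(a$truth$pop_freqs, b$truth$pop_freqs)
  c_ <- simulate_balding_nichols(2, 0.05, 40, 20, 1:2, seed = 8)
  expect_false(identical(a$dataset$dosage, c_$dataset$dosage))
  w1 <- simulate_wright_fisher_ld(ne = 20, n_generations = 15, n_loci = 30,
                                  sample_size = 10, seed = 3)
  w2 <- simulate_wright_fisher_ld(ne = 20, n_generations = 15, n_loci = 30,
                                  sample_size = 10, seed = 3)
  expect_identical(w1$dataset$dosage, w2$dataset$dosage)
  td <- withr::local_tempdir()
  write_sim_truth(a$truth, file.path(td, "truth.json"))
  back <- jsonlite::read_json(file.path(td, "truth.json"), simplifyVector = TRUE)
  expect_equal(back$f, a$truth$f)
  expect_equal(back$seed, 7)
  expect_equal(unname(back$expected_theta), unname(a$truth$expected_theta))
})

test_that("Balding-Nichols drift vanishes as F goes to zero and matches theta truth", {
  low <- simulate_balding_nichols(2, 1e-6, 200, 10, 1, seed = 9)
  expect_lt(max(abs(t(low$truth$pop_freqs) - low$truth$p_anc)), 0.01)
  sim <- simulate_balding_nichols(2, 0.05, 1500, 70, 1:2, seed = 10)
  parts <- split_by_population(sim$dataset)
  th <- wc_fst_pair(parts[[1]], parts[[2]])$theta
  expect_lt(abs(th - sim$truth$expected_theta[1, 2]), 0.015)
})

test_that("admixed genomes reduce to sources for one-hot Q and mix frequencies half-half", {
  set.seed(15)
  P <- rbind(runif(300, 0.1, 0.9), runif(300, 0.1, 0.9))
  Q1 <- cbind(rep(1, 200), rep(0, 200))
  one <- simulate_admixed(Q1, P, seed = 5)
  fr <- colMeans(one$dataset$dosage) / 2
  expect_lt(mean(abs(fr - P[1, ])), 0.02)
  Qh <- matrix(0.5, 200, 2)
  half <- simulate_admixed(Qh, P, seed = 6)
  fh <- colMeans(half$dataset$dosage) / 2
  expect_lt(mean(abs(fh - colMeans(P))), 0.02)
  expect_error(simulate_admixed(cbind(1, 1), P, seed = 1), "rowSums")
})

test_that("without recombination LD shows no decay with distance", {
  sim <- simulate_wright_fisher_ld(ne = 80, n_generations = 160, n_loci = 80,
                                   chrom_length_morgans = 1e-3,
                                   sample_size = 60, seed = 22)
  q <- apply_qc(sim$dataset, qc_thresholds(min_call = 1, min_maf = 0.05, min_hwe_p = 0))
  pw <- pairwise_ld(q$dataset, Inf)
  near <- pw$r2[pw$distance_bp <= stats::median(pw$distance_bp)]
  far <- pw$r2[pw$distance_bp > stats::median(pw$distance_bp)]
  # a ~0.1 cM chromosome is effectively unlinked from recombination's view:
  # near and far pairs carry the same drift LD
  expect_lt(abs(mean(near, na.rm = TRUE) - mean(far, na.rm = TRUE)), 0.08)
  expect_gt(mean(pw$r2, na.rm = TRUE), 0.05)      # drift LD clearly present
})

test_that("equilibrium r2 at known recombination matches Sved's expectation with sampling inflation", {
  sim <- simulate_wright_fisher_ld(ne = 100, n_generations = 400, n_loci = 600,
                                   chrom_length_morgans = 1, sample_size = 70,
                                   n_chrom = 2, seed = 1)
  q <- apply_qc(sim$dataset, qc_thresholds(min_call = 1, min_maf = 0.05, min_hwe_p = 0))
  pw <- pairwise_ld(q$dataset, Inf)
  sel <- pw$distance_bp >= 5e5 & pw$distance_bp <= 1.5e6   # c ~ 0.01 M
  expect_gt(sum(sel), 100)
  expected <- 1 / (1 + 4 * 100 * 0.01) + 1 / (2 * 70)
  expect_equal(mean(pw$r2[sel], na.rm = TRUE), expected, tolerance = 0.25)
})

test_that("unlinked equilibrium r2 reflects 1/(2n) sampling noise, not zero", {
  sim <- simulate_balding_nichols(1, 0.01, n_loci_per_chrom = 60,
                                  n_ind_per_pop = 70, chromosomes = 1:2, seed = 25)
  pw <- pairwise_ld(sim$dataset, Inf)
  m <- mean(pw$r2, na.rm = TRUE)
  expect_gt(m, 0.2 / (2 * 70))                    # clearly above zero
  expect_lt(m, 5 / (2 * 70))                      # and on the 1/(2n) scale
})
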