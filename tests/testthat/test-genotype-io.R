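test_that("PED/MAP reading codes dosage as copies of the B allele and maps '0 0' to missing", {
  td <- withr::local_tempdir()
  writeLines(c("1\ts1\t0\t100\t0.0001", "1\ts2\t0\t200\t0.0002", "1\ts3\t0\t300\t0.0003"),
             file.path(td, "x.map"))
  expect_error(read_plink(file.path(td, "x"), "text"), "columns")
  writeLines(c("1 s1 0 100", "1 s2 0 200", "1 s3 0 300"), file.path(td, "x.map"))
  writeLines(c("fam1 ind1 0 0 0 -9 A A A A G G",
               "fam1 ind2 0 0 0 -9 A A A G 0 0"), file.path(td, "x.ped"))
  ds <- read_plink(file.path(td, "x"), "text")
  # s1 monomorphic A; s2 alleles A<G so B=G; s3 only G observed
  expect_equal(unname(ds$dosage[, 2]), c(0L, 1L))
  expect_equal(ds$variants$alleleB[2], "G")
  expect_true(is.na(ds$dosage[2, 3]))
  expect_equal(ds$dosage[1, 3], 2L)             # B allele = the observed G
  expect_equal(sum(!is.na(ds$dosage[, 3])), 1)  # missing excluded from counts
})

test_that("malformed PED lines and >2 alleles are hard errors naming the problem", {
  td <- withr::local_tempdir()
  writeLines(c("1 s1 0 100"), file.path(td, "y.map"))
  writeLines(c("f i1 0 0 0 -9 A A", "f i2 0 0 0 -9 A"), file.path(td, "y.ped"))
  expect_error(read_plink(file.path(td, "y"), "text"), "line 2")
  writeLines(c("f i1 0 0 0 -9 A C", "f i2 0 0 0 -9 A G"), file.path(td, "y.ped"))
  expect_error(read_plink(file.path(td, "y"), "text"), "3 alleles")
})

test_that("write/read roundtrips are the identity for both dialects on a 50-sample dataset", {
  sim <- simulate_balding_nichols(2, 0.05, n_loci_per_chrom = 25,
                                  n_ind_per_pop = 25, chromosomes = 1:2, seed = 4)
  ds <- sim$dataset
  ds$dosage[3, 7] <- NA_integer_
  ds$dosage[10, 1] <- NA_integer_
  td <- withr::local_tempdir()
  for (fmt in c("text", "binary")) {
    write_plink(ds, file.path(td, fmt), fmt)
    back <- read_plink(file.path(td, fmt), fmt)
    expect_identical(unname(back$dosage), unname(ds$dosage))
    expect_equal(back$variants$id, ds$variants$id)
    expect_equal(back$samples$id, ds$samples$id)
  }
  # empty dataset still writes valid files
  empty <- subset_dataset(ds, variants = integer(0))
  write_plink(empty, file.path(td, "empty"), "text")
  back <- read_plink(file.path(td, "empty"), "text")
  expect_equal(ncol(back$dosage), 0)
  expect_equal(nrow(back$dosage), 50)
})

test_that("binary files carry the magic bytes and the standard SNP-major 2-bit encoding", {
  # hand-encoded reference: 2 samples, dosages (0, 2) -> codes 00 and 11 ->
  # byte 0b00001100 = 0x0c after the 6c 1b 01 magic
  ds <- make_ds(matrix(c(0L, 2L), 2, 1))
  td <- withr::local_tempdir()
  write_plink(ds, file.path(td, "b"), "binary")
  raw <- readBin(file.path(td, "b.bed"), "raw", 10)
  expect_identical(raw, as.raw(c(0x6c, 0x1b, 0x01, 0x0c)))
  # truncated payload is a hard error
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), file.path(td, "b.bed"))
  expect_error(read_plink(file.path(td, "b"), "binary"), "data bytes")
})

test_that("flipping which allele is B flips dosage and leaves r2, He and FST unchanged", {
  sim <- simulate_balding_nichols(2, 0.08, n_loci_per_chrom = 30,
                                  n_ind_per_pop = 30, chromosomes = 1, seed = 6)
  ds <- sim$dataset
  flipped <- ds
  flipped$dosage <- 2L - ds$dosage
  flipped$variants[, c("alleleA", "alleleB")] <- ds$variants[, c("alleleB", "alleleA")]
  expect_equal(adjacent_ld_summary(flipped)$genome$mean_r2,
               adjacent_ld_summary(ds)$genome$mean_r2)
  expect_equal(snp_diversity(flipped)$per_snp$he, snp_diversity(ds)$per_snp$he)
  pa <- split_by_population(ds); pf <- split_by_population(flipped)
  expect_equal(wc_fst_pair(pf[[1]], pf[[2]])$theta,
               wc_fst_pair(pa[[1]], pa[[2]])$theta)
})
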