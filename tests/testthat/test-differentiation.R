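test_that("Weir-Cockerham theta is exact on fixed differences and a hand oracle", {
  expect_equal(wc_fst_pair(matrix(0L, 10, 1), matrix(2L, 10, 1))$theta, 1)
  # single locus, pop1 (AA=6, Aa=3, aa=1) vs pop2 (AA=1, Aa=3, aa=6)
  d1 <- matrix(c(rep(0L, 6), rep(1L, 3), rep(2L, 1)), ncol = 1)
  d2 <- matrix(c(rep(0L, 1), rep(1L, 3), rep(2L, 6)), ncol = 1)
  got <- wc_fst_pair(d1, d2)$theta
  oracle <- wc_oracle_single_locus(10, 0.25, 0.3, 10, 0.75, 0.3)
  expect_equal(got, oracle, tolerance = 1e-12)
  # no differentiation: identical genotype counts over simulated loci
  set.seed(51)
  pool <- matrix(rbinom(120 * 100, 2, rep(runif(100, 0.2, 0.8), each = 120)), 120, 100)
  w0 <- wc_fst_pair(pool[1:60, ], pool[1:60, ][sample(60), ])
  expect_lt(abs(w0$theta), 0.02)                  # literally identical counts
  w1 <- wc_fst_pair(pool[1:60, ], pool[61:120, ]) # same source population
  expect_lt(abs(w1$theta), 0.02)
})

test_that("theta is invariant to allele relabelling and population order", {
  set.seed(52)
  d1 <- matrix(rbinom(60, 2, 0.3), 30, 2)
  d2 <- matrix(rbinom(60, 2, 0.6), 30, 2)
  w <- wc_fst_pair(d1, d2)$theta
  expect_equal(wc_fst_pair(2L - d1, 2L - d2)$theta, w, tolerance = 1e-12)
  expect_equal(wc_fst_pair(d2, d1)$theta, w, tolerance = 1e-12)
  expect_error(wc_fst_pair(matrix(0L, 5, 1), matrix(0L, 5, 1)), "no usable locus")
})

test_that("the FST matrix covers every unordered pair and recovers drift truth additively", {
  sim <- simulate_balding_nichols(3, f = c(0.02, 0.05, 0.10),
                                  n_loci_per_chrom = 2500, n_ind_per_pop = 70,
                                  chromosomes = 1:2, seed = 28)
  fm <- fst_matrix(sim$dataset)
  expect_equal(fm$fst, t(fm$fst))
  expect_equal(diag(fm$fst), rep(0, 3), ignore_attr = TRUE)
  expect_equal(sum(fm$fst[upper.tri(fm$fst)] != 0), 3)
  expect_lt(max(abs(fm$fst[upper.tri(fm$fst)] -
                      sim$truth$expected_theta[upper.tri(fm$fst)])), 0.012)
})

test_that("NeighborNet reproduces additive trees and crafted circular split systems exactly", {
  lab <- c("A", "B", "C", "D")
  D <- matrix(3, 4, 4, dimnames = list(lab, lab))
  D["A", "B"] <- D["B", "A"] <- 2
  D["C", "D"] <- D["D", "C"] <- 2
  diag(D) <- 0
  net <- neighbor_net(D)
  expect_equal(length(net$splits), 5)             # 4 trivial + the cherry split
  expect_lt(net$residual, 1e-9)
  sizes <- lengths(net$splits)
  big <- net$splits[sizes == 2]
  expect_length(big, 1)
  expect_setequal(lab[big[[1]]], c("A", "B"))     # or equivalently {C,D}
  expect_equal(net$weights[sizes == 2], 1)
  expect_equal(unname(trivial_split_weights(net)), rep(1, 4))
  # 5-taxon circularly decomposable distance: exact split recovery
  set.seed(61)
  D5 <- random_circular_distance(5, n_extra_splits = 3)
  net5 <- neighbor_net(D5)
  expect_lt(net5$residual, 1e-9)
  path <- matrix(0, 5, 5)
  for (s in seq_along(net5$splits)) {
    side <- net5$splits[[s]]
    sep <- outer(seq_len(5) %in% side, seq_len(5) %in% side, "!=")
    path <- path + net5$weights[s] * sep
  }
  expect_equal(path, D5, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("NEXUS export writes the documented dialect and roundtrips", {
  lab <- c("A", "B", "C", "D")
  D <- matrix(3, 4, 4, dimnames = list(lab, lab))
  D["A", "B"] <- D["B", "A"] <- 2; D["C", "D"] <- D["D", "C"] <- 2; diag(D) <- 0
  net <- neighbor_net(D)
  td <- withr::local_tempdir()
  path <- file.path(td, "net.nex")
  write_nexus(net, path)
  lines <- readLines(path)
  expect_equal(lines[1], "#NEXUS")
  expect_true("BEGIN Taxa;" %in% lines)
  expect_true("DIMENSIONS ntax=4;" %in% lines)
  expect_true(any(grepl("^CYCLE ", lines)))
  expect_true("DIMENSIONS ntax=4 nsplits=5;" %in% lines)
  back <- read_nexus_splits(path)
  expect_equal(back$labels, net$labels)
  expect_equal(back$order, net$order)
  expect_equal(back$splits, net$splits)
  expect_equal(back$weights, net$weights, tolerance = 1e-12)
  # an all-trivial (star) network still writes a valid, parseable file
  star <- neighbor_net(matrix(1, 4, 4) - diag(4))
  write_nexus(star, path)
  expect_equal(length(read_nexus_splits(path)$splits), length(star$splits))
})
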