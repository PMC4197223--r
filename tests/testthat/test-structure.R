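test_that("IBS allele sharing matches hand counts and handles missingness", {
  ds <- make_ds(rbind(c(0L, 2L, 1L, 1L), c(0L, 2L, 1L, 1L)))
  ident <- ibs_distance_matrix(ds)
  expect_equal(ident$as[1, 2], 1)
  expect_equal(ident$d[1, 2], 0)
  ds2 <- make_ds(rbind(c(0L, 2L, 1L, 1L), c(2L, 0L, 1L, 2L)))
  out <- ibs_distance_matrix(ds2)
  expect_equal(out$as[1, 2], 0.375)               # IBS (0,0,2,1) over 4 loci
  expect_equal(out$d[1, 2], 0.625)
  ds3 <- make_ds(rbind(c(0L, 2L, 1L, NA), c(2L, 0L, 1L, 2L)))
  out3 <- ibs_distance_matrix(ds3)
  expect_equal(out3$n_loci[1, 2], 3L)
  expect_equal(out3$as[1, 2], 1 / 3)              # IBS (0,0,2) over 3 loci
  ds4 <- make_ds(rbind(c(NA, 0L), c(1L, NA)))
  expect_error(ibs_distance_matrix(ds4), "share no typed locus")
})

test_that("classical MDS recovers 1-D and 2-D configurations and equals PCA", {
  # collinear points at 0, 3, 7
  D <- as.matrix(dist(c(0, 3, 7)))
  expect_warning(m <- classical_mds(D, 2), "1 positive eigenvalue")
  expect_equal(dim(m$points), c(3, 1))            # second eigenvalue collapses
  expect_equal(as.matrix(dist(m$points)), D, ignore_attr = TRUE, tolerance = 1e-9)
  set.seed(13)
  pts <- matrix(rnorm(16), 8, 2)
  D2 <- as.matrix(dist(pts))
  m2 <- classical_mds(D2, 2)
  expect_equal(as.matrix(dist(m2$points)), D2, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(sum(m2$eig > 1e-9), 2)
  expect_length(m2$negative_eig, 0)
  # MDS on Euclidean row distances == PCA scores of the centred data
  X <- matrix(rnorm(60), 10, 6)
  mds_pts <- classical_mds(as.matrix(dist(X)), 3)$points
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:3) {
    expect_equal(abs(mds_pts[, j]), abs(pca$x[, j]), ignore_attr = TRUE,
                 tolerance = 1e-8)
  }
  # deterministic sign convention: largest-magnitude loading positive
  expect_true(all(apply(m2$points, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("discriminant panels require fixation in one breed and MAF > 0.25 in the other", {
  # three loci with exact MAF pairs: (0, 0.30) selected; (0.30, 0.30) not;
  # (0, 0.20) not (the bound is strict)
  a <- cbind(rep(0L, 20), c(rep(1L, 12), rep(0L, 8)), rep(0L, 20))
  b <- cbind(c(rep(1L, 12), rep(0L, 8)), c(rep(1L, 12), rep(0L, 8)),
             c(rep(1L, 8), rep(0L, 12)))
  ds <- make_ds(rbind(a, b), population = rep(c("A", "B"), each = 20))
  sel <- select_discriminant_snps(ds, maf_min = 0.25)
  expect_equal(sel$panel, "s001")                 # MAF (0, 0.30)
  expect_equal(sel$pairs$pop_fixed, "A")
})

test_that("admixture EM has the degenerate K=1 closed form and a monotone likelihood", {
  set.seed(33)
  G <- matrix(rbinom(40 * 60, 2, 0.4), 40, 60)
  G[sample(length(G), 50)] <- NA
  f1 <- admixture_fit(G, 1)
  p <- colSums(G, na.rm = TRUE) / (2 * colSums(!is.na(G)))
  expect_equal(as.vector(f1$P), pmin(pmax(p, 1e-6), 1 - 1e-6))
  expect_equal(f1$Q, matrix(1, 40, 1))
  f2 <- admixture_fit(G, 2, seed = 5, n_starts = 2, max_iter = 300)
  expect_true(all(diff(f2$trace) >= -1e-8))
  expect_equal(rowSums(f2$Q), rep(1, 40), tolerance = 1e-8)
  expect_true(all(f2$P >= 1e-6 & f2$P <= 1 - 1e-6))
  expect_error(admixture_fit(G, 41), "exceed")
  # label-permutation invariance of the likelihood
  miss <- is.na(G); G0 <- G; G0[miss] <- 0
  ll <- function(Q, P) {
    R <- pmin(pmax(Q %*% P, 1e-12), 1 - 1e-12)
    sum((G0 * log(R) + (2 - G0) * (1 - miss) * log(1 - R))[!miss])
  }
  expect_equal(ll(f2$Q[, 2:1], f2$P[2:1, ]), ll(f2$Q, f2$P))
})

test_that("admixture recovers two-population ancestry after label alignment", {
  src <- simulate_balding_nichols(2, 0.15, n_loci_per_chrom = 150,
                                  n_ind_per_pop = 2, chromosomes = 1:2, seed = 3)
  Qt <- cbind(rep(c(1, 0), c(30, 30)), rep(c(0, 1), c(30, 30)))
  adm <- simulate_admixed(Qt, src$truth$pop_freqs, seed = 8)
  fit <- admixture_fit(adm$dataset, 2, seed = 1, max_iter = 700)
  expect_lt(align_q(fit$Q, Qt)$mae, 0.1)
})

test_that("cross-validation folds partition the non-missing cells exactly once", {
  set.seed(44)
  G <- matrix(rbinom(30 * 50, 2, 0.5), 30, 50)
  G[sample(length(G), 60)] <- NA
  cv <- admixture_cv(G, k_range = 1:2, folds = 5, seed = 2, max_iter = 150)
  expect_length(cv$fold_of, sum(!is.na(G)))
  expect_true(all(table(cv$fold_of) >= floor(sum(!is.na(G)) / 5)))
  expect_setequal(unique(cv$fold_of), 1:5)
})

test_that("cross-validated K finds one cluster in one population and two in two", {
  one <- simulate_balding_nichols(1, 0.05, n_loci_per_chrom = 100,
                                  n_ind_per_pop = 40, chromosomes = 1:2, seed = 2)
  cv1 <- admixture_cv(one$dataset, 1:3, seed = 1, max_iter = 500)
  expect_equal(cv1$best_k, 1)
  two <- simulate_balding_nichols(2, 0.2, n_loci_per_chrom = 100,
                                  n_ind_per_pop = 30, chromosomes = 1:2, seed = 1)
  cv2 <- admixture_cv(two$dataset, 1:3, seed = 1, max_iter = 500)
  expect_equal(cv2$best_k, 2)
})
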