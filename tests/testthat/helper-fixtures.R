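# Shared fixture builders and independent oracles for the test suite.

# Quick dataset constructor around a dosage matrix.
make_ds <- function(dosage, chrom = "1", bp = NULL, population = NULL,
                    alleleA = "A", alleleB = "B") {
  dosage <- as.matrix(dosage)
  L <- ncol(dosage)
  n <- nrow(dosage)
  chrom <- rep_len(chrom, L)
  if (is.null(bp)) bp <- seq_len(L) * 1000
  v <- data.frame(chrom = chrom, id = sprintf("s%03d", seq_len(L)),
                  cm = bp / 1e6, bp = bp,
                  alleleA = rep_len(alleleA, L), alleleB = rep_len(alleleB, L),
                  stringsAsFactors = FALSE)
  s <- data.frame(family = if (is.null(population)) "f" else population,
                  id = sprintf("i%03d", seq_len(n)),
                  stringsAsFactors = FALSE)
  if (!is.null(population)) s$population <- population
  genotype_dataset(dosage, v, s)
}

# Independent HWE oracle: direct enumeration of all genotype configurations
# compatible with the observed allele counts, probabilities from the plain
# multinomial mass (no log-space tricks, no shared code with the package).
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  hets <- seq(min(n_a, 2 * n - n_a) %% 2, min(n_a, 2 * n - n_a), by = 2)
  mass <- sapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- n - aa - h
    factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) * 2^h
  })
  prob <- mass / sum(mass)
  obs <- prob[hets == n_ab]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# 1-D grid-search oracle for two-locus ML: margins fixed at the observed
# allele frequencies (an invariant of the EM), f11 scanned on a grid.
grid_r2_oracle <- function(counts9, step = 1e-4) {
  N <- as.numeric(counts9)
  nn <- sum(N)
  pA <- (2 * (N[7] + N[8] + N[9]) + N[4] + N[5] + N[6]) / (2 * nn)
  pB <- (2 * (N[3] + N[6] + N[9]) + N[2] + N[5] + N[8]) / (2 * nn)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  g <- seq(max(0, pA + pB - 1), min(pA, pB), by = step)
  ll <- vapply(g, function(f11) {
    f10 <- pA - f11; f01 <- pB - f11; f00 <- 1 - pA - pB + f11
    if (min(f10, f01, f00) < -1e-9) return(-Inf)
    f10 <- max(f10, 0); f01 <- max(f01, 0); f00 <- max(f00, 0)
    P <- c(f00^2, 2 * f00 * f01, f01^2, 2 * f00 * f10,
           2 * (f11 * f00 + f10 * f01), 2 * f01 * f11,
           f10^2, 2 * f10 * f11, f11^2)
    sum(N * log(P + 1e-300))
  }, numeric(1))
  f11 <- g[which.max(ll)]
  d <- f11 - pA * pB
  d^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Random two-locus genotype count table with both loci polymorphic.
random_count_table <- function(n_ind) {
  repeat {
    f <- stats::runif(4) + 0.05
    f <- f / sum(f)
    hap <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), 4, 2, byrow = TRUE)
    i1 <- sample(4, n_ind, TRUE, prob = f)
    i2 <- sample(4, n_ind, TRUE, prob = f)
    x <- hap[i1, 1] + hap[i2, 1]
    y <- hap[i1, 2] + hap[i2, 2]
    if (length(unique(x)) >= 2 && length(unique(y)) >= 2) {
      N <- numeric(9)
      for (k in seq_len(n_ind)) N[3 * x[k] + y[k] + 1] <- N[3 * x[k] + y[k] + 1] + 1
      return(N)
    }
  }
}

# The crafted 10-SNP QC fixture: one SNP per failure mode (unmapped,
# X-linked, low call rate, low MAF, HWE failure) plus five clean markers;
# 40 individuals, one population.
qc_fixture <- function() {
  n <- 40
  clean <- function() c(rep(0L, 10), rep(1L, 20), rep(2L, 10))  # HWE, MAF .5
  cols <- list(
    unmapped  = clean(),
    x_linked  = clean(),
    low_call  = { z <- clean(); z[1:4] <- NA_integer_; z },      # call rate .9
    low_maf   = c(rep(0L, 38), 1L, 1L),                          # MAF .025
    hwe_fail  = c(rep(0L, 20), rep(2L, 20)),                     # exact p << .001
    clean1 = clean(), clean2 = clean(), clean3 = clean(),
    clean4 = clean(), clean5 = clean())
  dosage <- do.call(cbind, cols)
  chrom <- c("0", "27", rep("1", 8))
  make_ds(dosage, chrom = chrom, bp = seq_len(10) * 1e5)
}

# WC84 theta oracle for a single biallelic locus, two populations, written
# directly from the published component formulas (independent transcription).
wc_oracle_single_locus <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# NNLS residual of fitting a circular split system with a given ordering.
nnls_residual_for_order <- function(D, ord) {
  css <- popgenpipe:::circular_split_system(ord)
  dv <- D[t(css$pairs)]
  fit <- pracma::lsqnonneg(css$A, dv)
  sqrt(sum((css$A %*% fit$x - dv)^2))
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# Random circularly decomposable distance matrix with known split weights.
random_circular_distance <- function(n, n_extra_splits = 8) {
  ord <- sample(n)
  css <- popgenpipe:::circular_split_system(ord)
  nsp <- length(css$sides)
  w <- numeric(nsp)
  w[sample(nsp, min(n_extra_splits, nsp))] <- stats::runif(min(n_extra_splits, nsp), 0.2, 1)
  sizes <- lengths(css$sides)
  triv <- sizes == 1 | sizes == n - 1
  w[triv] <- w[triv] + stats::runif(sum(triv), 0.2, 1)
  dv <- as.vector(css$A %*% w)
  D <- matrix(0, n, n)
  D[t(css$pairs)] <- dv
  D + t(D)
}
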