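# Synthetic genotype generators with known truth.
#
# Every generator is seeded and returns a list(dataset, truth): `dataset` is
# a genotype_dataset ready for the pipeline, `truth` records the parameters
# the pipeline is expected to recover (ancestral frequencies, drift F, true
# Q, true Ne, the recombination map, the seed).  The generators emulate the
# shape of multi-breed 50K-chip data — ~26 autosomes, ~60 kb marker spacing,
# 70-80 individuals per breed, MAF spread over (0, 0.5), LD decaying with
# distance, between-breed FST of a few percent — without any real genotypes.

# Marker map with roughly chip-like spacing (default ~60 kb between SNPs).
make_map <- function(n_loci_per_chrom, chromosomes, mean_spacing_bp = 6e4) {
  rows <- lapply(chromosomes, function(ch) {
    gaps <- stats::runif(n_loci_per_chrom, 0.5 * mean_spacing_bp, 1.5 * mean_spacing_bp)
    bp <- round(cumsum(gaps))
    data.frame(chrom = as.character(ch),
               id = sprintf("snp_%s_%04d", ch, seq_len(n_loci_per_chrom)),
               cm = bp / 1e6, bp = bp, alleleA = "A", alleleB = "B",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

make_samples <- function(n_per_pop, pop_names) {
  data.frame(
    family = rep(pop_names, n_per_pop),
    id = unlist(lapply(seq_along(pop_names), function(k)
      sprintf("%s_%03d", pop_names[k], seq_len(n_per_pop[k])))),
    population = rep(pop_names, n_per_pop),
    stringsAsFactors = FALSE)
}

#' Simulate structured populations under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn uniformly on `p_anc_range`; each
#' population's frequency at a locus is a Beta draw around the ancestral
#' value with drift parameter `F` (`Beta(p(1-F)/F, (1-p)(1-F)/F)`), and
#' genotypes are binomial(2) draws — unlinked loci, Hardy-Weinberg within
#' populations.  The expected pairwise Weir-Cockerham FST between
#' populations with drifts `F1`, `F2` is approximately `(F1 + F2)/2`, which
#' the truth record stores for recovery tests.
#'
#' @param n_pops number of populations.
#' @param f per-population drift F, recycled to `n_pops`; each in `(0, 1)`.
#' @param n_loci_per_chrom loci per chromosome.
#' @param n_ind_per_pop individuals per population, recycled.
#' @param chromosomes chromosome labels (default `1:2`).
#' @param seed integer seed; same seed, same dataset.
#' @param p_anc_range range of the ancestral frequency draw.
#' @return List with `dataset` (a `genotype_dataset`) and `truth` (class
#'   `sim_truth`): `p_anc`, `f`, `pop_freqs`, `expected_theta`, `seed`.
#' @export
simulate_balding_nichols <- function(n_pops = 2, f = 0.05,
                                     n_loci_per_chrom = 100,
                                     n_ind_per_pop = 70,
                                     chromosomes = 1:2, seed = 1,
                                     p_anc_range = c(0.05, 0.95)) {
  stopifnot(all(f > 0), all(f < 1))
  set.seed(seed)
  f <- rep_len(f, n_pops)
  n_ind <- rep_len(n_ind_per_pop, n_pops)
  pops <- sprintf("pop%d", seq_len(n_pops))
  variants <- make_map(n_loci_per_chrom, chromosomes)
  L <- nrow(variants)
  p_anc <- stats::runif(L, p_anc_range[1], p_anc_range[2])
  pop_freqs <- matrix(NA_real_, n_pops, L, dimnames = list(pops, variants$id))
  for (k in seq_len(n_pops)) {
    shape1 <- p_anc * (1 - f[k]) / f[k]
    shape2 <- (1 - p_anc) * (1 - f[k]) / f[k]
    pop_freqs[k, ] <- stats::rbeta(L, shape1, shape2)
  }
  dosage <- matrix(NA_integer_, sum(n_ind), L)
  row0 <- 0
  for (k in seq_len(n_pops)) {
    dosage[row0 + seq_len(n_ind[k]), ] <-
      matrix(stats::rbinom(n_ind[k] * L, 2, rep(pop_freqs[k, ], each = n_ind[k])),
             n_ind[k], L)
    row0 <- row0 + n_ind[k]
  }
  expected_theta <- outer(f, f, function(a, b) (a + b) / 2)
  diag(expected_theta) <- 0
  dimnames(expected_theta) <- list(pops, pops)
  ds <- genotype_dataset(dosage, variants, make_samples(n_ind, pops))
  truth <- structure(list(model = "balding_nichols", p_anc = p_anc, f = f,
                          pop_freqs = pop_freqs, expected_theta = expected_theta,
                          seed = seed), class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' Simulate admixed genomes from known ancestry proportions
#'
#' Genotype of individual `i` at locus `j` is binomial(2, `sum_k Q[i,k]
#' P[k,j]`) over unlinked loci: the generative model of the admixture
#' analysis itself.  One-hot Q rows reduce to discrete source populations.
#'
#' @param Q n x K matrix of true ancestry proportions (rows sum to 1).
#' @param source_freqs K x L matrix of source-population allele
#'   frequencies; `L` loci are laid on chromosome 1 with chip-like spacing.
#' @param seed integer seed.
#' @return List with `dataset` and `truth` (`Q`, `source_freqs`, `seed`).
#' @export
simulate_admixed <- function(Q, source_freqs, seed = 1) {
  Q <- as.matrix(Q); source_freqs <- as.matrix(source_freqs)
  stopifnot(ncol(Q) == nrow(source_freqs),
            max(abs(rowSums(Q) - 1)) < 1e-8)
  set.seed(seed)
  n <- nrow(Q); L <- ncol(source_freqs)
  mix <- Q %*% source_freqs
  dosage <- matrix(stats::rbinom(n * L, 2, as.vector(mix)), n, L)
  variants <- make_map(L, 1)
  samples <- data.frame(family = "adm", id = sprintf("ind_%03d", seq_len(n)),
                        population = "adm", stringsAsFactors = FALSE)
  ds <- genotype_dataset(dosage, variants, samples)
  truth <- structure(list(model = "admixed", Q = Q, source_freqs = source_freqs,
                          seed = seed), class = "sim_truth")
  list(dataset = ds, truth = truth)
}

# One generation of Wright-Fisher random mating with Poisson recombination.
# H: 2Ne x L 0/1 haplotype matrix; pos_m: locus positions in Morgans.
wf_next_generation <- function(H, pos_m, chrom_len_m) {
  n_hap <- nrow(H)
  ne <- n_hap / 2
  L <- ncol(H)
  parents <- sample.int(ne, n_hap, replace = TRUE)
  n_cross <- stats::rpois(n_hap, chrom_len_m)
  start_hap <- sample.int(2, n_hap, replace = TRUE)
  out <- matrix(0L, n_hap, L)
  for (g in seq_len(n_hap)) {
    h1 <- H[2 * parents[g] - 1, ]
    h2 <- H[2 * parents[g], ]
    if (n_cross[g] == 0) {
      out[g, ] <- if (start_hap[g] == 1) h1 else h2
    } else {
      breaks <- sort(stats::runif(n_cross[g], 0, chrom_len_m))
      seg <- findInterval(pos_m, breaks)
      use1 <- (seg + start_hap[g]) %% 2L == 1L
      out[g, ] <- ifelse(use1, h1, h2)
    }
  }
  out
}

#' Forward Wright-Fisher simulation with recombination (known Ne)
#'
#' Simulates `2 Ne` haplotypes per discrete generation under random mating
#' with Poisson crossovers on a chromosome of `chrom_length_morgans`;
#' initial haplotypes are at linkage equilibrium with uniform allele
#' frequencies, so the LD present at the end is the drift-recombination
#' equilibrium of the chosen Ne (running at least `4 Ne` generations is
#' recommended).  Physical positions use the 1 cM = 1 Mb conversion, so the
#' LD-based Ne machinery can be tested end to end against the known truth.
#'
#' @param ne true (constant) effective population size, `>= 10`.
#' @param n_generations generations to evolve.
#' @param chrom_length_morgans genetic length per chromosome (default 1).
#' @param n_loci loci per chromosome (those fixed by drift remain in the
#'   dataset and are left to QC to remove).
#' @param sample_size diploid individuals sampled (without replacement)
#'   from the final generation; `<= ne`.
#' @param n_chrom independent chromosomes (replicates of the same process).
#' @param seed integer seed.
#' @return List with `dataset` and `truth` (`ne`, `n_generations`,
#'   `chrom_length_morgans`, `bp_per_morgan`, `seed`).
#' @export
simulate_wright_fisher_ld <- function(ne = 100, n_generations = 4 * ne,
                                      chrom_length_morgans = 1, n_loci = 200,
                                      sample_size = 50, n_chrom = 1, seed = 1) {
  stopifnot(ne >= 10, sample_size <= ne)
  set.seed(seed)
  bp_per_morgan <- 1e8
  all_var <- list(); all_dos <- list()
  for (ch in seq_len(n_chrom)) {
    pos_m <- sort(stats::runif(n_loci, 0, chrom_length_morgans))
    p0 <- stats::runif(n_loci, 0.05, 0.95)
    H <- matrix(stats::rbinom(2 * ne * n_loci, 1, rep(p0, each = 2 * ne)),
                2 * ne, n_loci)
    for (gen in seq_len(n_generations)) {
      H <- wf_next_generation(H, pos_m, chrom_length_morgans)
    }
    ind <- sample.int(ne, sample_size)
    dos <- H[2 * ind - 1, , drop = FALSE] + H[2 * ind, , drop = FALSE]
    bp <- round(pos_m * bp_per_morgan)
    # collapse rare duplicate positions to keep within-chromosome bp unique
    while (any(duplicated(bp))) bp[duplicated(bp)] <- bp[duplicated(bp)] + 1
    all_var[[ch]] <- data.frame(chrom = as.character(ch),
                                id = sprintf("wf_%d_%04d", ch, seq_len(n_loci)),
                                cm = pos_m * 100, bp = bp,
                                alleleA = "A", alleleB = "B",
                                stringsAsFactors = FALSE)
    all_dos[[ch]] <- dos
  }
  variants <- do.call(rbind, all_var)
  dosage <- do.call(cbind, all_dos)
  samples <- data.frame(family = "wf", id = sprintf("ind_%03d", seq_len(sample_size)),
                        population = "wf", stringsAsFactors = FALSE)
  ds <- genotype_dataset(dosage, variants, samples)
  truth <- structure(list(model = "wright_fisher", ne = ne,
                          n_generations = n_generations,
                          chrom_length_morgans = chrom_length_morgans,
                          bp_per_morgan = bp_per_morgan, seed = seed),
                     class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' Chip-scale simulation preset
#'
#' Parameters emulating a 50K-array breed survey: 26 autosomes, ~1,700 SNPs
#' per chromosome (~45K markers), 70-80 individuals per breed, drift F a few
#' percent.  Intended for full-scale runs from the analysis scripts; unit
#' tests use 2 chromosomes.
#'
#' @return Named list of arguments for [simulate_balding_nichols()].
#' @export
sheep50k_preset <- function() {
  list(n_pops = 3, f = c(0.04, 0.05, 0.06), n_loci_per_chrom = 1700,
       n_ind_per_pop = c(71, 71, 77), chromosomes = 1:26)
}

#' Serialize simulation truth as JSON
#'
#' @param truth a `sim_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
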