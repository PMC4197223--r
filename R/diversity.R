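#' Per-SNP diversity indices
#'
#' Minor allele frequency, observed heterozygosity and expected
#' heterozygosity `2p(1-p)` per locus, on non-missing calls, plus their
#' means and standard deviations over loci — the per-population summary that
#' diversity tables of chip surveys report.
#'
#' @param ds a QC'd `genotype_dataset`.
#' @return List with `per_snp` (id, n, p, maf, ho, he) and `summary`
#'   (mean/sd of maf, ho, he over loci with at least one call).
#' @export
snp_diversity <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  d <- ds$dosage
  n <- colSums(!is.na(d))
  p <- allele_freq(d)
  maf <- pmin(p, 1 - p)
  ho <- colSums(d == 1L, na.rm = TRUE) / n
  ho[n == 0] <- NA_real_
  he <- 2 * p * (1 - p)
  per_snp <- data.frame(id = ds$variants$id, n = n, p = p, maf = maf,
                        ho = ho, he = he, stringsAsFactors = FALSE)
  ok <- n > 0
  summary <- data.frame(
    mean_maf = mean(maf[ok]), sd_maf = stats::sd(maf[ok]),
    mean_ho = mean(ho[ok]), sd_ho = stats::sd(ho[ok]),
    mean_he = mean(he[ok]), sd_he = stats::sd(he[ok]),
    n_snps = sum(ok))
  list(per_snp = per_snp, summary = summary)
}

#' Method-of-moments inbreeding coefficient per individual
#'
#' `F = (observedHom - expectedHom) / (nTyped - expectedHom)`, where the
#' expected homozygote count sums `1 - 2 p_j (1 - p_j) * n_j/(n_j - 1)` over
#' the individual's typed loci (the small-sample-unbiased heterozygosity,
#' the PLINK `--het` convention).  Allele frequencies are estimated from the
#' dataset itself; loci typed in fewer than two individuals are skipped.
#' Negative values mark individuals less homozygous than expected.
#'
#' @param ds a QC'd `genotype_dataset`, normally one population.
#' @return Data frame (id, population, observed_hom, expected_hom, n_typed, f).
#' @export
individual_inbreeding <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  d <- ds$dosage
  nj <- colSums(!is.na(d))
  use <- nj >= 2
  d <- d[, use, drop = FALSE]
  nj <- nj[use]
  p <- allele_freq(d)
  exp_het_j <- 2 * p * (1 - p) * nj / (nj - 1)
  typed <- !is.na(d)
  n_typed <- rowSums(typed)
  obs_hom <- rowSums(d == 0L | d == 2L, na.rm = TRUE)
  exp_hom <- as.vector(typed %*% (1 - exp_het_j))
  f <- (obs_hom - exp_hom) / (n_typed - exp_hom)
  data.frame(id = ds$samples$id, population = ds$samples$population,
             observed_hom = obs_hom, expected_hom = exp_hom,
             n_typed = n_typed, f = f, stringsAsFactors = FALSE)
}

#' LD-based effective population size (Sved's relation)
#'
#' `Ne = (1/(4c)) (1/r2 - 1)` for markers `c` Morgans apart; the estimate
#' probes the population `t = 1/(2c)` generations ago.
#'
#' @param mean_r2 mean r2 of marker pairs at distance `c` (in `(0, 1]`).
#' @param c_morgans inter-marker distance in Morgans (`> 0`).
#' @return List (class `ne_estimate`) with `ne`, `generations_ago`,
#'   `c_morgans`, `mean_r2`.  `mean_r2 = 0` gives `ne = Inf` with a warning.
#' @export
sved_ne <- function(mean_r2, c_morgans) {
  stopifnot(c_morgans > 0, mean_r2 >= 0, mean_r2 <= 1)
  if (mean_r2 == 0) {
    warning("mean r2 of zero implies infinite effective population size")
    ne <- Inf
  } else {
    ne <- (1 / (4 * c_morgans)) * (1 / mean_r2 - 1)
  }
  structure(list(ne = ne, generations_ago = 1 / (2 * c_morgans),
                 c_morgans = c_morgans, mean_r2 = mean_r2),
            class = "ne_estimate")
}

#' Effective-population-size trajectory from sliding LD bins
#'
#' Converts each sliding distance bin into one point of the Ne history:
#' `c = center / bp_per_morgan` Morgans, `t = 1/(2c)` generations ago, and
#' `Ne` from [sved_ne()] applied to the bin's mean r2.  The default map
#' conversion is 1 cM per Mb, the standard assumption when no linkage map is
#' supplied; under it the 1 Mb bin probes 50 generations ago.  An optional
#' sample-size correction subtracts the chip-sample inflation `1/(2n)` from
#' r2 before inversion (off by default, mirroring the plain formula).
#'
#' @param bins data frame from [sliding_ld_bins()].
#' @param bp_per_morgan physical length of one Morgan (default `1e8`).
#' @param sample_size number of individuals behind the r2 values; used only
#'   when `correct_sample_size = TRUE`.
#' @param correct_sample_size subtract `1/(2 * sample_size)` from mean r2.
#' @return Data frame (center_bp, c_morgans, generations_ago, mean_r2, ne),
#'   ordered as supplied; bins with no pairs or non-positive corrected r2
#'   get `NA` ne.
#' @export
ne_trajectory <- function(bins, bp_per_morgan = 1e8, sample_size = NULL,
                          correct_sample_size = FALSE) {
  r2 <- bins$mean_r2
  if (correct_sample_size) {
    if (is.null(sample_size)) stop("sample_size is required for the correction")
    r2 <- r2 - 1 / (2 * sample_size)
  }
  c_m <- bins$center_bp / bp_per_morgan
  ne <- ifelse(!is.na(r2) & r2 > 0, (1 / (4 * c_m)) * (1 / r2 - 1), NA_real_)
  data.frame(center_bp = bins$center_bp, c_morgans = c_m,
             generations_ago = 1 / (2 * c_m), mean_r2 = r2, ne = ne)
}

#' Diversity table by population
#'
#' One row per population: MAF, Ho, He (means +/- sd over loci) and mean
#' inbreeding F — the per-breed diversity summary.  Indices are computed
#' within each population on its own allele frequencies.
#'
#' @param ds a QC'd `genotype_dataset` with population labels.
#' @return Data frame with one row per population.
#' @export
diversity_by_population <- function(ds) {
  parts <- split_by_population(ds)
  rows <- lapply(names(parts), function(p) {
    sd_ <- snp_diversity(parts[[p]])
    f <- individual_inbreeding(parts[[p]])
    cbind(data.frame(population = p, n_ind = nrow(parts[[p]]$dosage)),
          sd_$summary,
          data.frame(mean_f = mean(f$f), sd_f = stats::sd(f$f)))
  })
  do.call(rbind, rows)
}
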