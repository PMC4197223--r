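#' Marker quality-control thresholds
#'
#' Holds the three marker filters applied before any analysis: call
#' frequency (proportion of samples genotyped at a locus) at least
#' `min_call`, minor allele frequency at least `min_maf`, and exact
#' Hardy-Weinberg p-value strictly above `min_hwe_p`.  Defaults are the
#' standard 50K-chip settings (0.95 / 0.05 / 0.001).
#'
#' @param min_call minimum call frequency, in `[0, 1]`.
#' @param min_maf minimum minor allele frequency, in `[0, 1]`.
#' @param min_hwe_p loci with exact HWE p-value `<= min_hwe_p` are dropped.
#' @param autosomes retained chromosome numbers (sheep: `1:26`).
#' @param hwe_per_population test HWE within each population label and drop a
#'   locus that fails in any of them (`TRUE`, the default, matching per-breed
#'   QC), or pool all samples (`FALSE`).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call = 0.95, min_maf = 0.05, min_hwe_p = 0.001,
                          autosomes = 1:26, hwe_per_population = TRUE) {
  stopifnot(min_call >= 0, min_call <= 1, min_maf >= 0, min_maf <= 1,
            min_hwe_p >= 0, min_hwe_p <= 1)
  structure(list(min_call = min_call, min_maf = min_maf, min_hwe_p = min_hwe_p,
                 autosomes = autosomes, hwe_per_population = hwe_per_population),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium p-value
#'
#' Two-sided exact test from genotype counts: conditional on the allele
#' counts, every heterozygote count of matching parity is enumerated, each
#' configuration weighted by its multinomial probability under random mating
#' (proportional to `n!/(nAA! nAB! nBB!) * 2^nAB`), and the p-value is the
#' total probability of configurations no more probable than the observed
#' one.  This is the standard exact test used by SNP QC tools (no mid-p
#' adjustment).
#'
#' @param n_aa,n_ab,n_bb genotype counts (AA homozygote, heterozygote, BB
#'   homozygote).
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_pvalue <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be non-negative")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotyped individual is required")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  logw <- vapply(hets, function(h) {
    haa <- (n_a - h) / 2
    hbb <- (n_b - h) / 2
    h * log(2) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb)
  }, numeric(1))
  w <- exp(logw - max(logw))
  p_config <- w / sum(w)
  obs <- p_config[match(n_ab, hets)]
  sum(p_config[p_config <= obs * (1 + 1e-12)])
}

# Per-locus genotype counts (columns: n0, n1, n2 of B-allele dosage).
genotype_counts <- function(dosage) {
  cbind(n0 = colSums(dosage == 0L, na.rm = TRUE),
        n1 = colSums(dosage == 1L, na.rm = TRUE),
        n2 = colSums(dosage == 2L, na.rm = TRUE))
}

# B-allele frequency and MAF per locus from a dosage matrix.
allele_freq <- function(dosage) {
  n <- colSums(!is.na(dosage))
  p <- colSums(dosage, na.rm = TRUE) / (2 * n)
  p[n == 0] <- NA_real_
  p
}

#' Minor allele frequency per locus
#'
#' @param ds a `genotype_dataset` (or dosage matrix).
#' @return Numeric vector of per-locus MAF on non-missing calls.
#' @export
snp_maf <- function(ds) {
  d <- if (inherits(ds, "genotype_dataset")) ds$dosage else ds
  p <- allele_freq(d)
  pmin(p, 1 - p)
}

hwe_pvalues <- function(dosage) {
  cnt <- genotype_counts(dosage)
  vapply(seq_len(nrow(cnt)), function(j) {
    if (sum(cnt[j, ]) == 0) return(1)
    hwe_exact_pvalue(cnt[j, 1], cnt[j, 2], cnt[j, 3])
  }, numeric(1))
}

#' Apply marker quality control
#'
#' Filters run in a fixed order so attrition is reproducible: unmapped
#' markers, non-autosomal markers, call frequency, minor allele frequency
#' (computed on non-missing calls of the markers surviving the call-rate
#' filter), then the exact HWE test.  No sample-level filter is applied.
#'
#' @param ds a `genotype_dataset`.
#' @param thresholds a [qc_thresholds()].
#' @return List with `dataset` (the filtered `genotype_dataset`) and
#'   `report` (class `qc_report`): per-step removal counts, retained SNP and
#'   sample counts, and an `empty` flag when no SNP survives.
#' @export
apply_qc <- function(ds, thresholds = qc_thresholds()) {
  stopifnot(inherits(ds, "genotype_dataset"))
  t <- thresholds
  chrom <- ds$variants$chrom
  n0 <- ncol(ds$dosage)
  keep <- rep(TRUE, n0)

  cn <- chrom_number(chrom)
  # chromosome code 0 (or an unparseable label) marks an unmapped contig;
  # listing 0 in the retained set disables this structural filter
  unmapped <- (is.na(cn) | cn == 0) & !(0 %in% t$autosomes)
  removed_unmapped <- sum(keep & unmapped)
  keep <- keep & !unmapped

  non_auto <- !is_autosome(chrom, t$autosomes)
  removed_nonauto <- sum(keep & non_auto)
  keep <- keep & !non_auto

  call_freq <- colSums(!is.na(ds$dosage)) / nrow(ds$dosage)
  low_call <- call_freq < t$min_call
  removed_call <- sum(keep & low_call)
  keep <- keep & !low_call

  maf <- snp_maf(ds$dosage[, , drop = FALSE])
  low_maf <- is.na(maf) | maf < t$min_maf
  removed_maf <- sum(keep & low_maf)
  keep <- keep & !low_maf

  idx <- which(keep)
  fail_hwe <- rep(FALSE, length(idx))
  if (length(idx) > 0 && t$min_hwe_p > 0) {
    pops <- if (t$hwe_per_population) unique(ds$samples$population) else "all"
    for (p in pops) {
      rows <- if (identical(p, "all")) seq_len(nrow(ds$dosage)) else
        which(ds$samples$population == p)
      pv <- hwe_pvalues(ds$dosage[rows, idx, drop = FALSE])
      fail_hwe <- fail_hwe | pv <= t$min_hwe_p
    }
  }
  removed_hwe <- sum(fail_hwe)
  keep[idx[fail_hwe]] <- FALSE

  out <- subset_dataset(ds, variants = keep)
  report <- structure(list(
    removed = c(unmapped = removed_unmapped, non_autosomal = removed_nonauto,
                call_rate = removed_call, maf = removed_maf, hwe = removed_hwe),
    snps_initial = n0, snps_retained = sum(keep),
    samples_retained = nrow(ds$dosage),
    thresholds = t, empty = sum(keep) == 0
  ), class = "qc_report")
  if (report$empty) warning("no SNPs survive quality control")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control:", x$snps_initial, "->", x$snps_retained, "markers\n")
  for (nm in names(x$removed)) cat(sprintf("  removed by %-13s %d\n", nm, x$removed[[nm]]))
  invisible(x)
}

#' Serialize a QC report
#'
#' @param report a `qc_report`.
#' @param path_prefix files `<prefix>.json` and `<prefix>.tsv` are written.
#' @return The two paths, invisibly.
#' @export
write_qc_report <- function(report, path_prefix) {
  json <- paste0(path_prefix, ".json")
  tsv <- paste0(path_prefix, ".tsv")
  jsonlite::write_json(list(removed = as.list(report$removed),
                            snps_initial = report$snps_initial,
                            snps_retained = report$snps_retained,
                            samples_retained = report$samples_retained),
                       json, auto_unbox = TRUE, pretty = TRUE)
  utils::write.table(data.frame(step = names(report$removed),
                                removed = as.integer(report$removed)),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json, tsv))
}
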