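# Two-locus LD machinery.
#
# All pairwise statistics flow through one vectorised core: each SNP pair is
# reduced to its 3x3 two-locus genotype count table (9 integers), and the EM
# estimator of the four haplotype frequencies runs elementwise over a matrix
# of such tables.  Column order of a count table is n00, n01, n02, n10, n11,
# n12, n20, n21, n22, where the first digit is the B-allele dosage at locus 1
# and the second at locus 2.

# Build count-table rows for a list of SNP pairs from a dosage matrix.
pair_count_tables <- function(dosage, ia, ib) {
  I0 <- (dosage == 0L); I0[is.na(I0)] <- FALSE; storage.mode(I0) <- "double"
  I1 <- (dosage == 1L); I1[is.na(I1)] <- FALSE; storage.mode(I1) <- "double"
  I2 <- (dosage == 2L); I2[is.na(I2)] <- FALSE; storage.mode(I2) <- "double"
  ind <- list(I0, I1, I2)
  out <- matrix(0, length(ia), 9)
  colnames(out) <- c("n00", "n01", "n02", "n10", "n11", "n12", "n20", "n21", "n22")
  k <- 0
  for (x in 0:2) for (y in 0:2) {
    k <- k + 1
    out[, k] <- colSums(ind[[x + 1]][, ia, drop = FALSE] *
                        ind[[y + 1]][, ib, drop = FALSE])
  }
  out
}

# Vectorised EM over m count tables.  Returns haplotype frequencies f11, f10,
# f01, f00 (1 = B allele) and the final log-likelihood per table.
# Three deterministic initialisations are run (linkage equilibrium of the
# observed margins, and the two phase-pure corners for the double
# heterozygotes); the best-likelihood solution is kept, which removes the
# initialisation sensitivity of tables dominated by double heterozygotes.
em_haplo_vec <- function(N, tol = 1e-10, max_iter = 1000) {
  n <- rowSums(N)
  if (any(n < 1)) stop("each count table needs at least one individual")
  c11 <- 2 * N[, "n22"] + N[, "n21"] + N[, "n12"]
  c10 <- 2 * N[, "n20"] + N[, "n21"] + N[, "n10"]
  c01 <- 2 * N[, "n02"] + N[, "n12"] + N[, "n01"]
  c00 <- 2 * N[, "n00"] + N[, "n01"] + N[, "n10"]
  ndh <- N[, "n11"]
  tot <- 2 * n
  pA <- (c11 + c10 + ndh) / tot          # B-allele freq, locus 1
  pB <- (c11 + c01 + ndh) / tot          # B-allele freq, locus 2

  loglik <- function(f11, f10, f01, f00) {
    eps <- 1e-300
    N[, "n00"] * log(f00^2 + eps) + N[, "n01"] * log(2 * f00 * f01 + eps) +
      N[, "n02"] * log(f01^2 + eps) + N[, "n10"] * log(2 * f00 * f10 + eps) +
      N[, "n12"] * log(2 * f01 * f11 + eps) + N[, "n20"] * log(f10^2 + eps) +
      N[, "n21"] * log(2 * f10 * f11 + eps) + N[, "n22"] * log(f11^2 + eps) +
      ndh * log(2 * (f11 * f00 + f10 * f01) + eps)
  }
  run_em <- function(w0) {
    f11 <- (c11 + w0 * ndh) / tot
    f10 <- (c10 + (1 - w0) * ndh) / tot
    f01 <- (c01 + (1 - w0) * ndh) / tot
    f00 <- (c00 + w0 * ndh) / tot
    ll <- loglik(f11, f10, f01, f00)
    for (it in seq_len(max_iter)) {
      num <- f11 * f00
      den <- num + f10 * f01
      w <- ifelse(den > 0, num / den, 0.5)
      f11 <- (c11 + w * ndh) / tot
      f10 <- (c10 + (1 - w) * ndh) / tot
      f01 <- (c01 + (1 - w) * ndh) / tot
      f00 <- (c00 + w * ndh) / tot
      ll_new <- loglik(f11, f10, f01, f00)
      if (max(abs(ll_new - ll)) < tol) { ll <- ll_new; break }
      ll <- ll_new
    }
    list(f11 = f11, f10 = f10, f01 = f01, f00 = f00, ll = ll)
  }
  # init at linkage equilibrium (EM weight implied by product freqs), plus corners
  den0 <- pA * (1 - pA) * pB * (1 - pB) + (pA * pB) * ((1 - pA) * (1 - pB))
  w_eq <- ifelse(den0 > 0, (pA * pB) * ((1 - pA) * (1 - pB)) / den0, 0.5)
  sols <- list(run_em(w_eq), run_em(1), run_em(0))
  best <- sols[[1]]
  for (s in sols[-1]) {
    better <- s$ll > best$ll + 1e-12
    for (fld in c("f11", "f10", "f01", "f00", "ll"))
      best[[fld]] <- ifelse(better, s[[fld]], best[[fld]])
  }
  best
}

#' EM haplotype frequencies for one SNP pair
#'
#' Maximum-likelihood two-locus haplotype frequencies under random mating
#' from unphased genotype counts, resolving the double-heterozygote phase
#' ambiguity by EM (the estimator behind PLINK-style unphased r2).
#'
#' @param counts 3x3 matrix of two-locus genotype counts; rows = B-allele
#'   dosage 0/1/2 at locus 1, columns = dosage at locus 2.  A length-9 vector
#'   in column order `n00, n01, n02, n10, ..., n22` is also accepted.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap.
#' @return List of class `haplotype_freqs` with `pAB`, `pAb`, `paB`, `pab`
#'   (A/B = the B allele at locus 1 / locus 2), `logLikelihood`, the allele
#'   frequencies `pA`, `pB`, and `trace`, the per-iteration log-likelihood of
#'   the best run (monotone non-decreasing).
#' @export
em_haplotype_frequencies <- function(counts, tol = 1e-10, max_iter = 1000) {
  if (is.matrix(counts) && all(dim(counts) == c(3, 3))) {
    v <- as.numeric(t(counts))
  } else if (length(counts) == 9) {
    v <- as.numeric(counts)
  } else stop("counts must be a 3x3 matrix or length-9 vector")
  if (any(v < 0)) stop("counts must be non-negative")
  N <- matrix(v, 1, 9)
  colnames(N) <- c("n00", "n01", "n02", "n10", "n11", "n12", "n20", "n21", "n22")
  sol <- em_haplo_vec(N, tol = tol, max_iter = max_iter)
  # recompute the winning run's trace for the monotonicity contract
  trace <- em_trace_scalar(N, sol, tol, max_iter)
  structure(list(pAB = unname(sol$f11), pAb = unname(sol$f10),
                 paB = unname(sol$f01), pab = unname(sol$f00),
                 logLikelihood = unname(sol$ll),
                 pA = unname(sol$f11 + sol$f10), pB = unname(sol$f11 + sol$f01),
                 trace = trace),
            class = "haplotype_freqs")
}

# Re-run EM from each start, return the log-likelihood trace of the best.
em_trace_scalar <- function(N, best_sol, tol, max_iter) {
  n <- rowSums(N); tot <- 2 * n
  c11 <- 2 * N[, "n22"] + N[, "n21"] + N[, "n12"]
  c10 <- 2 * N[, "n20"] + N[, "n21"] + N[, "n10"]
  c01 <- 2 * N[, "n02"] + N[, "n12"] + N[, "n01"]
  c00 <- 2 * N[, "n00"] + N[, "n01"] + N[, "n10"]
  ndh <- N[, "n11"]
  pA <- (c11 + c10 + ndh) / tot; pB <- (c11 + c01 + ndh) / tot
  ll_of <- function(f11, f10, f01, f00) {
    eps <- 1e-300
    sum(N[, c("n00", "n01", "n02", "n10", "n12", "n20", "n21", "n22")] *
          log(c(f00^2, 2 * f00 * f01, f01^2, 2 * f00 * f10, 2 * f01 * f11,
                f10^2, 2 * f10 * f11, f11^2) + eps)) +
      ndh * log(2 * (f11 * f00 + f10 * f01) + 1e-300)
  }
  den0 <- pA * (1 - pA) * pB * (1 - pB) + (pA * pB) * ((1 - pA) * (1 - pB))
  w_eq <- if (den0 > 0) (pA * pB) * ((1 - pA) * (1 - pB)) / den0 else 0.5
  best_trace <- NULL; best_ll <- -Inf
  for (w0 in c(w_eq, 1, 0)) {
    f11 <- (c11 + w0 * ndh) / tot; f10 <- (c10 + (1 - w0) * ndh) / tot
    f01 <- (c01 + (1 - w0) * ndh) / tot; f00 <- (c00 + w0 * ndh) / tot
    trace <- ll_of(f11, f10, f01, f00)
    for (it in seq_len(max_iter)) {
      num <- f11 * f00; den <- num + f10 * f01
      w <- if (den > 0) num / den else 0.5
      f11 <- (c11 + w * ndh) / tot; f10 <- (c10 + (1 - w) * ndh) / tot
      f01 <- (c01 + (1 - w) * ndh) / tot; f00 <- (c00 + w * ndh) / tot
      ll <- ll_of(f11, f10, f01, f00)
      trace <- c(trace, ll)
      if (abs(ll - trace[length(trace) - 1]) < tol) break
    }
    if (trace[length(trace)] > best_ll) { best_ll <- trace[length(trace)]; best_trace <- trace }
  }
  best_trace
}

#' Squared allelic correlation r2 (and D') from haplotype frequencies
#'
#' `r2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB`; `dprime` is
#' `|D|` scaled by its maximum attainable value given the allele margins.
#' A locus fixed in the sample has no defined r2: `NA` is returned, which is
#' deliberately distinct from 0.
#'
#' @param h a `haplotype_freqs` (or list with `pAB`, `pAb`, `paB`, `pab`).
#' @return List with `r2`, `dprime`, `d`.
#' @export
r_squared <- function(h) {
  pA <- h$pAB + h$pAb
  pB <- h$pAB + h$paB
  d <- h$pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) return(list(r2 = NA_real_, dprime = NA_real_, d = d))
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  list(r2 = min(1, d^2 / denom),
       dprime = if (dmax > 0) min(1, abs(d) / dmax) else NA_real_,
       d = d)
}

# Vectorised r2/D' for many pairs given dosage matrix and index vectors.
ld_stats_for_pairs <- function(dosage, ia, ib) {
  N <- pair_count_tables(dosage, ia, ib)
  sol <- em_haplo_vec(N)
  pA <- sol$f11 + sol$f10
  pB <- sol$f11 + sol$f01
  d <- sol$f11 - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(denom > 0, pmin(1, d^2 / denom), NA_real_)
  dmax <- ifelse(d >= 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  dprime <- ifelse(denom > 0 & dmax > 0, pmin(1, abs(d) / dmax), NA_real_)
  data.frame(r2 = r2, dprime = dprime, n = rowSums(N))
}

#' Adjacent-SNP linkage disequilibrium per chromosome
#'
#' r2 between every pair of consecutive SNPs along each chromosome, reported
#' as a per-chromosome table of mean spacing and mean +/- sd r2, with a
#' genome-wide row computed over all pairs pooled (not the mean of
#' chromosome means).  Pairs with undefined r2 (a locus fixed in the sample)
#' are excluded from both the r2 and the spacing averages and counted.
#'
#' @param ds a QC'd `genotype_dataset`.
#' @return List with `by_chromosome` (chrom, n_pairs, n_undefined,
#'   mean_spacing_bp, mean_r2, sd_r2), `genome` (the pooled row), and
#'   `pairs` (per-pair records).  Chromosomes with fewer than two SNPs are
#'   omitted with a warning.
#' @export
adjacent_ld_summary <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  chroms <- unique(ds$variants$chrom)
  rec <- list()
  for (ch in chroms) {
    vi <- which(ds$variants$chrom == ch)
    vi <- vi[order(ds$variants$bp[vi])]
    if (length(vi) < 2) {
      warning("chromosome ", ch, " has fewer than 2 SNPs; omitted")
      next
    }
    ia <- vi[-length(vi)]
    ib <- vi[-1]
    st <- ld_stats_for_pairs(ds$dosage, ia, ib)
    rec[[ch]] <- data.frame(chrom = ch,
                            id_a = ds$variants$id[ia], id_b = ds$variants$id[ib],
                            distance_bp = ds$variants$bp[ib] - ds$variants$bp[ia],
                            r2 = st$r2, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rec)
  if (is.null(pairs)) stop("no chromosome with at least 2 SNPs")
  rownames(pairs) <- NULL
  summarise <- function(df) {
    ok <- !is.na(df$r2)
    data.frame(n_pairs = sum(ok), n_undefined = sum(!ok),
               mean_spacing_bp = mean(df$distance_bp[ok]),
               mean_r2 = mean(df$r2[ok]), sd_r2 = stats::sd(df$r2[ok]))
  }
  by_chrom <- do.call(rbind, lapply(split(pairs, pairs$chrom), summarise))
  by_chrom <- cbind(chrom = rownames(by_chrom), by_chrom)
  rownames(by_chrom) <- NULL
  by_chrom <- by_chrom[order(chrom_number(by_chrom$chrom)), ]
  genome <- summarise(pairs)
  list(by_chromosome = by_chrom, genome = genome, pairs = pairs)
}

#' All within-chromosome SNP pairs up to a distance cap
#'
#' Emits one LD record per within-chromosome SNP pair whose inter-marker
#' distance does not exceed `max_distance_bp` (default 50 Mb, the usual
#' chip-survey cap); between-chromosome pairs are never formed.
#'
#' @param ds a QC'd `genotype_dataset`.
#' @param max_distance_bp distance cap in base pairs; `Inf` for all pairs.
#' @return Data frame (chrom, id_a, id_b, distance_bp, r2, dprime); r2 is
#'   `NA` where undefined.
#' @export
pairwise_ld <- function(ds, max_distance_bp = 5e7) {
  stopifnot(inherits(ds, "genotype_dataset"))
  out <- list()
  for (ch in unique(ds$variants$chrom)) {
    vi <- which(ds$variants$chrom == ch)
    vi <- vi[order(ds$variants$bp[vi])]
    L <- length(vi)
    if (L < 2) next
    bp <- ds$variants$bp[vi]
    ia <- integer(0); ib <- integer(0)
    for (i in seq_len(L - 1)) {
      jmax <- findInterval(bp[i] + max_distance_bp, bp)
      if (jmax > i) {
        ia <- c(ia, rep(vi[i], jmax - i))
        ib <- c(ib, vi[(i + 1):jmax])
      }
    }
    if (length(ia) == 0) next
    st <- ld_stats_for_pairs(ds$dosage, ia, ib)
    out[[ch]] <- data.frame(chrom = ch, id_a = ds$variants$id[ia],
                            id_b = ds$variants$id[ib],
                            distance_bp = abs(ds$variants$bp[ib] - ds$variants$bp[ia]),
                            r2 = st$r2, dprime = st$dprime,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), id_a = character(), id_b = character(),
                      distance_bp = numeric(), r2 = numeric(), dprime = numeric())
  rownames(res) <- NULL
  res
}

#' Default distance-bin edges for LD decay
#'
#' 0-50 kb, 50-100 kb, 100-200 kb, 200-500 kb, 0.5-1 Mb, 1-2 Mb and >2 Mb:
#' the bins conventionally quoted for 50K-chip decay profiles.
#' @return Numeric vector of bin edges in bp.
#' @export
default_decay_bins <- function() c(0, 5e4, 1e5, 2e5, 5e5, 1e6, 2e6, Inf)

#' Distance-binned LD decay profile
#'
#' Arithmetic mean and sd of r2 per inter-marker distance bin.
#'
#' @param records pair records from [pairwise_ld()].
#' @param bin_edges_bp strictly increasing bin edges; a pair falls in bin `k`
#'   when `edges[k] <= distance < edges[k+1]`.
#' @return Data frame (low_bp, high_bp, n_pairs, mean_r2, sd_r2); empty bins
#'   have `n_pairs = 0` and `NA` means.
#' @export
ld_decay_profile <- function(records, bin_edges_bp = default_decay_bins()) {
  if (is.unsorted(bin_edges_bp, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  rec <- records[!is.na(records$r2), , drop = FALSE]
  bin <- findInterval(rec$distance_bp, bin_edges_bp)
  k <- length(bin_edges_bp) - 1
  out <- data.frame(low_bp = bin_edges_bp[-length(bin_edges_bp)],
                    high_bp = bin_edges_bp[-1],
                    n_pairs = 0L, mean_r2 = NA_real_, sd_r2 = NA_real_)
  for (b in seq_len(k)) {
    r <- rec$r2[bin == b]
    out$n_pairs[b] <- length(r)
    if (length(r) > 0) {
      out$mean_r2[b] <- mean(r)
      out$sd_r2[b] <- stats::sd(r)
    }
  }
  out
}

#' Sliding-window LD means over the distance axis
#'
#' Overlapping windows of width `width_bp` advanced by `step_bp`; every pair
#' contributes to each window containing its distance.  This is the smoothed
#' r2(distance) curve used to convert LD into an effective-population-size
#' trajectory.
#'
#' @param records pair records from [pairwise_ld()].
#' @param width_bp window width (default 1 Mb).
#' @param step_bp step between window centres (default 50 kb).
#' @return Data frame (center_bp, n_pairs, mean_r2); windows with no pairs
#'   keep `NA` mean.
#' @export
sliding_ld_bins <- function(records, width_bp = 1e6, step_bp = 5e4) {
  rec <- records[!is.na(records$r2), , drop = FALSE]
  if (nrow(rec) == 0) stop("no defined r2 records")
  dmax <- max(rec$distance_bp)
  centers <- seq(width_bp / 2, max(width_bp / 2, dmax), by = step_bp)
  n <- integer(length(centers)); m <- rep(NA_real_, length(centers))
  o <- order(rec$distance_bp)
  dist <- rec$distance_bp[o]; r2 <- rec$r2[o]
  cs <- cumsum(r2)
  for (i in seq_along(centers)) {
    lo <- findInterval(centers[i] - width_bp / 2, dist, left.open = TRUE) + 1
    hi <- findInterval(centers[i] + width_bp / 2, dist)
    if (hi >= lo) {
      n[i] <- hi - lo + 1
      m[i] <- (cs[hi] - if (lo > 1) cs[lo - 1] else 0) / n[i]
    }
  }
  data.frame(center_bp = centers, n_pairs = n, mean_r2 = m)
}

# R^2 of regressing column y of X on the remaining columns (mean-imputed,
# centred).  Returns 1 when the residual is numerically zero.
window_r2 <- function(X, j) {
  y <- X[, j]
  Z <- X[, -j, drop = FALSE]
  tss <- sum(y^2)
  if (tss < 1e-12) return(0)
  keep <- colSums(Z^2) > 1e-12
  Z <- Z[, keep, drop = FALSE]
  if (ncol(Z) == 0) return(0)
  qrz <- qr(Z)
  res <- qr.resid(qrz, y)
  r2 <- 1 - sum(res^2) / tss
  max(0, min(1, r2))
}

#' Sliding-window VIF pruning of SNPs
#'
#' Within each window of `window_snps` markers (advanced by `shift_snps`),
#' SNPs are removed greedily while any retained SNP's variance inflation
#' factor `1/(1-R^2)` exceeds `vif_threshold`, where `R^2` comes from
#' regressing its (mean-imputed, centred) dosage on the other retained SNPs
#' of the window.  Ties are broken deterministically: the SNP with the
#' highest VIF goes first, and among equals the one at the later map
#' position.  A removal is global: a SNP pruned in one window stays pruned.
#' The two parameter sets in routine use are 50/5/2 (structure analyses) and
#' 50/10/1.5 (diversity indices).
#'
#' @param ds a `genotype_dataset`.
#' @param window_snps SNPs per window.
#' @param shift_snps window shift in SNPs; must be `< window_snps`.
#' @param vif_threshold VIF above which a SNP may be removed; `> 1`.
#' @return Character vector of retained SNP ids, in map order.
#' @export
vif_prune <- function(ds, window_snps = 50, shift_snps = 5, vif_threshold = 2) {
  stopifnot(inherits(ds, "genotype_dataset"),
            window_snps > shift_snps, shift_snps > 0, vif_threshold > 1)
  retained_ids <- character(0)
  for (ch in unique(ds$variants$chrom)) {
    vi <- which(ds$variants$chrom == ch)
    vi <- vi[order(ds$variants$bp[vi])]
    L <- length(vi)
    D <- ds$dosage[, vi, drop = FALSE]
    storage.mode(D) <- "double"
    for (j in seq_len(ncol(D))) {          # mean-impute and centre
      mu <- mean(D[, j], na.rm = TRUE)
      if (is.nan(mu)) mu <- 0
      D[is.na(D[, j]), j] <- mu
      D[, j] <- D[, j] - mean(D[, j])
    }
    keep <- rep(TRUE, L)
    starts <- if (L <= window_snps) 1L else seq(1L, L - 1L, by = shift_snps)
    for (s in starts) {
      win <- s:min(s + window_snps - 1L, L)
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        Xw <- D[, act, drop = FALSE]
        vifs <- vapply(seq_along(act), function(k) {
          r2 <- window_r2(Xw, k)
          if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
        }, numeric(1))
        if (max(vifs) <= vif_threshold) break
        worst <- which(vifs == max(vifs))
        drop_k <- worst[length(worst)]     # later map position on ties
        keep[act[drop_k]] <- FALSE
      }
    }
    retained_ids <- c(retained_ids, ds$variants$id[vi[keep]])
  }
  retained_ids
}
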