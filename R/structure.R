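#' Identity-by-state allele-sharing distance matrix
#'
#' For each sample pair, over mutually non-missing loci: a locus counts as
#' IBS2 when the genotypes share both alleles (|dosage difference| = 0,
#' heterozygote-heterozygote included), IBS1 when they share one
#' (difference 1), IBS0 otherwise.  The allele-sharing proportion is
#' `As = (IBS2 + 0.5 IBS1) / N` and the genetic distance `D = 1 - As`.
#'
#' @param ds a `genotype_dataset` with at least two samples.
#' @return List with `labels`, `as` (allele sharing) and `d` (distance),
#'   both symmetric with unit/zero diagonals, and `n_loci` (shared-locus
#'   counts).  A pair with no shared typed locus is an error.
#' @export
ibs_distance_matrix <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  d <- ds$dosage
  n <- nrow(d)
  if (n < 2) stop("at least two samples are required")
  storage.mode(d) <- "double"
  As <- matrix(0, n, n)
  Nm <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    xi <- d[i, ]
    for (j in (i + 1):n) {
      ok <- !is.na(xi) & !is.na(d[j, ])
      nl <- sum(ok)
      if (nl == 0) stop("samples ", ds$samples$id[i], " and ", ds$samples$id[j],
                        " share no typed locus")
      sim <- 2 - abs(xi[ok] - d[j, ok])
      As[i, j] <- As[j, i] <- sum(sim) / (2 * nl)
      Nm[i, j] <- Nm[j, i] <- nl
    }
  }
  diag(As) <- 1
  D <- 1 - As
  labels <- ds$samples$id
  dimnames(As) <- dimnames(D) <- dimnames(Nm) <- list(labels, labels)
  list(labels = labels, as = As, d = D, n_loci = Nm)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distances, eigendecomposes, and returns
#' coordinates scaled by the square root of the eigenvalues, ordered by
#' decreasing eigenvalue.  Applied to an allele-sharing distance matrix this
#' is numerically the PCA of the samples, which is why chip studies use the
#' two interchangeably.  Axis signs are fixed deterministically: the
#' largest-magnitude loading of each component is made positive.  Negative
#' eigenvalues (non-Euclidean input) are reported but never used for
#' coordinates.
#'
#' @param d symmetric distance matrix (or the list from
#'   [ibs_distance_matrix()]).
#' @param n_components number of components, `<` number of samples.
#' @return List with `points` (n x k coordinates), `eig` (all eigenvalues),
#'   `negative_eig` (the negative ones) and `labels`.
#' @export
classical_mds <- function(d, n_components = 2) {
  if (is.list(d) && !is.null(d$d)) d <- d$d
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n_components < n)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-12 & e$values > 0)
  k <- min(n_components, length(pos))
  if (k < n_components)
    warning("only ", k, " positive eigenvalues; returning ", k, " components")
  pts <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  labels <- rownames(d)
  if (!is.null(labels)) rownames(pts) <- labels
  colnames(pts) <- paste0("C", seq_len(k))
  neg_tol <- max(abs(e$values)) * 1e-10
  list(points = pts, eig = e$values,
       negative_eig = e$values[e$values < -neg_tol],
       labels = labels)
}

#' Breed-discriminant SNP panel
#'
#' A SNP enters the panel of an ordered population pair (A, B) when its
#' minor allele frequency is exactly 0 in one population (a fixed allele)
#' and above `maf_min` in the other; the returned panel is the deduplicated
#' union over all ordered pairs.  Such maximally informative markers are the
#' usual candidates for breed-assignment panels.
#'
#' @param ds a `genotype_dataset` with at least two populations.
#' @param maf_min strict lower MAF bound in the variable population
#'   (default 0.25).
#' @return List with `panel` (SNP ids, union) and `pairs` (data frame:
#'   pop_fixed, pop_variable, id).
#' @export
select_discriminant_snps <- function(ds, maf_min = 0.25) {
  parts <- split_by_population(ds)
  if (length(parts) < 2) stop("at least two populations are required")
  mafs <- vapply(parts, function(p) snp_maf(p), numeric(ncol(ds$dosage)))
  pops <- colnames(mafs)
  rows <- list()
  for (a in pops) for (b in setdiff(pops, a)) {
    sel <- which(!is.na(mafs[, a]) & !is.na(mafs[, b]) &
                   mafs[, a] == 0 & mafs[, b] > maf_min)
    if (length(sel) > 0)
      rows[[paste(a, b)]] <- data.frame(pop_fixed = a, pop_variable = b,
                                        id = ds$variants$id[sel],
                                        stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pop_fixed = character(), pop_variable = character(), id = character())
  rownames(pairs) <- NULL
  list(panel = unique(pairs$id), pairs = pairs)
}

# Internal: one EM run of the admixture model from a given start.
# G: n x J dosage matrix with NA allowed; returns Q, P, logLik, trace.
admixture_em_run <- function(G, K, max_iter, tol, p_eps = 1e-6) {
  n <- nrow(G); J <- ncol(G)
  miss <- is.na(G)
  G0 <- G; G0[miss] <- 0
  G2 <- 2 - G; G2[miss] <- 0
  Ji <- rowSums(!miss)
  Q <- matrix(stats::runif(n * K), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(stats::runif(K * J, 0.05, 0.95), K, J)
  ll_of <- function(R) {
    Rc <- pmin(pmax(R, 1e-12), 1 - 1e-12)
    sum((G0 * log(Rc) + G2 * log(1 - Rc))[!miss])
  }
  trace <- numeric(0)
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    R <- Q %*% P
    R <- pmin(pmax(R, 1e-12), 1 - 1e-12)
    A <- G0 / R
    B <- G2 / (1 - R)
    QA <- crossprod(Q, A)              # K x J
    QB <- crossprod(Q, B)
    num_p <- P * QA
    P_new <- num_p / (num_p + (1 - P) * QB)
    Q_new <- Q * (A %*% t(P) + B %*% t(1 - P)) / (2 * Ji)
    Q_new <- Q_new / rowSums(Q_new)
    P <- pmin(pmax(P_new, p_eps), 1 - p_eps)
    Q <- Q_new
    ll_new <- ll_of(Q %*% P)
    trace <- c(trace, ll_new)
    if (is.finite(ll) && abs(ll_new - ll) < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(Q = Q, P = P, logLik = ll, trace = trace)
}

#' Fit the admixture model by EM
#'
#' Each individual's genome is modelled as proportions `Q[i, ]` over `K`
#' ancestral populations with allele frequencies `P[k, j]`; genotypes are
#' binomial draws of 2 alleles with success probability `sum_k Q[i,k]
#' P[k,j]`.  The likelihood is maximised by EM (the FRAPPE-style updates),
#' iterated until the log-likelihood changes by less than `tol` or
#' `max_iter` iterations; missing genotypes are skipped in every sum.
#' Several random starts are run and the best likelihood kept.  `P` is
#' clipped to `[1e-6, 1-1e-6]` to keep the likelihood finite.
#'
#' @param ds a `genotype_dataset` (QC'd and LD-pruned) or a dosage matrix.
#' @param K number of ancestral clusters, `1 <= K <=` samples.
#' @param seed integer seed; start `s` uses `seed + s - 1`.
#' @param n_starts random restarts (default 3).
#' @param max_iter,tol EM stopping rule (defaults 2000 and 1e-6).
#' @return List of class `admixture_solution`: `K`, `Q` (rows sum to 1),
#'   `P`, `logLik`, `trace` (per-iteration log-likelihood of the winning
#'   start, non-decreasing), `seed`.
#' @export
admixture_fit <- function(ds, K, seed = 1, n_starts = 3,
                          max_iter = 2000, tol = 1e-6) {
  G <- if (inherits(ds, "genotype_dataset")) ds$dosage else as.matrix(ds)
  storage.mode(G) <- "double"
  n <- nrow(G)
  if (K > n) stop("K must not exceed the number of samples")
  stopifnot(K >= 1)
  if (K == 1) {
    p <- allele_freq(G)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    miss <- is.na(G); G0 <- G; G0[miss] <- 0; G2 <- 2 - G; G2[miss] <- 0
    ll <- sum(t(G0) * log(p) + t(G2) * log(1 - p))
    return(structure(list(K = 1L, Q = matrix(1, n, 1), P = matrix(p, 1),
                          logLik = ll, trace = ll, seed = seed),
                     class = "admixture_solution"))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seed + s - 1)
    run <- admixture_em_run(G, K, max_iter, tol)
    if (is.null(best) || run$logLik > best$logLik) best <- run
  }
  structure(list(K = as.integer(K), Q = best$Q, P = best$P,
                 logLik = best$logLik, trace = best$trace, seed = seed),
            class = "admixture_solution")
}

#' Align cluster labels of an estimated Q to a reference Q
#'
#' Searches all column permutations for the one minimising the mean absolute
#' difference; the admixture likelihood is invariant to cluster relabelling,
#' so recovery is always judged after alignment.
#'
#' @param Q estimated n x K matrix.
#' @param Q_ref reference n x K matrix.
#' @return List with `Q` (permuted), `perm`, `mae`.
#' @export
align_q <- function(Q, Q_ref) {
  K <- ncol(Q)
  perms <- permutations_of(seq_len(K))
  best <- NULL
  for (p in perms) {
    mae <- mean(abs(Q[, p, drop = FALSE] - Q_ref))
    if (is.null(best) || mae < best$mae) best <- list(Q = Q[, p, drop = FALSE], perm = p, mae = mae)
  }
  best
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

#' Cross-validated choice of the number of clusters K
#'
#' The non-missing genotype cells are partitioned into `folds` folds; each
#' fold in turn is masked (set missing), the admixture model refit, and the
#' masked cells predicted as `ghat = 2 sum_k Q[i,k] P[k,j]`.  The prediction
#' error of a K is the mean binomial deviance over all masked cells; the
#' best K minimises it (ties go to the smaller K), mirroring the masked-cell
#' "leave-one-out" cross-validation used to pick K in admixture analyses.
#'
#' @param ds a `genotype_dataset` or dosage matrix.
#' @param k_range integer vector of candidate K.
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling both the fold split and the fits.
#' @param n_starts restarts per fit (default 1; CV refits are many).
#' @param max_iter,tol EM stopping rule per fit.
#' @return List of class `cv_result`: `k` (candidates), `error` (mean
#'   deviance per K), `best_k`, `folds`, `fold_of` (fold id per non-missing
#'   cell, in column-major cell order).
#' @export
admixture_cv <- function(ds, k_range, folds = 5, seed = 1, n_starts = 1,
                         max_iter = 2000, tol = 1e-6) {
  G <- if (inherits(ds, "genotype_dataset")) ds$dosage else as.matrix(ds)
  storage.mode(G) <- "double"
  n <- nrow(G)
  stopifnot(all(k_range >= 1), all(k_range < n), folds >= 2)
  cells <- which(!is.na(G))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(cells)))
  errs <- numeric(length(k_range))
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    dev_sum <- 0; dev_n <- 0
    for (f in seq_len(folds)) {
      masked <- cells[fold_of == f]
      Gf <- G
      Gf[masked] <- NA
      fit <- admixture_fit(Gf, K, seed = seed + 1000 * ki + f,
                           n_starts = n_starts, max_iter = max_iter, tol = tol)
      Rhat <- fit$Q %*% fit$P
      ghat <- pmin(pmax(2 * Rhat[masked], 1e-9), 2 - 1e-9)
      g <- G[masked]
      term <- function(y, mu) ifelse(y > 0, y * log(y / mu), 0)
      dev_sum <- dev_sum + sum(2 * (term(g, ghat) + term(2 - g, 2 - ghat)))
      dev_n <- dev_n + length(masked)
    }
    errs[ki] <- dev_sum / dev_n
  }
  best_k <- k_range[which.min(errs)]   # which.min takes the first minimum;
  # k_range is expected increasing, so ties resolve to the smaller K
  structure(list(k = k_range, error = errs, best_k = best_k,
                 folds = folds, fold_of = fold_of, seed = seed),
            class = "cv_result")
}
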