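#' Pairwise Weir-Cockerham FST (theta) between two populations
#'
#' Per-locus variance components of the 1984 Weir & Cockerham estimator for
#' two populations at a biallelic locus — `a` (between populations), `b`
#' (between individuals within populations) and `c` (within individuals,
#' carrying the heterozygosity term) — combined into the multilocus
#' estimate as a ratio of sums, `theta = sum(a) / sum(a + b + c)`, never a
#' mean of per-locus ratios.  Loci monomorphic across both populations, or
#' with fewer than two typed individuals in either population, are excluded.
#' Negative per-locus components are kept: the ratio of sums absorbs them,
#' and small negative multilocus values are a legitimate property of the
#' estimator.
#'
#' @param ds_a,ds_b `genotype_dataset`s (or dosage matrices) over the same
#'   variants, one population each.
#' @return List with `theta`, per-locus `a`, `b`, `c`, `n_loci` used and
#'   `used` (logical per input locus).
#' @export
wc_fst_pair <- function(ds_a, ds_b) {
  da <- if (inherits(ds_a, "genotype_dataset")) ds_a$dosage else as.matrix(ds_a)
  db <- if (inherits(ds_b, "genotype_dataset")) ds_b$dosage else as.matrix(ds_b)
  if (ncol(da) != ncol(db)) stop("datasets cover different variant sets")
  n1 <- colSums(!is.na(da)); n2 <- colSums(!is.na(db))
  p1 <- allele_freq(da); p2 <- allele_freq(db)
  h1 <- colSums(da == 1L, na.rm = TRUE) / n1
  h2 <- colSums(db == 1L, na.rm = TRUE) / n2
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  use <- n1 >= 2 & n2 >= 2 & !is.na(pbar) & pbar > 0 & pbar < 1
  if (!any(use)) stop("no usable locus: need >= 2 typed individuals per population and a polymorphic pooled sample")
  n1 <- n1[use]; n2 <- n2[use]; p1 <- p1[use]; p2 <- p2[use]
  h1 <- h1[use]; h2 <- h2[use]; pbar <- pbar[use]
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  theta <- sum(a) / sum(a + b + c_)
  list(theta = theta, a = a, b = b, c = c_, n_loci = sum(use), used = use)
}

#' Pairwise FST matrix over all populations
#'
#' [wc_fst_pair()] applied to every unordered population pair; row/column
#' order follows the order of first appearance of the population labels.
#'
#' @param ds a `genotype_dataset` with at least two populations.
#' @return List of class `fst_matrix`: `labels`, `fst` (symmetric, zero
#'   diagonal), `n_loci` (loci used per pair).
#' @export
fst_matrix <- function(ds) {
  parts <- split_by_population(ds)
  pops <- names(parts)
  k <- length(pops)
  if (k < 2) stop("at least two populations are required")
  M <- matrix(0, k, k, dimnames = list(pops, pops))
  NL <- matrix(0L, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    w <- wc_fst_pair(parts[[i]], parts[[j]])
    M[i, j] <- M[j, i] <- w$theta
    NL[i, j] <- NL[j, i] <- w$n_loci
  }
  structure(list(labels = pops, fst = M, n_loci = NL), class = "fst_matrix")
}

# ---- NeighborNet ----------------------------------------------------------

# Average distance between two node sets.
nn_cluster_dist <- function(D, A, B) mean(D[A, B])

# One 3-path reduction (a-b-c) -> two replacement nodes; returns updated
# distance matrix rows for the new nodes (indices new_u, new_v in D).
nn_reduce <- function(D, a, b, c, new_u, new_v, active) {
  others <- setdiff(active, c(a, b, c))
  D[new_u, others] <- D[others, new_u] <- (2 / 3) * D[a, others] + (1 / 3) * D[b, others]
  D[new_v, others] <- D[others, new_v] <- (1 / 3) * D[b, others] + (2 / 3) * D[c, others]
  duv <- (D[a, b] + D[b, c] + D[a, c]) / 3
  D[new_u, new_v] <- D[new_v, new_u] <- duv
  D
}

# Circular ordering of taxa by the NeighborNet agglomeration: clusters of at
# most two nodes are merged by a two-stage neighbour-joining criterion
# (cluster pair by the NJ Q score on average distances, then the node pair
# within them with the clusters exploded into singletons), 3- and 4-node
# paths are collapsed by the 2/3-1/3 reduction, and the reductions are
# expanded in reverse once a single path remains and is closed into a cycle.
# Ties break to the lowest-index pair, making the ordering deterministic.
nn_ordering <- function(D0) {
  n <- nrow(D0)
  if (n <= 3) return(seq_len(n))
  max_nodes <- 6 * n
  D <- matrix(0, max_nodes, max_nodes)
  D[1:n, 1:n] <- D0
  clusters <- lapply(seq_len(n), identity)
  expansions <- list()
  next_id <- n + 1

  repeat {
    m <- length(clusters)
    if (m <= 1) break
    # unit = cluster level distances
    dc <- matrix(0, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dc[i, j] <- dc[j, i] <- nn_cluster_dist(D, clusters[[i]], clusters[[j]])
    }
    if (m == 2) {
      sel <- c(1L, 2L)
    } else {
      R <- rowSums(dc)
      Q <- (m - 2) * dc - outer(R, R, "+")
      best <- NULL
      for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        if (is.null(best) || Q[i, j] < best$q - 1e-12) best <- list(q = Q[i, j], i = i, j = j)
      }
      sel <- c(best$i, best$j)
    }
    C1 <- clusters[[sel[1]]]; C2 <- clusters[[sel[2]]]
    # node-level selection: C1 and C2 exploded into singletons, other
    # clusters kept whole
    other_idx <- setdiff(seq_len(m), sel)
    units <- c(lapply(C1, identity), lapply(C2, identity),
               clusters[other_idx])
    mu <- length(units)
    du <- matrix(0, mu, mu)
    for (i in seq_len(mu - 1)) for (j in (i + 1):mu) {
      du[i, j] <- du[j, i] <- nn_cluster_dist(D, units[[i]], units[[j]])
    }
    Ru <- rowSums(du)
    n1 <- length(C1)
    best <- NULL
    for (xi in seq_len(n1)) for (yi in seq_len(length(C2))) {
      ui <- xi; vi <- n1 + yi
      q <- (mu - 2) * du[ui, vi] - Ru[ui] - Ru[vi]
      if (is.null(best) || q < best$q - 1e-12) best <- list(q = q, x = C1[xi], y = C2[yi])
    }
    x <- best$x; y <- best$y
    # orient: x last in C1, y first in C2
    if (C1[length(C1)] != x) C1 <- rev(C1)
    if (C2[1] != y) C2 <- rev(C2)
    path <- c(C1, C2)
    active <- unlist(clusters)
    while (length(path) > 2) {
      a <- path[1]; b <- path[2]; c_ <- path[3]
      u <- next_id; v <- next_id + 1; next_id <- next_id + 2
      D <- nn_reduce(D, a, b, c_, u, v, active)
      expansions[[length(expansions) + 1]] <- c(u = u, v = v, a = a, b = b, c = c_)
      active <- c(setdiff(active, c(a, b, c_)), u, v)
      path <- c(u, v, path[-(1:3)])
    }
    clusters[[sel[1]]] <- path
    clusters[[sel[2]]] <- NULL
  }
  cycle <- clusters[[1]]
  # expand reductions in reverse
  for (k in rev(seq_along(expansions))) {
    e <- expansions[[k]]
    pos_u <- match(e["u"], cycle)
    nn_len <- length(cycle)
    nxt <- cycle[if (pos_u == nn_len) 1 else pos_u + 1]
    prv <- cycle[if (pos_u == 1) nn_len else pos_u - 1]
    if (!is.na(nxt) && nxt == e["v"]) {
      repl <- c(e["a"], e["b"], e["c"])
      pos_v <- if (pos_u == nn_len) 1 else pos_u + 1
    } else if (!is.na(prv) && prv == e["v"]) {
      repl <- c(e["c"], e["b"], e["a"])
      pos_v <- pos_u
      pos_u <- if (pos_v == 1) nn_len else pos_v - 1
      # now cycle[pos_u] == v, cycle[pos_v] == u; replace v,u with c,b,a
    } else stop("internal error: reduced pair not adjacent in cycle")
    lo <- min(pos_u, pos_v); hi <- max(pos_u, pos_v)
    if (hi - lo == 1) {
      cycle <- append(cycle[-c(lo, hi)], repl, after = lo - 1)
    } else { # wrap-around adjacency (positions 1 and n)
      cycle <- c(cycle[-c(lo, hi)], repl)
    }
    names(cycle) <- NULL
  }
  as.integer(cycle)
}

# Pair x split incidence matrix for a circular ordering.
circular_split_system <- function(order_) {
  n <- length(order_)
  sides <- list()
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    sides[[length(sides) + 1]] <- sort(order_[a:(b - 1)])
  }
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), length(sides))
  for (s in seq_along(sides)) {
    inside <- logical(n)
    inside[sides[[s]]] <- TRUE
    A[, s] <- as.numeric(xor(inside[pairs[1, ]], inside[pairs[2, ]]))
  }
  list(sides = sides, pairs = pairs, A = A)
}

#' NeighborNet split network from a distance matrix
#'
#' Builds a circular ordering of the taxa by the NeighborNet agglomeration,
#' then fits non-negative split weights for the circular split system by
#' non-negative least squares against the supplied distances.  Splits with
#' (numerically) zero weight are dropped.  For a tree-additive distance
#' matrix the output is exactly the tree's splits with weights equal to the
#' branch lengths; reticulate structure appears as additional compatible
#' circular splits.
#'
#' @param d symmetric distance matrix with labels (or an `fst_matrix`,
#'   whose FST values are used directly as distances).
#' @param weight_tol split weights at or below this are dropped (default
#'   1e-9).
#' @return List of class `split_network`: `labels`, `order` (circular, as
#'   label indices), `splits` (list of taxon-index sides), `weights`,
#'   `residual` (NNLS residual norm).
#' @export
neighbor_net <- function(d, weight_tol = 1e-9) {
  if (inherits(d, "fst_matrix")) d <- d$fst
  if (is.list(d) && !is.null(d$d)) d <- d$d
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("at least two taxa are required")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ord <- nn_ordering(d)
  css <- circular_split_system(ord)
  dv <- d[t(css$pairs)]
  fit <- pracma::lsqnonneg(css$A, dv)
  w <- fit$x
  keep <- w > weight_tol
  structure(list(labels = labels, order = ord,
                 splits = css$sides[keep], weights = w[keep],
                 residual = sqrt(sum((css$A %*% w - dv)^2))),
            class = "split_network")
}

#' @export
print.split_network <- function(x, ...) {
  cat("split_network:", length(x$labels), "taxa,", length(x$splits), "splits\n")
  cat("circular order:", paste(x$labels[x$order], collapse = " "), "\n")
  cat("NNLS residual:", signif(x$residual, 4), "\n")
  invisible(x)
}

#' Total split weight attached to each taxon's trivial split
#'
#' The weight of the split separating one taxon from all others — the
#' "branch length" of that taxon in the network; long trivial splits mark
#' divergent, low-heterozygosity populations.
#'
#' @param net a `split_network`.
#' @return Named numeric vector (0 for taxa whose trivial split was dropped).
#' @export
trivial_split_weights <- function(net) {
  n <- length(net$labels)
  out <- stats::setNames(numeric(n), net$labels)
  for (s in seq_along(net$splits)) {
    side <- net$splits[[s]]
    if (length(side) == 1) out[side] <- out[side] + net$weights[s]
    if (length(side) == n - 1) {
      lone <- setdiff(seq_len(n), side)
      out[lone] <- out[lone] + net$weights[s]
    }
  }
  out
}

#' Write a split network as a SplitsTree-compatible NEXUS file
#'
#' Emits TAXA and SPLITS blocks (with CYCLE and weighted MATRIX entries)
#' readable by standard split-network viewers.
#'
#' @param net a `split_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(net, path) {
  n <- length(net$labels)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("#NEXUS")
  wl("")
  wl("BEGIN Taxa;")
  wl("DIMENSIONS ntax=", n, ";")
  wl("TAXLABELS")
  for (i in seq_len(n)) wl("[", i, "] '", net$labels[i], "'")
  wl(";")
  wl("END; [Taxa]")
  wl("")
  wl("BEGIN Splits;")
  wl("DIMENSIONS ntax=", n, " nsplits=", length(net$splits), ";")
  wl("FORMAT labels=no weights=yes confidences=no intervals=no;")
  wl("CYCLE ", paste(net$order, collapse = " "), ";")
  wl("MATRIX")
  for (s in seq_along(net$splits)) {
    wl("[", s, ", size=", length(net$splits[[s]]), "]\t",
       format(net$weights[s], digits = 15), "\t",
       paste(net$splits[[s]], collapse = " "), ",")
  }
  wl(";")
  wl("END; [Splits]")
  invisible(path)
}

#' Read back a SPLITS-block NEXUS file written by [write_nexus()]
#'
#' Minimal parser for the TAXA/SPLITS dialect this package emits; used for
#' roundtrip checks and for re-loading saved networks.
#'
#' @param path NEXUS file.
#' @return A `split_network` (without residual).
#' @export
read_nexus_splits <- function(path) {
  lines <- readLines(path)
  lab_lines <- grep("^\\[[0-9]+\\] '", lines, value = TRUE)
  labels <- sub("^\\[[0-9]+\\] '(.*)'$", "\\1", lab_lines)
  cyc_line <- grep("^CYCLE ", lines, value = TRUE)
  order_ <- as.integer(strsplit(sub("^CYCLE ", "", sub(";$", "", cyc_line)), " +")[[1]])
  mstart <- which(lines == "MATRIX")
  mend <- which(lines == ";")
  mend <- min(mend[mend > mstart])
  splits <- list(); weights <- numeric(0)
  if (mend > mstart + 1) {
    for (ln in lines[(mstart + 1):(mend - 1)]) {
      body <- sub("^\\[[^]]*\\]\t", "", ln)
      parts <- strsplit(sub(",$", "", body), "\t")[[1]]
      weights <- c(weights, as.numeric(parts[1]))
      splits[[length(splits) + 1]] <- as.integer(strsplit(parts[2], " +")[[1]])
    }
  }
  structure(list(labels = labels, order = order_, splits = splits,
                 weights = weights, residual = NA_real_),
            class = "split_network")
}
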