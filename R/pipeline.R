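#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run, with the standard
#' chip-survey defaults: QC 0.95/0.05/0.001, pairwise LD capped at 50 Mb
#' with the conventional decay bins and 1 Mb / 50 kb sliding windows, VIF
#' pruning 50/5/2 for structure analyses and 50/10/1.5 for diversity
#' indices, Ne read at the 1 Mb bin (50 generations ago under 1 cM = 1 Mb),
#' and 5-fold cross-validated K.
#'
#' @param qc a [qc_thresholds()].
#' @param max_distance_bp pairwise-LD distance cap.
#' @param bin_edges_bp decay-profile bin edges.
#' @param sliding_width_bp,sliding_step_bp sliding-window geometry.
#' @param prune_structure,prune_diversity VIF parameter triplets
#'   `c(window, shift, threshold)`.
#' @param ne_generations target generations-ago for the headline Ne.
#' @param bp_per_morgan map conversion (default 1 cM = 1 Mb).
#' @param k_range candidate K for admixture cross-validation.
#' @param folds CV folds.
#' @param seed integer seed used by every stochastic stage.
#' @param correct_r2_sample_size apply the `1/(2n)` r2 correction before
#'   the Sved inversion (off by default).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            max_distance_bp = 5e7,
                            bin_edges_bp = default_decay_bins(),
                            sliding_width_bp = 1e6, sliding_step_bp = 5e4,
                            prune_structure = c(50, 5, 2),
                            prune_diversity = c(50, 10, 1.5),
                            ne_generations = 50, bp_per_morgan = 1e8,
                            k_range = 1:3, folds = 5, seed = 42,
                            correct_r2_sample_size = FALSE) {
  stopifnot(inherits(qc, "qc_thresholds"),
            length(prune_structure) == 3, length(prune_diversity) == 3,
            folds >= 2, all(k_range >= 1))
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 10)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Reproduces the complete chip-survey analysis graph on one dataset.
#' Within each population: QC, adjacent-SNP LD, pairwise LD with decay
#' profile and sliding bins, diversity indices on the 50/10/1.5-pruned set,
#' individual inbreeding, and the LD-based Ne trajectory.  Across
#' populations (on the intersection of SNPs surviving QC in every
#' population, 50/5/2-pruned): IBS allele-sharing distances, classical MDS,
#' admixture with cross-validated K, pairwise Weir-Cockerham FST, and the
#' NeighborNet split network exported as NEXUS.  Every artifact is written
#' as TSV/JSON/NEXUS under `out_dir` and a manifest records stage
#' parameters and output checksums; given the same input and seed the
#' output files are byte-identical.
#'
#' @param ds a `genotype_dataset` (or a PLINK path prefix).
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with all stage results (`qc`, `adjacent_ld`,
#'   `decay`, `diversity`, `ne`, `mds`, `cv`, `admixture`, `fst`,
#'   `network`, `manifest`).
#' @export
run_pipeline <- function(ds, config = pipeline_config(), out_dir) {
  if (is.character(ds)) ds <- read_plink(ds)
  stopifnot(inherits(ds, "genotype_dataset"), inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  res <- list()
  pops <- unique(ds$samples$population)

  # --- per-population: QC ---------------------------------------------------
  per_pop <- list()
  res$qc <- list()
  for (p in pops) {
    sub <- subset_dataset(ds, samples = ds$samples$population == p)
    q <- stage(paste0("qc:", p), apply_qc(sub, config$qc))
    per_pop[[p]] <- q$dataset
    res$qc[[p]] <- q$report
    write_qc_report(q$report, file.path(out_dir, paste0("qc_", p)))
  }

  # --- per-population: LD, diversity, Ne -----------------------------------
  adj_rows <- list(); decay_rows <- list(); ne_rows <- list(); div_rows <- list()
  res$adjacent_ld <- list(); res$decay <- list(); res$ne <- list()
  for (p in pops) {
    dsp <- per_pop[[p]]
    adj <- stage(paste0("adjacent_ld:", p), adjacent_ld_summary(dsp))
    res$adjacent_ld[[p]] <- adj
    adj_rows[[p]] <- cbind(population = p, adj$by_chromosome)
    pw <- stage(paste0("pairwise_ld:", p), pairwise_ld(dsp, config$max_distance_bp))
    dec <- stage(paste0("decay:", p), ld_decay_profile(pw, config$bin_edges_bp))
    res$decay[[p]] <- dec
    decay_rows[[p]] <- cbind(population = p, dec)
    sl <- stage(paste0("sliding:", p),
                sliding_ld_bins(pw, config$sliding_width_bp, config$sliding_step_bp))
    traj <- stage(paste0("ne:", p),
                  ne_trajectory(sl, config$bp_per_morgan,
                                sample_size = nrow(dsp$dosage),
                                correct_sample_size = config$correct_r2_sample_size))
    res$ne[[p]] <- traj
    ne_rows[[p]] <- cbind(population = p, traj)

    keep_div <- stage(paste0("prune_diversity:", p),
                      vif_prune(dsp, config$prune_diversity[1],
                                config$prune_diversity[2], config$prune_diversity[3]))
    dsd <- subset_dataset(dsp, variants = match(keep_div, dsp$variants$id))
    dv <- stage(paste0("diversity:", p), snp_diversity(dsd))
    fi <- stage(paste0("inbreeding:", p), individual_inbreeding(dsd))
    t_target <- config$ne_generations
    c_target <- 1 / (2 * t_target)
    i_bin <- which.min(abs(traj$generations_ago - t_target))
    div_rows[[p]] <- cbind(data.frame(population = p, n_ind = nrow(dsd$dosage),
                                      n_snps_pruned = length(keep_div)),
                           dv$summary[, c("mean_maf", "sd_maf", "mean_ho", "sd_ho",
                                          "mean_he", "sd_he")],
                           data.frame(mean_f = mean(fi$f), sd_f = stats::sd(fi$f),
                                      ne = traj$ne[i_bin],
                                      ne_generations_ago = traj$generations_ago[i_bin]))
  }
  res$diversity <- do.call(rbind, div_rows)
  write_tsv(do.call(rbind, adj_rows), file.path(out_dir, "adjacent_ld.tsv"))
  write_tsv(do.call(rbind, decay_rows), file.path(out_dir, "ld_decay.tsv"))
  write_tsv(do.call(rbind, ne_rows), file.path(out_dir, "ne_trajectory.tsv"))
  write_tsv(res$diversity, file.path(out_dir, "diversity.tsv"))

  # --- cross-population: intersection, pruning, structure ------------------
  common <- Reduce(intersect, lapply(per_pop, function(d) d$variants$id))
  cross <- subset_dataset(ds, variants = match(common, ds$variants$id))
  res$n_common_snps <- length(common)
  keep_str <- stage("prune_structure",
                    vif_prune(cross, config$prune_structure[1],
                              config$prune_structure[2], config$prune_structure[3]))
  cross_p <- subset_dataset(cross, variants = match(keep_str, cross$variants$id))

  ibs <- stage("ibs", ibs_distance_matrix(cross_p))
  mds <- stage("mds", classical_mds(ibs$d, n_components = min(3, nrow(ibs$d) - 1)))
  res$mds <- mds
  write_tsv(cbind(data.frame(id = rownames(mds$points),
                             population = cross_p$samples$population),
                  as.data.frame(mds$points)),
            file.path(out_dir, "mds_coordinates.tsv"))

  cv <- stage("admixture_cv",
              admixture_cv(cross_p, config$k_range, folds = config$folds,
                           seed = config$seed))
  res$cv <- cv
  write_tsv(data.frame(k = cv$k, cv_error = cv$error), file.path(out_dir, "cv_error.tsv"))
  fit <- stage("admixture_fit",
               admixture_fit(cross_p, cv$best_k, seed = config$seed))
  res$admixture <- fit
  qdf <- cbind(data.frame(id = cross_p$samples$id,
                          population = cross_p$samples$population),
               as.data.frame(fit$Q))
  names(qdf)[-(1:2)] <- paste0("q", seq_len(fit$K))
  write_tsv(qdf, file.path(out_dir, "admixture_q.tsv"))

  if (length(pops) >= 2) {
    fst <- stage("fst", fst_matrix(cross))
    res$fst <- fst
    write_tsv(cbind(data.frame(population = fst$labels), as.data.frame(fst$fst)),
              file.path(out_dir, "fst_matrix.tsv"))
    if (length(pops) >= 4) {
      net <- stage("neighbor_net", neighbor_net(fst))
      res$network <- net
      write_nexus(net, file.path(out_dir, "fst_network.nex"))
    }
  }

  # --- manifest -------------------------------------------------------------
  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    n_samples = nrow(ds$dosage), n_variants_input = ncol(ds$dosage),
    populations = as.list(stats::setNames(
      vapply(pops, function(p) sum(ds$samples$population == p), integer(1)), pops)),
    seed = config$seed,
    parameters = list(
      qc = unclass(config$qc)[c("min_call", "min_maf", "min_hwe_p")],
      max_distance_bp = config$max_distance_bp,
      prune_structure = config$prune_structure,
      prune_diversity = config$prune_diversity,
      k_range = config$k_range, folds = config$folds,
      ne_generations = config$ne_generations),
    outputs = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
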