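#' Construct a genotype dataset
#'
#' The central data container of the pipeline: a samples x variants dosage
#' matrix holding 0/1/2 copies of each variant's B allele (`NA` = missing
#' call), together with the marker map and the sample sheet.
#'
#' @param dosage integer matrix, samples in rows, variants in columns; values
#'   in `{0, 1, 2, NA}` counting copies of `alleleB`.
#' @param variants data frame with columns `chrom` (chromosome label; sheep
#'   autosomes are `1..26` or `"OARn"`, `"0"` = unmapped), `id`, `cm`
#'   (genetic position, centiMorgan), `bp` (physical position, 1-based),
#'   `alleleA`, `alleleB`.
#' @param samples data frame with columns `family`, `id` and optionally
#'   `population`; when `population` is absent the family identifier is used
#'   as the population label, the usual convention in PED files from breed
#'   surveys.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_v <- c("chrom", "id", "cm", "bp", "alleleA", "alleleB")
  missing_v <- setdiff(need_v, names(variants))
  if (length(missing_v) > 0)
    stop("variants is missing column(s): ", paste(missing_v, collapse = ", "))
  if (!all(c("family", "id") %in% names(samples)))
    stop("samples must have columns 'family' and 'id'")
  if (is.null(samples$population)) samples$population <- as.character(samples$family)
  variants$chrom <- as.character(variants$chrom)
  variants$id <- as.character(variants$id)
  samples$family <- as.character(samples$family)
  samples$id <- as.character(samples$id)
  samples$population <- as.character(samples$population)
  if (nrow(dosage) != nrow(samples))
    stop("dosage has ", nrow(dosage), " rows but samples has ", nrow(samples))
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but variants has ", nrow(variants))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L))
    stop("dosage values must be 0, 1, 2 or NA")
  if (anyDuplicated(paste(samples$family, samples$id)))
    stop("(family, id) pairs must be unique")
  rownames(dosage) <- samples$id
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$dosage), "samples x", ncol(x$dosage), "variants\n")
  pops <- table(x$samples$population)
  cat("populations:", paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  cat("chromosomes:", length(unique(x$variants$chrom)),
      "| missing rate:", signif(mean(is.na(x$dosage)), 3), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosage)

#' Subset a genotype dataset by samples and/or variants
#'
#' @param ds a `genotype_dataset`.
#' @param samples,variants logical, integer or character index into the sample
#'   / variant lists; `NULL` keeps everything.
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, variants = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(ds$dosage)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(ds$dosage)) else variants
  if (is.character(si)) si <- match(si, ds$samples$id)
  if (is.character(vi)) vi <- match(vi, ds$variants$id)
  genotype_dataset(ds$dosage[si, vi, drop = FALSE],
                   ds$variants[vi, , drop = FALSE],
                   ds$samples[si, , drop = FALSE])
}

#' Split a dataset by population label
#'
#' @param ds a `genotype_dataset`.
#' @return Named list of `genotype_dataset`, one per population, in order of
#'   first appearance.
#' @export
split_by_population <- function(ds) {
  pops <- unique(ds$samples$population)
  out <- lapply(pops, function(p) subset_dataset(ds, samples = ds$samples$population == p))
  names(out) <- pops
  out
}

# Normalise a chromosome label: "OAR3"/"oar3" -> "3", otherwise unchanged.
chrom_number <- function(chrom) {
  x <- sub("^[Oo][Aa][Rr]", "", as.character(chrom))
  suppressWarnings(as.numeric(x))
}

#' Is a chromosome label an autosome?
#'
#' @param chrom character vector of chromosome labels (`"3"` or `"OAR3"`).
#' @param autosomes integer set of autosome numbers (sheep: `1:26`).
#' @return Logical vector.
#' @export
is_autosome <- function(chrom, autosomes = 1:26) {
  n <- chrom_number(chrom)
  !is.na(n) & n %in% autosomes
}

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read PLINK genotypes
#'
#' Reads a PED/MAP text pair or a BED/BIM/FAM binary triplet into a
#' [genotype_dataset()].  Dosage counts copies of the B allele: for binary
#' files the B allele is the second allele column of the BIM file; for text
#' files the two alleles observed at a locus are assigned alphabetically
#' (`alleleA` < `alleleB`), since MAP files carry no allele columns.  Missing
#' genotypes ("0 0" in PED, the 01 code in BED) become `NA`.
#'
#' @param prefix path prefix; `<prefix>.ped/.map` or `<prefix>.bed/.bim/.fam`.
#' @param format `"text"`, `"binary"`, or `"auto"` (detect by file presence,
#'   binary preferred).
#' @return A `genotype_dataset`; variant order follows the MAP/BIM file.
#' @export
read_plink <- function(prefix, format = c("auto", "text", "binary")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(paste0(prefix, ".bed"))) "binary" else "text"
  }
  if (format == "text") read_plink_text(prefix) else read_plink_binary(prefix)
}

read_map_like <- function(path, n_cols) {
  if (length(readLines(path, n = 1)) == 0) {     # zero-variant file
    tab <- as.data.frame(matrix(character(0), 0, n_cols))
    return(tab)
  }
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(tab) != n_cols)
    stop(basename(path), " has ", ncol(tab), " columns; expected ", n_cols)
  tab
}

read_plink_text <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  map <- read_map_like(map_path, 4)
  n_var <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_samp <- length(lines)
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6 + 2 * n_var
  for (i in seq_len(n_samp)) {
    if (length(fields[[i]]) != expected)
      stop(basename(ped_path), " line ", i, " has ", length(fields[[i]]),
           " fields; expected ", expected, " for ", n_var, " variants")
  }
  a1 <- matrix("", n_samp, n_var)
  a2 <- matrix("", n_samp, n_var)
  if (n_var > 0) {
    for (i in seq_len(n_samp)) {
      g <- fields[[i]][-(1:6)]
      a1[i, ] <- g[seq(1, length(g), by = 2)]
      a2[i, ] <- g[seq(2, length(g), by = 2)]
    }
  }
  meta <- t(vapply(fields, function(f) f[1:2], character(2)))
  dosage <- matrix(NA_integer_, n_samp, n_var)
  alleleA <- character(n_var)
  alleleB <- character(n_var)
  for (j in seq_len(n_var)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(unique(obs[obs != "0"]))
    if (length(alleles) > 2)
      stop("locus ", map[j, 2], " has ", length(alleles), " alleles: ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0) alleles <- c("0", "0")
    if (length(alleles) == 1) alleles <- c("0", alleles)  # monomorphic: B = the observed allele
    alleleA[j] <- alleles[1]
    alleleB[j] <- alleles[2]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == alleles[2]) + (a2[, j] == alleles[2])
    d[miss] <- NA_integer_
    dosage[, j] <- d
  }
  variants <- data.frame(chrom = map[, 1], id = map[, 2],
                         cm = as.numeric(map[, 3]), bp = as.numeric(map[, 4]),
                         alleleA = alleleA, alleleB = alleleB,
                         stringsAsFactors = FALSE)
  samples <- data.frame(family = meta[, 1], id = meta[, 2], stringsAsFactors = FALSE)
  genotype_dataset(dosage, variants, samples)
}

read_plink_binary <- function(prefix) {
  bim <- read_map_like(paste0(prefix, ".bim"), 6)
  fam <- read_map_like(paste0(prefix, ".fam"), 6)
  n_var <- nrow(bim)
  n_samp <- nrow(fam)
  bed_path <- paste0(prefix, ".bed")
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], PLINK_MAGIC))
    stop(basename(bed_path), ": bad magic bytes; not a PLINK .bed file")
  bytes_per_var <- ceiling(n_samp / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_var * n_var)
    stop(basename(bed_path), " has ", length(body), " data bytes; expected ",
         bytes_per_var * n_var, " for ", n_samp, " samples x ", n_var,
         " variants (SNP-major)")
  # decode 2-bit fields: 00 hom-A1, 01 missing, 10 het, 11 hom-A2
  ints <- as.integer(body)
  codes <- matrix(NA_integer_, 4 * bytes_per_var, n_var)
  m <- matrix(ints, bytes_per_var, n_var)
  for (k in 0:3) {
    codes[seq(k + 1, 4 * bytes_per_var, by = 4), ] <-
      bitwAnd(bitwShiftR(m, 2L * k), 3L)
  }
  codes <- codes[seq_len(n_samp), , drop = FALSE]
  lookup <- c(0L, NA_integer_, 1L, 2L)   # dosage of A2 (= alleleB)
  dosage <- matrix(lookup[codes + 1L], n_samp, n_var)
  variants <- data.frame(chrom = bim[, 1], id = bim[, 2],
                         cm = as.numeric(bim[, 3]), bp = as.numeric(bim[, 4]),
                         alleleA = bim[, 5], alleleB = bim[, 6],
                         stringsAsFactors = FALSE)
  samples <- data.frame(family = fam[, 1], id = fam[, 2], stringsAsFactors = FALSE)
  genotype_dataset(dosage, variants, samples)
}

#' Write PLINK genotypes
#'
#' Writes a [genotype_dataset()] as PED/MAP text or BED/BIM/FAM binary
#' (SNP-major, magic bytes `6c 1b 01`).  `read_plink()` on the output
#' reproduces the dosage matrix exactly for the binary dialect always, and
#' for the text dialect whenever `alleleA` sorts before `alleleB` (text files
#' carry no allele ordering, so the reader assigns alleles alphabetically).
#'
#' @param ds a `genotype_dataset`.
#' @param prefix output path prefix.
#' @param format `"text"` or `"binary"`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(ds, prefix, format = c("text", "binary")) {
  stopifnot(inherits(ds, "genotype_dataset"))
  format <- match.arg(format)
  v <- ds$variants
  s <- ds$samples
  if (format == "text") {
    utils::write.table(v[, c("chrom", "id", "cm", "bp")],
                       paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    n <- nrow(ds$dosage)
    ped <- character(n)
    for (i in seq_len(n)) {
      d <- ds$dosage[i, ]
      g1 <- ifelse(is.na(d), "0", ifelse(d >= 1, v$alleleB, v$alleleA))
      g2 <- ifelse(is.na(d), "0", ifelse(d == 2, v$alleleB, v$alleleA))
      ped[i] <- paste(c(s$family[i], s$id[i], "0", "0", "0", "-9",
                        as.vector(rbind(g1, g2))), collapse = " ")
    }
    writeLines(ped, paste0(prefix, ".ped"))
  } else {
    utils::write.table(v[, c("chrom", "id", "cm", "bp", "alleleA", "alleleB")],
                       paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    fam <- data.frame(s$family, s$id, 0, 0, 0, -9)
    utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    n_samp <- nrow(ds$dosage)
    n_var <- ncol(ds$dosage)
    bytes_per_var <- ceiling(n_samp / 4)
    code_of <- c(0L, 2L, 3L)              # dosage 0/1/2 -> 2-bit code
    out <- raw(bytes_per_var * n_var)
    for (j in seq_len(n_var)) {
      d <- ds$dosage[, j]
      code <- ifelse(is.na(d), 1L, code_of[d + 1L])
      length(code) <- 4 * bytes_per_var   # pad with NA -> treated as 0 below
      code[is.na(code) & seq_along(code) > n_samp] <- 0L
      cm <- matrix(code, 4, bytes_per_var)
      byte <- cm[1, ] + bitwShiftL(cm[2, ], 2L) +
        bitwShiftL(cm[3, ], 4L) + bitwShiftL(cm[4, ], 6L)
      out[((j - 1) * bytes_per_var + 1):(j * bytes_per_var)] <- as.raw(byte)
    }
    con <- file(paste0(prefix, ".bed"), "wb")
    writeBin(PLINK_MAGIC, con)
    writeBin(out, con)
    close(con)
  }
  invisible(prefix)
}
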