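# Genotype containers and readers/writers.
#
# A genotype_matrix stores alt-allele dosages (0, 1, 2, NA) for samples x
# loci; an allele_freq_table stores per (group, locus) alt-allele frequency
# and the number of non-missing chromosomes behind it.  These two objects
# are the substrate of every statistic in the package.

#' Construct a locus table
#'
#' A panel is described by a data frame of biallelic loci.  Reference and
#' alternate alleles are taken exactly as written; the package never flips
#' strands or harmonizes alleles.
#'
#' @param rsid Character vector of unique locus identifiers.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based base positions.
#' @param ref,alt Single-character reference and alternate alleles.
#' @return A `data.frame` with columns `rsid`, `chrom`, `pos`, `ref`, `alt`.
#' @export
locus_table <- function(rsid, chrom = "1", pos = seq_along(rsid),
                        ref = "A", alt = "G") {
  n <- length(rsid)
  df <- data.frame(rsid = as.character(rsid),
                   chrom = rep_len(as.character(chrom), n),
                   pos = as.integer(rep_len(pos, n)),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n),
                   stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(df$rsid), "duplicated rsid in locus table")
  assert_that(all(df$ref != df$alt), "ref allele equals alt allele at %s",
              paste(df$rsid[df$ref == df$alt], collapse = ", "))
  df
}

#' Construct a genotype matrix
#'
#' @param codes Integer matrix (samples x loci) of alt-allele dosages in
#'   \{0, 1, 2\}; `NA` marks a missing genotype.  Row names are sample
#'   identifiers, column names locus rsids.
#' @param loci Optional locus table (see [locus_table()]); defaults to a
#'   placeholder panel built from the column names.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, loci = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) == 0 && is.null(rownames(codes)))
    rownames(codes) <- character(0)
  else
    assert_that(!is.null(rownames(codes)), "codes must have sample row names")
  assert_that(!is.null(colnames(codes)), "codes must have rsid column names")
  assert_that(!anyDuplicated(rownames(codes)), "duplicated sample identifiers")
  bad <- !(codes %in% c(0L, 1L, 2L, NA_integer_))
  assert_that(!any(bad), "genotype codes must be 0, 1, 2 or NA")
  if (is.null(loci)) loci <- locus_table(colnames(codes))
  assert_that(identical(loci$rsid, colnames(codes)),
              "locus table does not match genotype columns")
  structure(list(codes = codes, loci = loci), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d missing calls)\n",
              nrow(x$codes), ncol(x$codes), sum(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

samples_of <- function(gm) rownames(gm$codes)
rsids_of <- function(gm) colnames(gm$codes)

#' Subset a genotype matrix by sample and/or locus
#' @param gm A `genotype_matrix`.
#' @param samples,rsids Character vectors naming the rows/columns to keep.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, samples = NULL, rsids = NULL) {
  codes <- gm$codes
  if (!is.null(samples)) codes <- codes[samples, , drop = FALSE]
  if (!is.null(rsids)) codes <- codes[, rsids, drop = FALSE]
  genotype_matrix(codes, gm$loci[match(colnames(codes), gm$loci$rsid), ,
                                 drop = FALSE])
}

#' Construct a population manifest
#'
#' Maps each sample to a population and each population to a
#' super-population (continental) label, e.g. AFR/AMR/EAS/EUR/SAS.
#'
#' @param sample,population,super_population Character vectors of equal
#'   length (one row per sample).
#' @return A `data.frame` of class `population_manifest`.
#' @export
population_manifest <- function(sample, population, super_population) {
  df <- data.frame(sample = as.character(sample),
                   population = as.character(population),
                   super_population = as.character(super_population),
                   stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(df$sample), "duplicated samples in manifest")
  p2s <- unique(df[, c("population", "super_population")])
  assert_that(!anyDuplicated(p2s$population),
              "population mapped to more than one super-population")
  class(df) <- c("population_manifest", "data.frame")
  df
}

manifest_groups <- function(manifest, gm,
                            level = c("population", "super_population",
                                      "pooled")) {
  level <- match.arg(level)
  idx <- match(samples_of(gm), manifest$sample)
  assert_that(!anyNA(idx), "samples missing from manifest: %s",
              paste(utils::head(samples_of(gm)[is.na(idx)], 5), collapse = ", "))
  if (level == "pooled") rep("ALL", nrow(gm$codes)) else manifest[[level]][idx]
}

#' Read / write a TSV genotype matrix
#'
#' Dialect: tab-separated, header row of locus rsids, first column `sample`,
#' cells in \{0, 1, 2, NA\}.  `write_genotypes_tsv()` and
#' `read_genotypes_tsv()` round-trip bit-exactly.
#'
#' @param path File path.
#' @return A `genotype_matrix`.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", na.strings = "NA")
  assert_that(nrow(df) > 0, "no samples in %s", path)
  assert_that(ncol(df) >= 2, "no loci in %s", path)
  codes <- as.matrix(df[, -1, drop = FALSE])
  rownames(codes) <- df[[1]]
  ok <- codes %in% c("0", "1", "2", NA_character_)
  if (any(!ok)) {
    bad <- which(!ok, arr.ind = FALSE)[1]
    rc <- arrayInd(bad, dim(codes))
    stop_aisnp("invalid genotype code '%s' at sample %s, locus %s",
               codes[bad], rownames(codes)[rc[1]], colnames(codes)[rc[2]])
  }
  storage.mode(codes) <- "integer"
  genotype_matrix(codes)
}

#' @rdname read_genotypes_tsv
#' @param gm A `genotype_matrix`.
#' @export
write_genotypes_tsv <- function(gm, path) {
  df <- data.frame(sample = samples_of(gm), gm$codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a population manifest TSV
#'
#' Columns: `sample`, `population`, `super_population`.
#' @param path File path.
#' @return A `population_manifest`.
#' @export
read_manifest_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  assert_that(all(c("sample", "population", "super_population") %in%
                    names(df)), "manifest must have sample/population/super_population columns")
  population_manifest(df$sample, df$population, df$super_population)
}

#' @rdname read_manifest_tsv
#' @param manifest A `population_manifest`.
#' @export
write_manifest_tsv <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses diploid GT fields into alt-allele dosages.  Multiallelic records
#' are skipped (with a warning) or rejected.  Missing and half calls
#' (`./.`, `0/.`) become `NA`.  When a `panel` is supplied, records outside
#' the panel are dropped; panel loci absent from the file are recorded in
#' the `missing_loci` attribute, and a ref/alt mismatch between panel and
#' file is a hard error (silent strand flips corrupt frequencies).
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param panel Optional locus table restricting and validating the loci.
#' @param multiallelic Either "skip" (default) or "error".
#' @return A `genotype_matrix`; attribute `missing_loci` lists panel rsids
#'   not found in the file.
#' @export
read_genotypes_vcf <- function(path, panel = NULL,
                               multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  multi <- nalt != 1L
  if (any(multi)) {
    if (multiallelic == "error")
      stop_aisnp("multiallelic record(s): %s",
                 paste(utils::head(rownames(vcf)[multi], 5), collapse = ", "))
    warning(sprintf("skipping %d multiallelic record(s)", sum(multi)),
            call. = FALSE)
    vcf <- vcf[!multi]
  }
  assert_that(nrow(vcf) > 0, "no biallelic records in %s", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  loci <- locus_table(
    rsid = rownames(vcf),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(VariantAnnotation::alt(vcf))))
  gt <- VariantAnnotation::geno(vcf)$GT
  assert_that(!is.null(gt), "VCF %s has no GT field", path)
  codes <- gt_to_dosage(gt)          # loci x samples
  codes <- t(codes)
  colnames(codes) <- loci$rsid
  missing_loci <- character(0)
  if (!is.null(panel)) {
    keep <- intersect(panel$rsid, loci$rsid)
    missing_loci <- setdiff(panel$rsid, loci$rsid)
    assert_that(length(keep) > 0, "no panel loci found in %s", path)
    li <- match(keep, loci$rsid)
    pi <- match(keep, panel$rsid)
    mism <- panel$ref[pi] != loci$ref[li] | panel$alt[pi] != loci$alt[li]
    assert_that(!any(mism), "ref/alt mismatch between panel and VCF at %s",
                paste(keep[mism], collapse = ", "))
    codes <- codes[, keep, drop = FALSE]
    loci <- loci[li, , drop = FALSE]
  }
  gm <- genotype_matrix(codes, loci)
  attr(gm, "missing_loci") <- missing_loci
  gm
}

# "0/1", "1|1", "./.", "0/." -> dosage; any missing allele voids the call.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(s) {
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    if (!all(al %in% c("0", "1")))
      stop_aisnp("non-biallelic allele index in GT '%s'", s)
    sum(al == "1")
  }, integer(1))
  out <- map[match(as.vector(gt), u)]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Write genotypes as a minimal VCF
#'
#' Emits VCFv4.2 with unphased GT only, one biallelic record per panel
#' locus, suitable for re-reading with [read_genotypes_vcf()].
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(gm, path) {
  loci <- gm$loci
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(gm$codes), ncol = nrow(gm$codes))
  obs <- !is.na(t(gm$codes))
  gt[obs] <- gtmap[t(gm$codes)[obs] + 1L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=aisnp",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples_of(gm)), collapse = "\t")),
             con)
  body <- cbind(loci$chrom, loci$pos, loci$rsid, loci$ref, loci$alt,
                ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Allele frequencies by group
#'
#' Computes per (group, locus) alt-allele frequencies from diploid dosages:
#' `alt_freq = sum(codes) / (2 * n_non_missing)`, `n_chrom = 2 *
#' n_non_missing`.  Missing genotypes contribute to neither numerator nor
#' denominator; a cell with zero non-missing calls has `alt_freq = NaN`
#' (undefined) and `n_chrom = 0`.
#'
#' @param gm A `genotype_matrix`.
#' @param manifest A `population_manifest` covering all samples.
#' @param level Grouping level: `"population"`, `"super_population"`, or
#'   `"pooled"` (a single group of all samples).
#' @return An `allele_freq_table`: list with `groups`, `rsids`, matrices
#'   `alt_freq` and `n_chrom` (groups x loci).
#' @export
allele_frequencies <- function(gm, manifest,
                               level = c("population", "super_population",
                                         "pooled")) {
  level <- match.arg(level)
  grp <- manifest_groups(manifest, gm, level)
  labels <- unique(grp)
  alt <- matrix(NA_real_, length(labels), ncol(gm$codes),
                dimnames = list(labels, rsids_of(gm)))
  nchrom <- matrix(0L, length(labels), ncol(gm$codes),
                   dimnames = list(labels, rsids_of(gm)))
  for (g in labels) {
    sub <- gm$codes[grp == g, , drop = FALSE]
    nc <- 2L * colSums(!is.na(sub))
    alt[g, ] <- ifelse(nc > 0, colSums(sub, na.rm = TRUE) / nc, NaN)
    nchrom[g, ] <- nc
  }
  allele_freq_table(alt, nchrom)
}

#' Construct an allele frequency table directly
#' @param alt_freq Numeric matrix (groups x loci) of alt-allele frequencies
#'   in \[0, 1\] (`NaN` for undefined cells).
#' @param n_chrom Integer matrix of non-missing chromosome counts.
#' @return An `allele_freq_table`.
#' @export
allele_freq_table <- function(alt_freq, n_chrom = NULL) {
  alt_freq <- as.matrix(alt_freq)
  assert_that(!is.null(rownames(alt_freq)), "alt_freq needs group row names")
  assert_that(!is.null(colnames(alt_freq)), "alt_freq needs rsid column names")
  if (is.null(n_chrom))
    n_chrom <- matrix(2L, nrow(alt_freq), ncol(alt_freq),
                      dimnames = dimnames(alt_freq))
  ok <- is.nan(alt_freq) | (alt_freq >= 0 & alt_freq <= 1)
  assert_that(all(ok, na.rm = TRUE), "alt_freq outside [0,1]")
  structure(list(groups = rownames(alt_freq), rsids = colnames(alt_freq),
                 alt_freq = alt_freq, n_chrom = n_chrom),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d groups x %d loci\n",
              length(x$groups), length(x$rsids)))
  invisible(x)
}

#' Pool groups for one-vs-rest analyses
#'
#' Splits a frequency table into the target group's frequencies and the
#' pooled frequencies of all remaining groups, as used for the
#' "one continent vs the other four" comparisons.  By default pooling is
#' chromosome-count weighted (equivalent to pooling the raw samples); set
#' `weighted = FALSE` for an unweighted mean of group frequencies.
#'
#' @param aft An `allele_freq_table`.
#' @param target A group label present in `aft`.
#' @param weighted Logical; chromosome-weighted pooling (default).
#' @return List with numeric vectors `target` and `rest` (per locus) and
#'   chromosome counts `n_target`, `n_rest`.
#' @export
pool_groups <- function(aft, target, weighted = TRUE) {
  assert_that(target %in% aft$groups, "unknown group '%s'", target)
  assert_that(length(aft$groups) >= 2, "need at least two groups to pool")
  rest <- setdiff(aft$groups, target)
  f <- aft$alt_freq[rest, , drop = FALSE]
  n <- aft$n_chrom[rest, , drop = FALSE]
  if (weighted) {
    counts <- colSums(f * n, na.rm = TRUE)
    tot <- colSums(n * !is.nan(f))
    rest_f <- ifelse(tot > 0, counts / tot, NaN)
  } else {
    rest_f <- colMeans(f, na.rm = TRUE)
    rest_f[colSums(!is.nan(f)) == 0] <- NaN
  }
  list(target = aft$alt_freq[target, ], rest = rest_f,
       n_target = aft$n_chrom[target, ],
       n_rest = colSums(n * !is.nan(f)))
}

#' Write / read an allele frequency table as TSV
#'
#' Long format: `group`, `rsid`, `alt_freq`, `n_chrom`.
#' @param aft An `allele_freq_table`.
#' @param path File path.
#' @export
write_freq_tsv <- function(aft, path) {
  df <- data.frame(group = rep(aft$groups, times = length(aft$rsids)),
                   rsid = rep(aft$rsids, each = length(aft$groups)),
                   alt_freq = as.vector(aft$alt_freq),
                   n_chrom = as.vector(aft$n_chrom))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_tsv
#' @export
read_freq_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  groups <- unique(df$group)
  rsids <- unique(df$rsid)
  alt <- matrix(NaN, length(groups), length(rsids),
                dimnames = list(groups, rsids))
  nch <- matrix(0L, length(groups), length(rsids),
                dimnames = list(groups, rsids))
  alt[cbind(df$group, df$rsid)] <- df$alt_freq
  nch[cbind(df$group, df$rsid)] <- df$n_chrom
  allele_freq_table(alt, nch)
}
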