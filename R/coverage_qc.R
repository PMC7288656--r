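# Sequencing coverage QC: depth of coverage (DOC) per call/locus and the
# allele coverage ratio (ACR), the heterozygote balance minor/major depth.

#' Read / write an allele depth table
#'
#' TSV columns: `sample`, `rsid`, `ref_depth`, `alt_depth` (non-negative
#' integers, one row per call).
#' @param path File path.
#' @return A data frame.
#' @export
read_depth_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  assert_that(all(c("sample", "rsid", "ref_depth", "alt_depth") %in%
                    names(df)), "depth table needs sample/rsid/ref_depth/alt_depth")
  assert_that(all(df$ref_depth >= 0) && all(df$alt_depth >= 0),
              "depths must be non-negative")
  assert_that(!anyDuplicated(df[, c("sample", "rsid")]),
              "duplicated (sample, rsid) in depth table")
  df
}

#' @rdname read_depth_tsv
#' @param adt An allele depth table.
#' @export
write_depth_tsv <- function(adt, path) {
  utils::write.table(adt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-locus depth of coverage
#'
#' DOC of a call is `ref_depth + alt_depth`; per locus the arithmetic mean
#' over all recorded calls and the minimum are reported.  Loci with no
#' records are absent from the summary.
#'
#' @param adt An allele depth table (see [read_depth_tsv()]).
#' @return Data frame: `rsid`, `mean_doc`, `min_doc`, `n_calls`.
#' @export
compute_doc <- function(adt) {
  assert_that(nrow(adt) > 0, "empty depth table")
  doc <- adt$ref_depth + adt$alt_depth
  agg <- split(doc, adt$rsid)
  data.frame(rsid = names(agg),
             mean_doc = vapply(agg, mean, 0),
             min_doc = vapply(agg, min, 0),
             n_calls = lengths(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-locus allele coverage ratio
#'
#' ACR of a heterozygous call is `min(ref_depth, alt_depth) / max(...)`;
#' the per-locus mean is taken over heterozygous calls only (the ratio is
#' meaningless for homozygotes).  Loci with no heterozygous calls get
#' `mean_acr = NA` (undefined), mirroring panels where a locus is
#' homozygous in every individual.
#'
#' @param adt An allele depth table.
#' @param gm The matching `genotype_matrix` (supplies the genotype of each
#'   call).
#' @return Data frame: `rsid`, `mean_acr`, `n_het`.
#' @export
compute_acr <- function(adt, gm) {
  g <- gm$codes[cbind(match(adt$sample, samples_of(gm)),
                      match(adt$rsid, rsids_of(gm)))]
  assert_that(!anyNA(match(adt$rsid, rsids_of(gm))),
              "depth table rsid not in genotype matrix")
  het <- !is.na(g) & g == 1L
  mx <- pmax(adt$ref_depth, adt$alt_depth)
  zero <- het & mx == 0
  if (any(zero)) {
    warning(sprintf("%d heterozygous call(s) with zero depth excluded",
                    sum(zero)), call. = FALSE)
    het <- het & !zero
  }
  acr <- pmin(adt$ref_depth, adt$alt_depth)[het] / mx[het]
  agg <- split(acr, factor(adt$rsid[het], levels = unique(adt$rsid)))
  data.frame(rsid = names(agg),
             mean_acr = vapply(agg, function(x)
               if (length(x)) mean(x) else NA_real_, 0),
             n_het = lengths(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag calls below coverage thresholds
#'
#' A call passes when its DOC meets the interpretation threshold
#' (DOC >= 30 by default; a DOC of exactly 30 passes), is
#' "below-interpretation" when it meets only the detection threshold
#' (default 20), and "below-detection" otherwise.
#'
#' @param adt An allele depth table.
#' @param detection,interpretation Positive DOC thresholds.
#' @return `adt` with columns `doc` and `flag` added.
#' @export
flag_low_coverage <- function(adt, detection = 20, interpretation = 30) {
  assert_that(detection > 0 && interpretation > 0, "thresholds must be positive")
  doc <- adt$ref_depth + adt$alt_depth
  flag <- ifelse(doc >= interpretation, "pass",
                 ifelse(doc >= detection, "below-interpretation",
                        "below-detection"))
  cbind(adt, doc = doc, flag = flag, stringsAsFactors = FALSE)
}

#' Combined per-locus coverage summary
#'
#' @param adt An allele depth table.
#' @param gm The matching `genotype_matrix`.
#' @inheritParams flag_low_coverage
#' @return Data frame joining [compute_doc()] and [compute_acr()] plus the
#'   count of below-detection calls per locus.
#' @export
coverage_summary <- function(adt, gm, detection = 20, interpretation = 30) {
  doc <- compute_doc(adt)
  acr <- compute_acr(adt, gm)
  flags <- flag_low_coverage(adt, detection, interpretation)
  below <- tapply(flags$flag == "below-detection", flags$rsid, sum)
  out <- merge(doc, acr, by = "rsid", all.x = TRUE, sort = FALSE)
  out$n_below_detection <- as.integer(below[out$rsid])
  out
}
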