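# Per-locus ancestry informativeness: one-vs-rest allele-frequency
# difference (delta), Nei's Gst fixation index, and Rosenberg's
# informativeness-for-assignment (In).

#' Nei's Gst for one biallelic locus
#'
#' With group alt-allele frequencies p_1..p_K, let p-bar be their
#' unweighted mean, H_T = 2 p-bar (1 - p-bar) the total expected
#' heterozygosity and H_S the mean of the within-group 2 p (1 - p).  Gst =
#' (H_T - H_S) / H_T; a locus monomorphic in every group (H_T = 0) is
#' defined to have Gst 0.  The estimator is non-negative by construction
#' and invariant to ref/alt relabelling.
#'
#' @param p Numeric vector of group alt-allele frequencies (length >= 2).
#' @return Gst in \[0, 1\].
#' @export
fst_nei <- function(p) {
  assert_that(length(p) >= 2, "need >= 2 groups for Fst")
  if (anyNA(p)) return(NA_real_)
  pbar <- mean(p)
  ht <- 2 * pbar * (1 - pbar)
  if (ht == 0) return(0)
  hs <- mean(2 * p * (1 - p))
  (ht - hs) / ht
}

#' Weir-Cockerham theta for one biallelic locus
#'
#' Variance-components estimator using group sample sizes (chromosome
#' counts / 2).  Unlike [fst_nei()] it can go negative for weakly
#' differentiated loci; the raw value is returned alongside a
#' zero-clamped one.
#'
#' @param p Group alt-allele frequencies.
#' @param n Per-group diploid sample sizes.
#' @return List with `theta` (clamped to \[0,1\]) and `raw`.
#' @export
fst_weir_cockerham <- function(p, n) {
  assert_that(length(p) == length(n) && length(p) >= 2,
              "need matching frequencies and sizes for >= 2 groups")
  r <- length(p)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * 2 * p * (1 - p)) / (r * nbar)  # HWE expected hets
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  raw <- if (denom == 0) 0 else a / denom
  list(theta = min(max(raw, 0), 1), raw = raw)
}

#' Rosenberg's informativeness-for-assignment (In)
#'
#' For K groups with alt frequencies p_1..p_K (ref frequencies 1 - p), with
#' p-bar_j the unweighted mean frequency of allele j and natural
#' logarithms (0 log 0 := 0):
#' In = sum_j \[ -p-bar_j log p-bar_j + (1/K) sum_i p_ij log p_ij \].
#' Zero iff all groups share the same frequency; maximal value log K for
#' fully distinct fixed alleles (log 2 for a biallelic fixed difference
#' between two groups).
#'
#' @param p Numeric vector of group alt-allele frequencies (length >= 2).
#' @return In >= 0 (nats).
#' @export
informativeness <- function(p) {
  assert_that(length(p) >= 2, "need >= 2 groups for In")
  if (anyNA(p)) return(NA_real_)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  total <- 0
  for (pj in list(p, 1 - p)) {
    pbar <- mean(pj)
    total <- total - xlogx(pbar) + mean(xlogx(pj))
  }
  max(total, 0)   # guards tiny negative rounding at equality
}

#' One-vs-rest allele frequency differences (delta)
#'
#' delta for a target super-population is |p_target - p_rest| per locus,
#' with p_rest the pooled frequency of all remaining groups
#' ([pool_groups()]).
#'
#' @param aft An `allele_freq_table` at the desired grouping level.
#' @param target Group label.
#' @param weighted Chromosome-weighted pooling of the rest (default).
#' @return Named numeric vector of per-locus delta values.
#' @export
delta_one_vs_rest <- function(aft, target, weighted = TRUE) {
  pooled <- pool_groups(aft, target, weighted = weighted)
  d <- abs(pooled$target - pooled$rest)
  d[is.nan(pooled$target) | is.nan(pooled$rest)] <- NA_real_
  d
}

#' Pairwise and overall divergence report
#'
#' Assembles, per locus: delta for each group one-vs-rest, pairwise and
#' overall Gst, pairwise and overall In, plus counts of loci exceeding the
#' conventional reporting cutoffs (delta > 0.40, delta > 0.20, pairwise
#' Fst/In < 0.10).
#'
#' @param aft An `allele_freq_table` (typically super-population level).
#' @param delta_high,delta_mod delta cutoffs (defaults 0.40, 0.20).
#' @param low_cut Low Fst/In cutoff (default 0.10).
#' @param weighted Chromosome-weighted one-vs-rest pooling.
#' @return List of class `divergence_table`: `per_locus` data frame,
#'   `delta` (targets x loci), `fst_pairwise` and `in_pairwise` (pair x
#'   loci matrices), and `counts` summary data frame.
#' @export
divergence_report <- function(aft, delta_high = 0.40, delta_mod = 0.20,
                              low_cut = 0.10, weighted = TRUE) {
  groups <- aft$groups
  L <- length(aft$rsids)
  delta <- t(vapply(groups, function(g)
    delta_one_vs_rest(aft, g, weighted = weighted), numeric(L)))
  pairs <- utils::combn(groups, 2)
  pair_names <- apply(pairs, 2, paste, collapse = "-")
  fst_pw <- matrix(NA_real_, ncol(pairs), L,
                   dimnames = list(pair_names, aft$rsids))
  in_pw <- fst_pw
  for (j in seq_len(ncol(pairs))) {
    pp <- aft$alt_freq[pairs[, j], , drop = FALSE]
    fst_pw[j, ] <- apply(pp, 2, fst_nei)
    in_pw[j, ] <- apply(pp, 2, informativeness)
  }
  fst_all <- apply(aft$alt_freq, 2, fst_nei)
  in_all <- apply(aft$alt_freq, 2, informativeness)
  per_locus <- data.frame(rsid = aft$rsids, fst_overall = fst_all,
                          in_overall = in_all, t(delta),
                          check.names = FALSE, row.names = NULL)
  names(per_locus)[-(1:3)] <- paste0("delta_", groups)
  # one-vs-rest Fst/In: target group against the pooled remaining groups
  fst_ovr <- t(vapply(groups, function(g) {
    pooled <- pool_groups(aft, g, weighted = weighted)
    vapply(seq_len(L), function(l)
      fst_nei(c(pooled$target[l], pooled$rest[l])), 0)
  }, numeric(L)))
  in_ovr <- t(vapply(groups, function(g) {
    pooled <- pool_groups(aft, g, weighted = weighted)
    vapply(seq_len(L), function(l)
      informativeness(c(pooled$target[l], pooled$rest[l])), 0)
  }, numeric(L)))
  counts <- data.frame(
    target = groups,
    n_delta_high = rowSums(delta > delta_high, na.rm = TRUE),
    n_delta_mod = rowSums(delta > delta_mod, na.rm = TRUE),
    n_low_fst = rowSums(fst_ovr < low_cut, na.rm = TRUE),
    n_low_in = rowSums(in_ovr < low_cut, na.rm = TRUE),
    row.names = NULL)
  structure(list(per_locus = per_locus, delta = delta,
                 fst_pairwise = fst_pw, in_pairwise = in_pw,
                 fst_one_vs_rest = fst_ovr, in_one_vs_rest = in_ovr,
                 counts = counts,
                 cutoffs = c(delta_high = delta_high, delta_mod = delta_mod,
                             low = low_cut)),
            class = "divergence_table")
}

#' @export
print.divergence_table <- function(x, ...) {
  cat(sprintf("divergence_table: %d loci, %d groups\n",
              nrow(x$per_locus), nrow(x$delta)))
  cat(sprintf("  overall Fst range %.3f-%.3f, In range %.3f-%.3f\n",
              min(x$per_locus$fst_overall, na.rm = TRUE),
              max(x$per_locus$fst_overall, na.rm = TRUE),
              min(x$per_locus$in_overall, na.rm = TRUE),
              max(x$per_locus$in_overall, na.rm = TRUE)))
  invisible(x)
}

#' Write the per-locus divergence table as TSV
#' @param dt A `divergence_table`.
#' @param path File path.
#' @export
write_divergence_tsv <- function(dt, path) {
  utils::write.table(dt$per_locus, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
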