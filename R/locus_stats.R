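# Single-group per-locus statistics: exact HWE test, MAF and
# heterozygosities, EM-based two-locus LD, and forensic identity
# parameters (MP/PD/PIC/PE with panel-level CPD/CPE).

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Conditional exact ("probability") test: given the observed allele
#' counts, every compatible heterozygote count is enumerated with its
#' conditional probability
#' P(nAB | nA, n) = n! / (nAA! nAB! nBB!) * 2^nAB * nA! nB! / (2n)!,
#' and the p-value is the sum of probabilities not exceeding that of the
#' observed configuration.  Probabilities are computed by the numerically
#' stable ratio recurrence over nAB.  A monomorphic locus has no test
#' (returns `NA`), matching the convention of skipping such loci.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (ref-hom, het, alt-hom).
#' @return The exact p-value in (0, 1\], or `NA` for monomorphic input.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  assert_that(n_aa >= 0 && n_ab >= 0 && n_bb >= 0, "counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  assert_that(n >= 1, "need at least one individual")
  n_a <- 2 * n_aa + n_ab           # ref allele count
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(NA_real_)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)      # feasible het counts
  # unnormalized probabilities via the ratio
  # P(h+2)/P(h) = 4 * nAA(h) * nBB(h) / ((h+2)(h+1))
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - rare / 2))
  probs[mid] <- 1
  if (mid < length(hets)) for (i in mid:(length(hets) - 1)) {
    h <- hets[i]
    haa <- (n_a - h) / 2
    hbb <- (n_b - h) / 2
    probs[i + 1] <- probs[i] * 4 * haa * hbb / ((h + 2) * (h + 1))
  }
  if (mid > 1) for (i in mid:2) {
    h <- hets[i]
    haa <- (n_a - h) / 2
    hbb <- (n_b - h) / 2
    probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (haa + 1) * (hbb + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[hets == n_ab]
  min(sum(probs[probs <= p_obs * (1 + 1e-12)]), 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_that(m >= 1, "m must be >= 1")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  alpha / m
}

#' MAF, observed and expected heterozygosity for one locus
#'
#' `maf = min(p, 1-p)`; `ho` is the fraction of heterozygous calls; `he =
#' 2 p (1-p)` with no small-sample correction (set `unbiased = TRUE` for
#' the 2n/(2n-1) corrected version).
#'
#' @param codes Dosage vector (0/1/2, `NA` missing).
#' @param unbiased Apply the 2n/(2n-1) correction to He.
#' @return List `n`, `maf`, `ho`, `he`, `p` (alt frequency),
#'   `monomorphic`.
#' @export
maf_ho_he <- function(codes, unbiased = FALSE) {
  codes <- codes[!is.na(codes)]
  assert_that(length(codes) >= 1, "no non-missing calls")
  n <- length(codes)
  p <- sum(codes) / (2 * n)
  he <- 2 * p * (1 - p)
  if (unbiased) he <- he * 2 * n / (2 * n - 1)
  list(n = n, maf = min(p, 1 - p), ho = mean(codes == 1L), he = he, p = p,
       monomorphic = p == 0 || p == 1)
}

#' Per-locus summary for a study group
#'
#' @param gm A `genotype_matrix` (the study group only).
#' @param unbiased Passed to [maf_ho_he()].
#' @return Data frame: `rsid`, `n`, `maf`, `ho`, `he`, `hwe_p`,
#'   `monomorphic`.  `hwe_p` is `NA` for monomorphic loci.
#' @export
locus_summary <- function(gm, unbiased = FALSE) {
  rows <- lapply(rsids_of(gm), function(rs) {
    codes <- gm$codes[, rs]
    s <- maf_ho_he(codes, unbiased = unbiased)
    cc <- codes[!is.na(codes)]
    data.frame(rsid = rs, n = s$n, maf = s$maf, ho = s$ho, he = s$he,
               hwe_p = hwe_exact_test(sum(cc == 0L), sum(cc == 1L),
                                      sum(cc == 2L)),
               monomorphic = s$monomorphic, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' EM haplotype frequencies and r-squared for a locus pair
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' diploid dosages by EM over the double-heterozygote phase ambiguity,
#' starting from linkage-equilibrium product frequencies and iterating
#' until the largest frequency change is below `tol` (default 1e-10) or
#' `max_iter` iterations.  `r2 = D^2 / (pA (1-pA) pB (1-pB))` with `D =
#' f(AB) - pA pB`; if either locus is monomorphic r2 is defined as 0.
#'
#' @param codes_a,codes_b Dosage vectors over the same samples.
#' @param tol,max_iter Convergence controls.
#' @return List of class `ld_result`: `hap_freqs` (named AB/Ab/aB/ab,
#'   A/B = alt alleles), `d`, `r2`, `em_iterations`, `converged`,
#'   `loglik`, `n`.
#' @export
em_haplotype_freqs <- function(codes_a, codes_b, tol = 1e-10,
                               max_iter = 1000) {
  keep <- !is.na(codes_a) & !is.na(codes_b)
  a <- codes_a[keep]; b <- codes_b[keep]
  n <- length(a)
  assert_that(n >= 2, "need >= 2 individuals with calls at both loci")
  counts <- table(factor(a, 0:2), factor(b, 0:2))  # 3x3 genotype counts
  pa <- sum(a) / (2 * n)
  pb <- sum(b) / (2 * n)
  # known haplotype counts from unambiguous genotypes; double hets (1,1)
  # contribute to either (AB,ab) or (Ab,aB)
  ndh <- counts[2, 2]
  base <- c(AB = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3],
            Ab = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
            aB = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
            ab = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1])
  h <- c(AB = pa * pb, Ab = pa * (1 - pb), aB = (1 - pa) * pb,
         ab = (1 - pa) * (1 - pb))
  if (ndh == 0) h <- base / max(sum(base), 1)
  iter <- 0L; converged <- FALSE
  if (sum(base) + 2 * ndh > 0) repeat {
    iter <- iter + 1L
    cis <- h["AB"] * h["ab"]
    trans <- h["Ab"] * h["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new <- base + ndh * c(w, 1 - w, 1 - w, w)
    new <- new / sum(new)
    delta <- max(abs(new - h))
    h <- new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  } else converged <- TRUE
  d <- unname(h["AB"] - pa * pb)
  denom <- pa * (1 - pa) * pb * (1 - pb)
  r2 <- if (denom == 0) 0 else d^2 / denom
  probs <- genotype_pair_probs(h)
  ll <- sum(counts * ifelse(counts > 0, log(pmax(probs, 1e-300)), 0))
  structure(list(hap_freqs = h, d = d, r2 = r2, em_iterations = iter,
                 converged = converged, loglik = ll, n = n),
            class = "ld_result")
}

# 3x3 genotype-pair probabilities implied by haplotype frequencies
# (rows = dosage at A, cols = dosage at B), used for the likelihood.
genotype_pair_probs <- function(h) {
  hapd <- c(h["ab"], h["Ab"], h["aB"], h["AB"])  # index by (a_alt, b_alt)
  hap <- matrix(hapd, 2, 2)  # hap[i,j]: i-1 = alt at A, j-1 = alt at B
  probs <- matrix(0, 3, 3)
  for (i1 in 0:1) for (j1 in 0:1) for (i2 in 0:1) for (j2 in 0:1) {
    ga <- i1 + i2 + 1
    gb <- j1 + j2 + 1
    probs[ga, gb] <- probs[ga, gb] + hap[i1 + 1, j1 + 1] * hap[i2 + 1, j2 + 1]
  }
  probs
}

#' Pairwise r-squared matrix for a panel
#'
#' @param gm A `genotype_matrix`.
#' @return Symmetric matrix of EM r-squared values (diagonal 1).
#' @export
ld_matrix <- function(gm) {
  rs <- rsids_of(gm)
  m <- diag(1, length(rs))
  dimnames(m) <- list(rs, rs)
  for (i in seq_along(rs)[-length(rs)]) for (j in (i + 1):length(rs)) {
    m[i, j] <- m[j, i] <- em_haplotype_freqs(gm$codes[, i], gm$codes[, j])$r2
  }
  m
}

#' Forensic identity parameters for one locus
#'
#' Matching probability MP = sum over the three genotype classes of the
#' squared observed genotype frequency; PD = 1 - MP; PIC = 1 - p^2 - q^2 -
#' 2 p^2 q^2; PE = h^2 (1 - 2 h H^2) with h the observed heterozygosity
#' and H = 1 - h.
#'
#' @param codes Dosage vector (0/1/2, `NA` missing).
#' @return List `mp`, `pd`, `pic`, `pe`, `n`.
#' @export
forensic_parameters <- function(codes) {
  codes <- codes[!is.na(codes)]
  assert_that(length(codes) >= 1, "no non-missing calls")
  n <- length(codes)
  gf <- tabulate(codes + 1L, 3L) / n
  mp <- sum(gf^2)
  p <- sum(codes) / (2 * n)
  q <- 1 - p
  pic <- 1 - p^2 - q^2 - 2 * p^2 * q^2
  h <- gf[2]
  pe <- h^2 * (1 - 2 * h * (1 - h)^2)
  list(mp = mp, pd = 1 - mp, pic = pic, pe = pe, n = n)
}

#' Forensic summary for a panel
#'
#' @param gm A `genotype_matrix` of the study group.
#' @return List of class `forensic_stats`: `per_locus` data frame (`rsid`,
#'   `mp`, `pd`, `pic`, `pe`), `means`, `cpd`, `cpe`.
#' @export
forensic_summary <- function(gm) {
  per <- do.call(rbind, lapply(rsids_of(gm), function(rs) {
    f <- forensic_parameters(gm$codes[, rs])
    data.frame(rsid = rs, n = f$n, mp = f$mp, pd = f$pd, pic = f$pic,
               pe = f$pe, stringsAsFactors = FALSE)
  }))
  cum <- cumulative_panel_stats(per)
  structure(list(per_locus = per,
                 means = colMeans(per[, c("mp", "pd", "pic", "pe")]),
                 cpd = cum$cpd, cpe = cum$cpe),
            class = "forensic_stats")
}

#' Cumulative panel-level discrimination / exclusion power
#'
#' CPD = 1 - prod(1 - PD_l); CPE = 1 - prod(1 - PE_l).
#'
#' @param per_locus Data frame with columns `pd` and `pe`.
#' @return List `cpd`, `cpe`.
#' @export
cumulative_panel_stats <- function(per_locus) {
  assert_that(nrow(per_locus) >= 1, "need >= 1 locus")
  list(cpd = 1 - prod(1 - per_locus$pd), cpe = 1 - prod(1 - per_locus$pe))
}

#' @export
print.forensic_stats <- function(x, ...) {
  cat(sprintf("forensic_stats: %d loci; CPD %.9f, CPE %.4f\n",
              nrow(x$per_locus), x$cpd, x$cpe))
  invisible(x)
}
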