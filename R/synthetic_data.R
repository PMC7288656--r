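# Balding-Nichols genotype simulator.
#
# Population allele frequencies are drawn around a shared ancestral
# frequency p0 from Beta(p0 (1-F)/F, (1-p0)(1-F)/F), where F is the
# per-population drift (target Fst).  Genotypes are Hardy-Weinberg draws
# Binomial(2, p); admixed cohorts mix the source frequencies through
# Dirichlet ancestry fractions.  One master seed governs every generator
# through derived substreams.

#' Simulation configuration
#'
#' Describes a synthetic study: K drifted source populations (each with a
#' super-population label, sample size and Balding-Nichols drift F),
#' optional Dirichlet-admixed cohorts, an ancestral frequency range, and a
#' read-depth model for coverage QC inputs.
#'
#' @param n_loci Number of unlinked biallelic loci.
#' @param populations Data frame with columns `label`, `super`, `n`, `f`
#'   (drift, in (0,1)).
#' @param ancestral_range Length-2 range for the ancestral alt-allele
#'   frequency (uniform draw); default (0.1, 0.9) avoids near-fixed,
#'   uninformative loci, as AISNP panels are ascertained for intermediate
#'   frequencies.
#' @param admixed List of admixed cohorts, each
#'   `list(label=, super=, n=, alpha=)` with `alpha` a named Dirichlet
#'   parameter vector over source population labels.
#' @param depth List with `meanlog_range` (range of per-locus log mean
#'   depth), `sdlog` (within-locus lognormal spread) and `balance`
#'   (expected alt fraction at heterozygotes).
#' @param seed Master integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 30,
                       populations = data.frame(
                         label = c("AFR", "EUR", "EAS", "SAS"),
                         super = c("AFR", "EUR", "EAS", "SAS"),
                         n = 100L,
                         f = c(0.50, 0.35, 0.45, 0.30)),
                       ancestral_range = c(0.1, 0.9),
                       admixed = list(list(
                         label = "AMR", super = "AMR", n = 100L,
                         alpha = c(AFR = 0.8, EUR = 3.0, EAS = 1.6,
                                   SAS = 0.6))),
                       depth = list(meanlog_range = log(c(800, 20000)),
                                    sdlog = 0.5, balance = 0.5),
                       seed = 1L) {
  assert_that(n_loci >= 1, "n_loci must be >= 1")
  assert_that(all(populations$n >= 1), "population sizes must be >= 1")
  assert_that(all(populations$f > 0 & populations$f < 1),
              "drift F must be in (0,1)")
  assert_that(length(ancestral_range) == 2 && ancestral_range[1] > 0 &&
                ancestral_range[2] < 1 &&
                ancestral_range[1] <= ancestral_range[2],
              "ancestral_range must be within (0,1)")
  for (cohort in admixed) {
    assert_that(all(cohort$alpha > 0), "Dirichlet alpha must be positive")
    assert_that(all(names(cohort$alpha) %in% populations$label),
                "admixed alpha names must be source population labels")
  }
  structure(list(n_loci = as.integer(n_loci), populations = populations,
                 ancestral_range = ancestral_range, admixed = admixed,
                 depth = depth, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate true population allele frequencies (Balding-Nichols)
#'
#' @param cfg A [sim_config()].
#' @return An `allele_freq_table` of true source-population frequencies,
#'   with the ancestral frequencies in attribute `ancestral`.
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1))
  L <- cfg$n_loci
  p0 <- stats::runif(L, cfg$ancestral_range[1], cfg$ancestral_range[2])
  pops <- cfg$populations
  freq <- matrix(NA_real_, nrow(pops), L,
                 dimnames = list(pops$label,
                                 sprintf("locus%03d", seq_len(L))))
  for (k in seq_len(nrow(pops))) {
    f <- pops$f[k]
    freq[k, ] <- stats::rbeta(L, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  }
  aft <- allele_freq_table(freq)
  attr(aft, "ancestral") <- p0
  aft
}

#' Simulate HWE genotypes for the source populations
#'
#' Genotype of individual i at locus l is Binomial(2, p_kl) for its
#' population k.
#'
#' @param freqs True frequencies from [simulate_frequencies()].
#' @param cfg The same [sim_config()].
#' @return List with `genotypes` (a `genotype_matrix`) and `manifest`.
#' @export
simulate_genotypes <- function(freqs, cfg) {
  set.seed(derive_seed(cfg$seed, 2))
  pops <- cfg$populations
  rows <- vector("list", nrow(pops))
  for (k in seq_len(nrow(pops))) {
    n <- pops$n[k]
    p <- freqs$alt_freq[pops$label[k], ]
    g <- matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), nrow = n)
    rownames(g) <- sprintf("%s_%03d", pops$label[k], seq_len(n))
    rows[[k]] <- g
  }
  codes <- do.call(rbind, rows)
  colnames(codes) <- freqs$rsids
  manifest <- population_manifest(
    sample = rownames(codes),
    population = rep(pops$label, pops$n),
    super_population = rep(pops$super, pops$n))
  list(genotypes = genotype_matrix(codes), manifest = manifest)
}

#' Simulate a Dirichlet-admixed cohort
#'
#' Each individual draws ancestry fractions q ~ Dirichlet(alpha) over the
#' source populations; its genotype at locus l is Binomial(2, sum_k q_k
#' f_kl).  Emulates admixed cohorts such as the 1000 Genomes American
#' populations.
#'
#' @param freqs True source frequencies ([simulate_frequencies()]).
#' @param alpha Named Dirichlet parameters over source population labels.
#' @param n Cohort size.
#' @param label Sample-name prefix and population label.
#' @param seed Integer seed.
#' @return List with `genotypes` (a `genotype_matrix`) and `q` (the true
#'   n x K ancestry matrix).
#' @export
simulate_admixed_cohort <- function(freqs, alpha, n, label = "ADM",
                                    seed = 1L) {
  assert_that(length(alpha) >= 2, "need at least two source populations")
  assert_that(all(names(alpha) %in% freqs$groups),
              "alpha names must match frequency groups")
  set.seed(derive_seed(seed, 3))
  K <- length(alpha)
  q <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), nrow = n)
  q <- q / rowSums(q)
  colnames(q) <- names(alpha)
  f <- freqs$alt_freq[names(alpha), , drop = FALSE]
  p <- q %*% f                     # n x L mixed frequencies
  codes <- matrix(stats::rbinom(length(p), 2L, pmin(pmax(p, 0), 1)),
                  nrow = n, dimnames = list(sprintf("%s_%03d", label,
                                                   seq_len(n)),
                                            freqs$rsids))
  rownames(q) <- rownames(codes)
  list(genotypes = genotype_matrix(codes), q = q)
}

#' Simulate the full default study
#'
#' Runs [simulate_frequencies()], [simulate_genotypes()] and every
#' configured admixed cohort, returning one combined dataset.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes`, `manifest`, `freqs` (true source
#'   frequencies) and `true_q` (per-cohort true ancestry matrices).
#' @export
simulate_study <- function(cfg) {
  freqs <- simulate_frequencies(cfg)
  base <- simulate_genotypes(freqs, cfg)
  codes <- base$genotypes$codes
  manifest <- as.data.frame(base$manifest)
  true_q <- list()
  for (i in seq_along(cfg$admixed)) {
    cohort <- cfg$admixed[[i]]
    sim <- simulate_admixed_cohort(freqs, cohort$alpha, cohort$n,
                                   label = cohort$label,
                                   seed = derive_seed(cfg$seed, 10 + i))
    codes <- rbind(codes, sim$genotypes$codes)
    manifest <- rbind(manifest, data.frame(
      sample = samples_of(sim$genotypes),
      population = cohort$label,
      super_population = cohort$super %||% cohort$label))
    true_q[[cohort$label]] <- sim$q
  }
  list(genotypes = genotype_matrix(codes, base$genotypes$loci),
       manifest = population_manifest(manifest$sample, manifest$population,
                                      manifest$super_population),
       freqs = freqs, true_q = true_q)
}

#' Simulate per-call allele depths
#'
#' Total depth per call is LogNormal with a per-locus mean drawn from
#' `cfg$depth$meanlog_range` (emulating the wide per-locus coverage spread
#' of multiplexed amplicon sequencing); heterozygote alt depth is
#' Binomial(depth, balance); homozygote calls put all reads on the called
#' allele.
#'
#' @param gm A `genotype_matrix`.
#' @param cfg A [sim_config()] (its `depth` and `seed` fields are used).
#' @return A data frame (`sample`, `rsid`, `ref_depth`, `alt_depth`).
#' @export
simulate_allele_depths <- function(gm, cfg) {
  set.seed(derive_seed(cfg$seed, 4))
  dm <- cfg$depth
  L <- ncol(gm$codes)
  n <- nrow(gm$codes)
  meanlog <- stats::runif(L, dm$meanlog_range[1], dm$meanlog_range[2])
  depth <- matrix(pmax(1L, as.integer(round(stats::rlnorm(
    n * L, rep(meanlog, each = n), dm$sdlog)))), nrow = n)
  alt_d <- matrix(0L, n, L)
  g <- gm$codes
  het <- !is.na(g) & g == 1L
  alt_d[het] <- stats::rbinom(sum(het), depth[het], dm$balance)
  hom_alt <- !is.na(g) & g == 2L
  alt_d[hom_alt] <- depth[hom_alt]
  keep <- !is.na(g)
  idx <- which(keep, arr.ind = TRUE)
  data.frame(sample = samples_of(gm)[idx[, 1]],
             rsid = rsids_of(gm)[idx[, 2]],
             ref_depth = (depth - alt_d)[keep],
             alt_depth = alt_d[keep],
             stringsAsFactors = FALSE)
}
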