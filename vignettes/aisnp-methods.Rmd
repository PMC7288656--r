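---
title: "Methods: AISNP panel evaluation and ancestry inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AISNP panel evaluation and ancestry inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aisnp)
```

# The problem

An ancestry-informative SNP (AISNP) panel is a small set of unlinked
biallelic loci whose allele frequencies differ strongly between
continental populations. Evaluating such a panel means quantifying
per-locus divergence, verifying the population-genetic assumptions the
classifier relies on (Hardy–Weinberg equilibrium within groups, linkage
independence between loci), measuring forensic identity power, and
measuring assignment accuracy by cross-validation. This vignette explains
each model in the package, the parameters that matter, and exactly what
the synthetic tests do and do not establish.

# Data model

Genotypes are alt-allele dosages g ∈ {0, 1, 2} with `NA` for missing
calls; every statistic is computed from the derived
`allele_freq_table`: per (group, locus) the alt frequency
p = Σg / (2·n_nonmissing) and the chromosome count 2·n_nonmissing.
Missing calls never contribute to numerator or denominator; a group with
no calls at a locus carries an explicit undefined (`NaN`) cell which
downstream statistics propagate or drop with a warning (Nei's DA drops
the locus and adjusts L). Alleles are taken exactly as written in the
input; a ref/alt mismatch between a supplied panel and a VCF is a hard
error rather than a silent strand flip, because a flipped frequency
corrupts every statistic downstream.

One-vs-rest pooling ("one continent against the other four") is
chromosome-count weighted by default — equivalent to pooling the raw
samples. Published panel evaluations rarely state whether their pooled
"rest" weights continents by sample size; both modes are available
(`pool_groups(..., weighted = FALSE)`), weighted is the default, and the
choice only matters when reference cohorts differ greatly in size.

# Divergence metrics

* δ (delta): |p_target − p_rest| per locus, against the pooled rest.
* Fst: Nei's Gst on unweighted group frequencies,
  (H_T − H_S)/H_T with H_T = 2p̄(1−p̄) and H_S the mean within-group
  expected heterozygosity. The estimator behind published per-panel Fst
  tables is usually not stated; Gst is the documented assumption here
  because it is frequency-based (works directly on a frequency table),
  cannot go negative, and is invariant to allele relabelling. A
  Weir–Cockerham θ (`fst_weir_cockerham()`) is provided for comparison;
  its raw value is retained and the reported value clamped to [0, 1].
* In: Rosenberg's informativeness-for-assignment with natural logarithms
  and the unweighted mean across groups, 0·ln 0 := 0. In = 0 iff all
  groups share a frequency; the biallelic two-group maximum is ln 2.

Multi-locus pairwise Fst combines loci by ratio of sums
(Σ(H_T − H_S)/ΣH_T), the standard way to combine loci without letting
near-monomorphic loci dominate; the alternative (mean of per-locus
ratios) is noisier and not offered.

# Exact HWE test

The conditional ("probability") exact test enumerates every heterozygote
count compatible with the observed allele counts; the p-value is the sum
of conditional probabilities not exceeding that of the observed
configuration. Probabilities are computed by the ratio recurrence
P(h+2)/P(h) = 4·n_AA(h)·n_BB(h) / ((h+2)(h+1)) outward from the modal
configuration and normalized, which is numerically stable to n in the
thousands. Monomorphic loci return `NA` — "no test" rather than p = 1 —
matching the reporting convention of skipping such loci. The test suite
checks the implementation against an independent log-factorial oracle for
every genotype triple with n ≤ 50.

# Two-locus LD by EM

Unphased diploid genotypes at two loci determine all haplotype counts
except the phase of double heterozygotes. EM starts from
linkage-equilibrium product frequencies and redistributes the
double-heterozygote mass by the cis/trans responsibility
h_AB·h_ab / (h_AB·h_ab + h_Ab·h_aB), stopping when the largest frequency
change is below 1e-10 (or 1000 iterations). With no double heterozygotes
the first pass reproduces the closed-form counts. r² =
D²/(p_A q_A p_B q_B); a monomorphic locus gives r² = 0 by definition. The
likelihood profile is one-dimensional in the cis-pairing count, which is
what the grid-search oracle in the tests exploits.

# Forensic parameters

MP sums squared *observed* genotype frequencies (not HWE-expected ones),
PD = 1 − MP; PIC = 1 − p² − q² − 2p²q²; PE uses the
observed-heterozygosity formula h²(1 − 2hH²), H = 1 − h. These match the
conventions of the spreadsheet tools forensic labs use; which PE formula
those tools apply is typically undocumented, so the
observed-heterozygosity (Brenner-style) formula is the stated assumption.
Expected heterozygosity is 2p(1−p) without the 2n/(2n−1) correction
(`unbiased = TRUE` restores it). CPD/CPE are 1 − Π(1 − x_l).

# Naive-Bayes classification and LOOCV

Training frequencies are Laplace add-one smoothed on allele counts,
f = (x+1)/(2n+2), so no genotype has zero likelihood; with no data the
frequency is exactly 1/2 (uninformative). The web tools that popularized
this classifier do not document their smoothing constant, so add-one is
the reproduction assumption; confusion-matrix cells can differ from
published ones in the last decimal for this reason. Likelihoods are HWE
genotype probabilities multiplied across loci (missing loci skipped, the
likelihood factorizes); posteriors are computed in log space with
uniform priors. Exact ties go to the first group in model order and are
flagged — they occur only in degenerate inputs.

LOOCV removes one individual at a time and refits *only its own group's*
frequencies (removing a non-member cannot change another group's
counts), classifies it, and tallies assignment proportions per true
group. Iteration order is the input order; there is no randomness. One
consequence worth knowing: if a group is duplicated under two labels, the
held-out individual's exact copy remains in the twin group and pulls its
smoothed frequencies toward it, so assignments deterministically favour
the twin label rather than splitting 50/50 per row; the mass stays within
the duplicated pair and the tally is symmetric between the twin rows.

# Population structure

Nei's DA = 1 − mean over loci of Σ_j √(x_j y_j). It satisfies d(X,X) = 0,
symmetry, and boundedness in [0, 1] but may violate the triangle
inequality; it is used as NJ input, not as a metric. Neighbor-joining is
delegated to `ape::nj` (Saitou–Nei with the Q-criterion, exact on
additive distances — verified against randomly generated additive trees)
with negative branch lengths clamped to zero for display. Newick output
quotes labels containing spaces or metacharacters.

PCA is column-centred covariance PCA (`prcomp`): population-level on the
frequency matrix, individual-level on dosages with locus-mean imputation
for missing calls (imputed values are centred away, contributing
nothing). Genotypes are not scaled by √(p(1−p)) by default — matching
spreadsheet-style covariance PCA — with `scale = TRUE` available.

# Admixture model

The likelihood is binomial: dosage g_il ~ Binomial(2, π_il),
π = QF, Q row-stochastic, F ∈ (0,1). The reference implementation in the
field optimizes this likelihood by block relaxation with quasi-Newton
acceleration; this package uses plain EM on the same likelihood with the
same termination rule (ΔLL < 1e-4) — a deviation in optimizer, not in
model, chosen because EM is simple and provably monotone (the test suite
asserts monotonicity across random starts). F is clamped to
[1e-6, 1 − 1e-6] after each update to protect the logs; K = 1 reduces to
the closed-form per-locus MLE in ≤ 2 iterations. Runs are unsupervised,
initialized Q ~ Dirichlet(1,…,1), F ~ U(0.05, 0.95) under a derived
seed; `run_k_range()` keeps the best of N restarts (default 5 — the
replicate policy of published runs is rarely stated, so N is
configurable). Components are identified only up to label switching;
`align_ancestry()` resolves the permutation against a reference Q. No
cross-validation error for choosing K is computed: the workflow reports
K = 2..6 side by side.

# Coverage QC

DOC per call is ref+alt depth; the per-locus summary is the arithmetic
mean over calls (whether published per-locus means average per-sample or
pool reads is typically unstated; per-call is implemented). ACR is
min/max depth at *heterozygous calls only* — the ratio is meaningless for
homozygotes — and a locus with no heterozygotes has undefined ACR. A call
passes at DOC ≥ 30 (the interpretation threshold; equality passes),
is below-interpretation at ≥ 20, below-detection otherwise.

# The synthetic world

`sim_config()` defaults encode the study design the analyses assume:

* 30 unlinked biallelic loci, ancestral frequency p₀ ~ U(0.1, 0.9) —
  AISNP panels are ascertained for intermediate frequencies, and
  near-fixed loci carry no assignment information;
* four drifted source populations (AFR/EUR/EAS/SAS analogues, n = 100
  each) under the Balding–Nichols model, population frequency ~
  Beta(p₀(1−F)/F, (1−p₀)(1−F)/F), with drift F = (0.50, 0.35, 0.45,
  0.30). These values were calibrated once by Monte-Carlo so the
  per-locus overall Gst of the sources has mean ≈ 0.29 with an upper
  tail ≈ 0.6 — the divergence regime reported for real continental AISNP
  panels — and were then frozen;
* one admixed American-like cohort (n = 100), ancestry q ~
  Dirichlet(0.8, 3.0, 1.6, 0.6) over (AFR, EUR, EAS, SAS), genotype ~
  Binomial(2, Σ_k q_k f_kl): mean ancestry ≈ (13%, 50%, 27%, 10%),
  emulating cohorts with predominant European plus East-Asian-like
  (standing in for indigenous American) and African contributions;
* allele depths: per-locus mean depth log-uniform in [800, 20000],
  lognormal within-locus spread (σ_log = 0.5), heterozygote balance 0.5 —
  the wide per-locus coverage spread of multiplexed amplicon sequencing.

One master seed drives every generator through fixed derived substreams,
so a full pipeline run is reproducible end to end.

What the generator does **not** model: ascertainment of the loci (so a
low-Fst tail below the published minimum remains), linkage between loci
(the LD code is exercised on constructed genotype sets instead), genotype
error, related individuals, and real indigenous-American reference
frequencies (the admixed cohort mixes the four simulated sources). A
green classifier test therefore establishes that the pipeline recovers
the structure it simulates — near-perfect assignment of strongly drifted
sources and degraded, source-leaking assignment of admixed individuals —
not that any particular real panel achieves specific published accuracy
cells, which would require the reference genotypes themselves.

# Numerical choices

* Frequencies: pooled frequencies computed from counts, conserving mass
  to machine precision for any sample partition.
* HWE: recurrence from the modal configuration; p capped at 1; equality
  of probabilities tolerated to a 1e-12 relative factor.
* EM (LD and admixture): tolerances 1e-10 (frequency change) and 1e-4
  (log-likelihood) respectively; both monotone by construction.
* NJ: symmetric-matrix check at 1e-8; negative branch lengths clamped.
* Classifier ties: log-posterior difference below 1e-12 counts as a tie.
* Seeds are kept below 2³¹ − 1 by modular reduction in `derive_seed()`.

# Known limitations

Confusion-matrix reproduction of published panels needs their reference
genotypes (not redistributable here); the smoothing constant of the
original web classifier is undocumented, bounding cell-level agreement;
the admixture optimizer is EM, typically needing more iterations than
accelerated block relaxation (hundreds for n = 500, well under a second
per fit at panel scale); and Nei's DA non-metricity means NJ branch
lengths can be clamped at zero for nearly coincident populations.
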