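test_that("exact HWE test reproduces enumerated small cases", {
  expect_true(is.na(hwe_exact_test(2, 0, 0)))   # monomorphic: no test
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_error(hwe_exact_test(-1, 0, 2), ">= 0")
})

test_that("exact HWE test equals the log-factorial oracle (n <= 25)", {
  for (n in c(2, 5, 10, 25)) {
    for (n_ab in 0:n) for (n_aa in 0:(n - n_ab)) {
      n_bb <- n - n_ab - n_aa
      got <- hwe_exact_test(n_aa, n_ab, n_bb)
      want <- hwe_oracle(n_aa, n_ab, n_bb)
      if (is.na(want)) expect_true(is.na(got))
      else expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("bonferroni_threshold is alpha/m", {
  expect_equal(round(bonferroni_threshold(0.05, 29), 4), 0.0017)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("maf/ho/he follow their definitions", {
  s <- maf_ho_he(c(0, 1, 2, 1))
  expect_equal(s$maf, 0.5)
  expect_equal(s$ho, 0.5)
  expect_equal(s$he, 0.5)
  mono <- maf_ho_he(c(0, 0, 0))
  expect_equal(c(mono$maf, mono$ho, mono$he), c(0, 0, 0))
  expect_true(mono$monomorphic)
  allhet <- maf_ho_he(c(1, 1, 1, 1))
  expect_equal(allhet$ho, 1)
  expect_equal(allhet$he, 0.5)
  # unbiased flag applies 2n/(2n-1)
  expect_equal(maf_ho_he(c(0, 1, 2, 1), unbiased = TRUE)$he,
               0.5 * 8 / 7)
  expect_error(maf_ho_he(c(NA, NA)), "no non-missing")
})

test_that("locus_summary marks monomorphic loci with undefined HWE p", {
  gm <- tiny_gm()
  ls <- locus_summary(gm)
  expect_equal(ls$rsid, paste0("rs", 1:4))
  expect_true(ls$monomorphic[4])
  expect_true(is.na(ls$hwe_p[4]))
  expect_true(all(ls$hwe_p[1:3] > 0 & ls$hwe_p[1:3] <= 1, na.rm = TRUE))
  expect_equal(ls$n[2], 5L)   # one missing call at rs2
})

test_that("EM haplotype estimation: unambiguous data converges in one pass", {
  # no double heterozygotes: counting is exact
  a <- c(2, 2, 0, 0, 1, 0)
  b <- c(2, 2, 0, 0, 0, 1)
  r <- em_haplotype_freqs(a, b)
  expect_equal(r$em_iterations, 1L)
  expect_true(r$converged)
  want <- c(AB = 4, Ab = 1, aB = 1, ab = 6) / 12
  expect_equal(r$hap_freqs, want)
  expect_equal(sum(r$hap_freqs), 1, tolerance = 1e-12)
})

test_that("perfectly correlated loci give r2 = 1; monomorphic give 0", {
  codes <- c(0, 1, 2, 0, 1, 2, 1, 1)
  expect_equal(em_haplotype_freqs(codes, codes)$r2, 1, tolerance = 1e-9)
  expect_equal(em_haplotype_freqs(codes, 2 - codes)$r2, 1, tolerance = 1e-9)
  expect_equal(em_haplotype_freqs(codes, rep(0, 8))$r2, 0)
})

test_that("EM matches a 1-D profile grid-search likelihood maximizer", {
  # 20 constructed individuals with double heterozygotes; the likelihood
  # profile is 1-D in the cis-pairing count t of the double hets.
  a <- c(2, 1, 1, 1, 0, 2, 1, 0, 1, 2, 1, 1, 0, 1, 2, 1, 0, 1, 1, 0)
  b <- c(2, 1, 0, 1, 0, 1, 1, 1, 2, 2, 1, 0, 0, 1, 2, 1, 0, 2, 1, 1)
  r <- em_haplotype_freqs(a, b)
  counts <- table(factor(a, 0:2), factor(b, 0:2))
  ndh <- counts[2, 2]
  base <- c(AB = 2 * counts[3, 3] + counts[3, 2] + counts[2, 3],
            Ab = 2 * counts[3, 1] + counts[3, 2] + counts[2, 1],
            aB = 2 * counts[1, 3] + counts[1, 2] + counts[2, 3],
            ab = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1])
  tot <- sum(base) + 2 * ndh
  grid_ll <- function(t) {
    h <- (base + c(t, ndh - t, ndh - t, t)) / tot
    pr <- aisnp:::genotype_pair_probs(h)
    sum(counts * ifelse(counts > 0, log(pmax(pr, 1e-300)), 0))
  }
  ts <- seq(0, ndh, length.out = 20001)
  best_t <- ts[which.max(vapply(ts, grid_ll, 0))]
  best_h <- (base + c(best_t, ndh - best_t, ndh - best_t, best_t)) / tot
  expect_equal(unname(r$hap_freqs), unname(best_h), tolerance = 1e-4)
  expect_gte(r$loglik, grid_ll(best_t) - 1e-6)
})

test_that("EM likelihood is non-decreasing and frequencies stay normalized", {
  set.seed(37)
  for (rep in 1:10) {
    n <- 30
    a <- sample(0:2, n, replace = TRUE)
    b <- sample(0:2, n, replace = TRUE)
    r <- em_haplotype_freqs(a, b)
    expect_equal(sum(r$hap_freqs), 1, tolerance = 1e-12)
    expect_gte(r$r2, 0); expect_lte(r$r2, 1 + 1e-12)
    # r2 consistent with D^2 / product of allele frequencies
    pa <- sum(a) / (2 * n); pb <- sum(b) / (2 * n)
    denom <- pa * (1 - pa) * pb * (1 - pb)
    if (denom > 0) expect_equal(r$r2, r$d^2 / denom, tolerance = 1e-12)
  }
})

test_that("ld_matrix is symmetric with unit diagonal", {
  gm <- tiny_gm()
  m <- ld_matrix(gm)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
})

test_that("forensic parameters match hand-evaluated cases", {
  # genotype counts (2, 1, 1): mp = .5^2 + .25^2 + .25^2
  f <- forensic_parameters(c(0, 0, 1, 2))
  expect_equal(f$mp, 0.375)
  expect_equal(f$pd, 0.625)
  # p = 0.5 -> pic = 0.375
  expect_equal(forensic_parameters(c(0, 1, 2, 1))$pic, 0.375)
  # no heterozygotes -> pe = 0
  expect_equal(forensic_parameters(c(0, 0, 2, 2))$pe, 0)
  # pe formula h^2 (1 - 2 h H^2)
  h <- mean(c(0, 1, 2, 1) == 1)
  expect_equal(forensic_parameters(c(0, 1, 2, 1))$pe,
               h^2 * (1 - 2 * h * (1 - h)^2))
})

test_that("forensic statistics are probabilities and cumulate correctly", {
  set.seed(41)
  gm <- simulate_study(sim_config(seed = 43, n_loci = 12))$genotypes
  fs <- forensic_summary(gm)
  per <- fs$per_locus
  expect_true(all(per$mp >= 0 & per$mp <= 1))
  expect_true(all(per$pd >= 0 & per$pd <= 1))
  expect_true(all(per$pic >= 0 & per$pic <= 1))
  expect_true(all(per$pe >= 0 & per$pe <= 1))
  expect_equal(per$pd, 1 - per$mp)
  expect_equal(fs$cpd, 1 - prod(1 - per$pd), tolerance = 1e-15)
  expect_gte(fs$cpd, max(per$pd))
})

test_that("cumulative_panel_stats identities", {
  one <- data.frame(pd = 0.4, pe = 0.2)
  expect_equal(cumulative_panel_stats(one)$cpd, 0.4)
  two <- data.frame(pd = c(0.5, 0.5), pe = c(0, 0))
  expect_equal(cumulative_panel_stats(two)$cpd, 0.75)
  absorbing <- data.frame(pd = c(1, 0.3), pe = c(0.1, 0.1))
  expect_equal(cumulative_panel_stats(absorbing)$cpd, 1)
})

test_that("HWE rejection rate on HWE data is conservative (quick check)", {
  set.seed(47)
  p <- 0.3; n <- 98
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  reject <- vapply(seq_len(1000), function(i) {
    cnt <- as.vector(rmultinom(1, n, probs))
    pv <- hwe_exact_test(cnt[1], cnt[2], cnt[3])
    !is.na(pv) && pv < 0.05
  }, TRUE)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(reject), 0.05 + 3 * se)
})
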