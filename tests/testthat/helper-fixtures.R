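# Shared fixtures, built in code.

# A tiny deterministic genotype matrix: 6 samples, 4 loci, one missing call.
tiny_gm <- function() {
  codes <- rbind(
    s1 = c(0L, 2L, 1L, 0L),
    s2 = c(1L, 2L, 1L, 0L),
    s3 = c(2L, 2L, 0L, 0L),
    s4 = c(0L, 1L, 2L, 0L),
    s5 = c(1L, NA, 1L, 0L),
    s6 = c(2L, 0L, 0L, 0L))
  colnames(codes) <- paste0("rs", 1:4)
  genotype_matrix(codes)
}

tiny_manifest <- function() {
  population_manifest(
    sample = paste0("s", 1:6),
    population = c("P1", "P1", "P1", "P2", "P2", "P2"),
    super_population = c("S1", "S1", "S1", "S2", "S2", "S2"))
}

# Two sharply separated populations: fixed opposite alleles at every locus.
separated_gm <- function(n_per = 5, n_loci = 30) {
  codes <- rbind(matrix(0L, n_per, n_loci), matrix(2L, n_per, n_loci))
  rownames(codes) <- c(sprintf("a%02d", seq_len(n_per)),
                       sprintf("b%02d", seq_len(n_per)))
  colnames(codes) <- sprintf("L%02d", seq_len(n_loci))
  list(gm = genotype_matrix(codes),
       manifest = population_manifest(
         rownames(codes),
         rep(c("GA", "GB"), each = n_per),
         rep(c("GA", "GB"), each = n_per)))
}

# Write a small VCF text fixture and return its path.
write_vcf_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("s1", "s2", "s3")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_row <- function(id, gts, chrom = "1", pos = 100, ref = "A", alt = "G") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Independent log-factorial oracle for the exact HWE test.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(NA_real_)
  hets <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- (n_b - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, 0)
  p <- exp(logp)
  p_obs <- p[hets == n_ab]
  min(sum(p[p <= p_obs * (1 + 1e-12)]), 1)
}
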