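test_that("Nei DA matches hand-computed values and metric basics", {
  ident <- allele_freq_table(rbind(X = c(a = 0.3, b = 0.7),
                                   Y = c(a = 0.3, b = 0.7)))
  expect_equal(nei_da(ident)["X", "Y"], 0)
  opposite <- allele_freq_table(rbind(X = c(a = 0, b = 1),
                                      Y = c(a = 1, b = 0)))
  expect_equal(nei_da(opposite)["X", "Y"], 1)
  worked <- allele_freq_table(rbind(X = c(a = 0.5, b = 0.5),
                                    Y = c(a = 0.5, b = 1.0)))
  expect_equal(nei_da(worked)["X", "Y"],
               1 - 0.5 * ((sqrt(0.25) + sqrt(0.25)) + sqrt(0.5)),
               tolerance = 1e-12)   # ~0.146447
  # symmetry, zero diagonal, [0,1]
  set.seed(71)
  f <- matrix(runif(4 * 10), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("l", 1:10)))
  d <- nei_da(allele_freq_table(f))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_true(all(d >= 0 & d <= 1))
  # undefined cells drop the locus with a warning
  f2 <- f; f2[1, 1] <- NaN
  expect_warning(d2 <- nei_da(allele_freq_table(f2)), "dropping")
  expect_equal(dim(d2), c(4, 4))
})

test_that("pairwise Fst matrix combines loci by ratio of sums", {
  ident <- allele_freq_table(rbind(X = c(a = 0.3, b = 0.7),
                                   Y = c(a = 0.3, b = 0.7)))
  expect_equal(pairwise_fst_matrix(ident)["X", "Y"], 0)
  fixed <- allele_freq_table(rbind(X = c(a = 0, b = 1),
                                   Y = c(a = 1, b = 0)))
  expect_equal(pairwise_fst_matrix(fixed)["X", "Y"], 1)
  single <- allele_freq_table(rbind(X = c(a = 0.9), Y = c(a = 0.1)))
  expect_equal(pairwise_fst_matrix(single)["X", "Y"], fst_nei(c(0.9, 0.1)))
  mono <- allele_freq_table(rbind(X = c(a = 0, b = 1), Y = c(a = 0, b = 1)))
  expect_equal(pairwise_fst_matrix(mono)["X", "Y"], 0)
})

test_that("3-taxon NJ recovers the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  cd <- ape::cophenetic.phylo(tree)
  expect_equal(cd[rownames(d), colnames(d)], d)
  el <- setNames(tree$edge.length,
                 tree$tip.label[tree$edge[, 2]])
  expect_equal(el[["A"]], (3 + 4 - 5) / 2)
  expect_equal(el[["B"]], (3 + 5 - 4) / 2)
  expect_equal(el[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ recovers a known additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):5,C:3,D:4) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  bl <- c(A = 1, B = 2, C = 3, D = 4); internal <- 5
  d["A", "B"] <- d["B", "A"] <- bl["A"] + bl["B"]
  d["C", "D"] <- d["D", "C"] <- bl["C"] + bl["D"]
  for (x in c("A", "B")) for (y in c("C", "D"))
    d[x, y] <- d[y, x] <- bl[x] + internal + bl[y]
  tree <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d)
  truth <- ape::read.tree(text = "((A:1,B:2):5,C:3,D:4);")
  expect_equal(ape::dist.topo(ape::unroot(truth), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
  # invalid inputs
  expect_error(neighbor_joining(matrix(0, 2, 2)), ">= 3")
  asym <- d; asym[1, 2] <- 99
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("NJ on ultrametric distances matches single-linkage topology", {
  set.seed(73)
  for (rep in 1:5) {
    truth <- ape::rcoal(6)
    d <- ape::cophenetic.phylo(truth)
    njt <- neighbor_joining(d)
    sl <- ape::as.phylo(hclust(as.dist(d), method = "single"))
    expect_equal(ape::dist.topo(ape::unroot(sl), njt), 0,
                 ignore_attr = TRUE)
  }
})

test_that("newick serialization round-trips and quotes awkward labels", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  s <- to_newick(tree)
  expect_match(s, "^\\(.*\\);$")
  back <- from_newick(s)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[c("A", "B", "C"), c("A", "B", "C")],
               ape::cophenetic.phylo(tree)[c("A", "B", "C"), c("A", "B", "C")])
  # spaces are quoted
  dimnames(d) <- rep(list(c("Study group", "East Asia", "Europe")), 2)
  s2 <- to_newick(neighbor_joining(d))
  expect_match(s2, "'Study group'", fixed = TRUE)
  expect_setequal(from_newick(s2)$tip.label,
                  c("Study group", "East Asia", "Europe"))
})

test_that("random additive trees are recovered in topology and length", {
  set.seed(79)
  for (rep in 1:20) {
    ntax <- sample(4:8, 1)
    truth <- ape::rtree(ntax, br = function(n) runif(n, 0.1, 2))
    d <- ape::cophenetic.phylo(truth)
    tree <- neighbor_joining(d)
    expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(truth), tree), 0,
                 ignore_attr = TRUE)
  }
})

test_that("population PCA separates structured frequency vectors", {
  # identical populations share coordinates
  f <- rbind(P1 = c(0.1, 0.9, 0.4, 0.6), P2 = c(0.1, 0.9, 0.4, 0.6),
             P3 = c(0.9, 0.1, 0.8, 0.2))
  colnames(f) <- paste0("l", 1:4)
  res <- pca_populations(allele_freq_table(f))
  expect_equal(res$scores["P1", ], res$scores["P2", ], tolerance = 1e-10)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-12)
  # within-super distances smaller than between on PC1-2
  study <- simulate_study(sim_config(seed = 83, admixed = list()))
  aft <- allele_frequencies(study$genotypes, study$manifest,
                            level = "population")
  expect_equal(nrow(pca_populations(aft)$scores), 4)
})

test_that("individual PCA handles missing data and separates populations", {
  sep <- separated_gm(n_per = 10, n_loci = 25)
  gm <- sep$gm
  gm$codes[1, 3] <- NA_integer_   # mean imputation path
  res <- pca_individuals(gm)
  pc1 <- res$scores[, 1]
  ga <- pc1[1:10]; gb <- pc1[11:20]
  expect_true(max(ga) < min(gb) || min(ga) > max(gb))  # zero overlap
  # duplicated individual gets identical scores
  codes <- rbind(gm$codes, dup = gm$codes["a01", ])
  rownames(codes) <- c(rownames(gm$codes), "dup")
  res2 <- pca_individuals(genotype_matrix(codes))
  expect_equal(res2$scores["dup", ], res2$scores["a01", ],
               tolerance = 1e-10)
  # constant locus contributes zero loading variance
  const <- genotype_matrix(rbind(a = c(x = 1L, y = 0L), b = c(x = 1L, y = 2L),
                                 c = c(x = 1L, y = 1L)))
  res3 <- pca_individuals(const)
  expect_lt(abs(res3$loadings["x", 1]), 1e-10)
  # all-missing locus dropped with warning
  gm2 <- gm
  gm2$codes[, 5] <- NA_integer_
  expect_warning(pca_individuals(gm2), "all-missing")
})

test_that("PCA scores are row-order invariant up to sign", {
  sep <- separated_gm(n_per = 6, n_loci = 12)
  set.seed(89)
  perm <- sample(nrow(sep$gm$codes))
  r1 <- pca_individuals(sep$gm)
  r2 <- pca_individuals(subset_genotypes(
    sep$gm, samples = samples_of(sep$gm)[perm]))
  for (pc in 1:2) {
    a <- r1$scores[samples_of(sep$gm), pc]
    b <- r2$scores[samples_of(sep$gm), pc]
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-8)) ||
                  isTRUE(all.equal(a, -b, tolerance = 1e-8)))
  }
})

test_that("matrix TSV writer round-trips labelled matrices", {
  m <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, p)
  expect_equal(read_matrix_tsv(p), m)
})
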