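# Between-population analyses: Nei's DA distances, multi-locus pairwise
# Gst, neighbor-joining trees (newick-serializable), and PCA at the
# population and individual level.

#' Nei's DA genetic distance matrix
#'
#' DA(X, Y) = 1 - (1/L) sum_l sum_{j in \{ref, alt\}} sqrt(x_lj y_lj):
#' zero for identical frequency vectors, one for fixed opposite alleles at
#' every locus.  Loci with an undefined frequency in any requested group
#' are dropped (with a warning) and L adjusted.
#'
#' @param aft An `allele_freq_table`.
#' @param groups Group labels to include (default all).
#' @return Symmetric labelled matrix with zero diagonal.
#' @export
nei_da <- function(aft, groups = aft$groups) {
  f <- aft$alt_freq[groups, , drop = FALSE]
  bad <- colSums(is.nan(f)) > 0
  if (any(bad)) {
    warning(sprintf("dropping %d locus/loci with undefined frequencies",
                    sum(bad)), call. = FALSE)
    f <- f[, !bad, drop = FALSE]
  }
  assert_that(ncol(f) >= 1, "no loci with defined frequencies")
  K <- nrow(f)
  d <- matrix(0, K, K, dimnames = list(groups, groups))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    shared <- sqrt(f[i, ] * f[j, ]) + sqrt((1 - f[i, ]) * (1 - f[j, ]))
    d[i, j] <- d[j, i] <- 1 - mean(shared)
  }
  d
}

#' Multi-locus pairwise Fst matrix
#'
#' Per pair, loci are combined by ratio of sums: Fst = sum_l (H_T,l -
#' H_S,l) / sum_l H_T,l with the Gst components of [fst_nei()].  A pair
#' monomorphic at every locus gets 0.
#'
#' @param aft An `allele_freq_table`.
#' @param groups Group labels to include (default all).
#' @return Symmetric labelled matrix with zero diagonal.
#' @export
pairwise_fst_matrix <- function(aft, groups = aft$groups) {
  assert_that(length(groups) >= 2, "need >= 2 groups")
  f <- aft$alt_freq[groups, , drop = FALSE]
  K <- nrow(f)
  d <- matrix(0, K, K, dimnames = list(groups, groups))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    ok <- !is.nan(f[i, ]) & !is.nan(f[j, ])
    pbar <- (f[i, ok] + f[j, ok]) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- (2 * f[i, ok] * (1 - f[i, ok]) + 2 * f[j, ok] * (1 - f[j, ok])) / 2
    d[i, j] <- d[j, i] <- if (sum(ht) == 0) 0 else sum(ht - hs) / sum(ht)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); exact on additive distances.
#' Negative estimated branch lengths are clamped to zero for display, as
#' tree-drawing tools conventionally do.
#'
#' @param d Symmetric non-negative distance matrix with labels (>= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  assert_that(nrow(d) >= 3, "need >= 3 taxa")
  assert_that(isSymmetric(unname(d), tol = 1e-8), "distance matrix not symmetric")
  assert_that(all(d >= 0), "negative distances")
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Serialize / parse a tree as newick
#'
#' Labels containing whitespace or newick metacharacters are wrapped in
#' single quotes per the newick convention; `from_newick()` strips such
#' quotes again, so the pair round-trips.
#'
#' @param tree An `ape::phylo` tree.
#' @return `to_newick()`: a newick string (with branch lengths);
#'   `from_newick()`: a `phylo`.
#' @export
to_newick <- function(tree) {
  labs <- tree$tip.label
  need <- grepl("[][[:space:]();:,']", labs)
  if (!any(need)) return(ape::write.tree(tree))
  ph <- sprintf("AISNPTIP%03dPH", seq_along(labs))
  tree$tip.label[need] <- ph[need]
  s <- ape::write.tree(tree)
  for (i in which(need))
    s <- sub(ph[i], sprintf("'%s'", gsub("'", "''", labs[i])), s,
             fixed = TRUE)
  s
}

#' @rdname to_newick
#' @param text A newick string.
#' @export
from_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  tr$tip.label <- gsub("''", "'", sub("^'(.*)'$", "\\1", tr$tip.label))
  tr
}

#' Population-level PCA on allele frequencies
#'
#' Column-centred covariance PCA of the groups x loci frequency matrix
#' (no scaling: the frequencies share a scale).
#'
#' @param aft An `allele_freq_table` with >= 2 groups and >= 2 loci.
#' @return List of class `pca_result`: `scores` (entities x PCs),
#'   `explained` (variance fractions), `loadings`.
#' @export
pca_populations <- function(aft) {
  f <- aft$alt_freq
  assert_that(nrow(f) >= 2 && ncol(f) >= 2, "need >= 2 groups and >= 2 loci")
  bad <- colSums(is.nan(f)) > 0
  f <- f[, !bad, drop = FALSE]
  pca_result(stats::prcomp(f, center = TRUE, scale. = FALSE))
}

#' Individual-level PCA on genotype dosages
#'
#' Missing dosages are imputed with the locus mean before centring (so
#' they contribute nothing to the covariance); loci that are entirely
#' missing are dropped with a warning.  By default genotypes are not
#' scaled; `scale = TRUE` standardizes each locus.
#'
#' @param gm A `genotype_matrix` with >= 2 individuals.
#' @param scale Standardize loci before decomposition.
#' @return A `pca_result` (see [pca_populations()]).
#' @export
pca_individuals <- function(gm, scale = FALSE) {
  g <- gm$codes
  assert_that(nrow(g) >= 2, "need >= 2 individuals")
  allmiss <- colSums(!is.na(g)) == 0
  if (any(allmiss)) {
    warning(sprintf("dropping %d all-missing locus/loci", sum(allmiss)),
            call. = FALSE)
    g <- g[, !allmiss, drop = FALSE]
  }
  g <- apply(g, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  if (scale) {
    sds <- apply(g, 2, stats::sd)
    g <- g[, sds > 0, drop = FALSE]
  }
  pca_result(stats::prcomp(g, center = TRUE, scale. = scale))
}

pca_result <- function(pr) {
  v <- pr$sdev^2
  structure(list(scores = pr$x, explained = v / sum(v),
                 loadings = pr$rotation), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d entities, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$explained[1],
              100 * (if (length(x$explained) > 1) x$explained[2] else 0)))
  invisible(x)
}

#' Write a labelled square matrix as TSV
#' @param m Labelled matrix.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square matrix from TSV
#' @param path File path.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
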