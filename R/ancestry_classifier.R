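# Naive-Bayes ancestry assignment with HWE genotype likelihoods.
#
# Training frequencies are Laplace-smoothed, f = (x + 1) / (2n + 2), so
# genotype likelihoods are always finite; an individual's log-likelihood
# under group k is the sum over non-missing loci of log P(g | f_k) with
# P = f^2, 2f(1-f), (1-f)^2 for dosages 2, 1, 0.  Leave-one-out
# cross-validation refits only the held-out individual's own group.

#' Fit a naive-Bayes ancestry model
#'
#' @param gm Training `genotype_matrix`.
#' @param manifest A `population_manifest`.
#' @param level Grouping level (default super-population).
#' @param priors Optional named prior probabilities per group (default
#'   uniform).
#' @return List of class `nb_model`: `groups`, `freq` (smoothed, groups x
#'   loci), `alt_counts`, `chrom_counts`, `priors`, `rsids`.
#' @export
nb_fit <- function(gm, manifest,
                   level = c("super_population", "population", "pooled"),
                   priors = NULL) {
  level <- match.arg(level)
  grp <- manifest_groups(manifest, gm,
                         level = if (level == "pooled") "pooled" else level)
  groups <- unique(grp)
  assert_that(length(groups) >= 2, "need >= 2 training groups")
  L <- ncol(gm$codes)
  x <- matrix(0, length(groups), L, dimnames = list(groups, rsids_of(gm)))
  n2 <- x
  for (g in groups) {
    sub <- gm$codes[grp == g, , drop = FALSE]
    x[g, ] <- colSums(sub, na.rm = TRUE)
    n2[g, ] <- 2 * colSums(!is.na(sub))
  }
  if (is.null(priors)) {
    priors <- rep(1 / length(groups), length(groups))
    names(priors) <- groups
  }
  assert_that(abs(sum(priors) - 1) < 1e-8, "priors must sum to 1")
  structure(list(groups = groups, freq = (x + 1) / (n2 + 2),
                 alt_counts = x, chrom_counts = n2,
                 priors = priors[groups], rsids = rsids_of(gm),
                 smoothing = "laplace_add_one"),
            class = "nb_model")
}

#' Per-group genotype log-likelihoods
#'
#' @param codes Dosage vector aligned with `model$rsids` (`NA` skipped).
#' @param model An `nb_model`.
#' @return Named numeric vector of log-likelihoods (one per group).
#' @export
nb_log_likelihood <- function(codes, model) {
  obs <- !is.na(codes)
  f <- model$freq[, obs, drop = FALSE]
  g <- codes[obs]
  ll <- numeric(nrow(f))
  if (length(g)) {
    gm2 <- matrix(g, nrow(f), length(g), byrow = TRUE)
    lp <- ifelse(gm2 == 2, 2 * log(f),
                 ifelse(gm2 == 1, log(2) + log(f) + log(1 - f),
                        2 * log(1 - f)))
    ll <- rowSums(lp)
  }
  stats::setNames(ll, model$groups)
}

#' Classify one individual
#'
#' Posterior over groups is computed in log space (log-sum-exp) from
#' prior x HWE genotype likelihood; the maximum-posterior group is
#' assigned, with exact ties broken toward the first group in the model's
#' fixed group order and flagged.
#'
#' @param codes Dosage vector aligned with `model$rsids`.
#' @param model An `nb_model`.
#' @return List: `loglik`, `posterior`, `assigned`, `tie`, `n_loci_used`.
#' @export
nb_classify <- function(codes, model) {
  ll <- nb_log_likelihood(codes, model)
  lp <- ll + log(model$priors)
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  best <- which(lp >= max(lp) - 1e-12)
  list(loglik = ll, posterior = post,
       assigned = model$groups[best[1]],
       tie = length(best) > 1,
       n_loci_used = sum(!is.na(codes)))
}

#' Classify a cohort
#'
#' @param gm A `genotype_matrix` whose loci are a subset of the model's.
#' @param model An `nb_model`.
#' @return List of class `classification_result`: `per_individual` data
#'   frame (posterior per group, `assigned`, `tie`, `n_loci_used`) and
#'   `summary` (assignment proportions per group).
#' @export
classify_cohort <- function(gm, model) {
  shared <- intersect(model$rsids, rsids_of(gm))
  assert_that(length(shared) > 0, "no loci shared with the model")
  sub <- model
  keep <- match(shared, model$rsids)
  sub$freq <- model$freq[, keep, drop = FALSE]
  sub$rsids <- shared
  rows <- lapply(samples_of(gm), function(s) {
    r <- nb_classify(gm$codes[s, shared], sub)
    c(list(sample = s), as.list(r$posterior), list(
      assigned = r$assigned, tie = r$tie, n_loci_used = r$n_loci_used))
  })
  if (length(rows)) {
    per <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    per <- as.data.frame(c(list(sample = character(0)),
                           stats::setNames(rep(list(numeric(0)),
                                               length(model$groups)),
                                           model$groups),
                           list(assigned = character(0),
                                tie = logical(0),
                                n_loci_used = integer(0))))
  }
  names(per)[2:(1 + length(model$groups))] <-
    paste0("post_", model$groups)
  summary <- prop.table(table(factor(per$assigned, levels = model$groups)))
  if (!nrow(per)) summary[] <- 0
  structure(list(per_individual = per, summary = summary),
            class = "classification_result")
}

#' Leave-one-out cross-validated confusion matrix
#'
#' For each individual in input order: its own group's allele counts are
#' reduced by its genotype, that group's smoothed frequencies refitted
#' (other groups are untouched -- removing a non-member cannot change
#' them), the individual classified, and the assignment tallied.  The
#' procedure is fully deterministic.
#'
#' @param gm Training `genotype_matrix`.
#' @param manifest A `population_manifest`.
#' @param level Grouping level (default super-population).
#' @return List of class `confusion_matrix`: `proportions` (K x K
#'   row-stochastic, rows = true group), `counts`, `row_n`,
#'   `assignments` (per-individual data frame).
#' @export
nb_loocv <- function(gm, manifest,
                     level = c("super_population", "population")) {
  level <- match.arg(level)
  model <- nb_fit(gm, manifest, level = level)
  grp <- manifest_groups(manifest, gm, level)
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2]
  assert_that(length(small) == 0, "group(s) with < 2 samples: %s",
              paste(small, collapse = ", "))
  groups <- model$groups
  counts <- matrix(0L, length(groups), length(groups),
                   dimnames = list(groups, groups))
  out <- vector("list", nrow(gm$codes))
  for (i in seq_len(nrow(gm$codes))) {
    g <- grp[i]
    codes <- gm$codes[i, ]
    obs <- !is.na(codes)
    m2 <- model
    x <- model$alt_counts[g, ]
    n2 <- model$chrom_counts[g, ]
    x[obs] <- x[obs] - codes[obs]
    n2[obs] <- n2[obs] - 2
    m2$freq[g, ] <- (x + 1) / (n2 + 2)
    r <- nb_classify(codes, m2)
    counts[g, r$assigned] <- counts[g, r$assigned] + 1L
    out[[i]] <- data.frame(sample = samples_of(gm)[i], true = g,
                           assigned = r$assigned, tie = r$tie,
                           posterior = max(r$posterior),
                           stringsAsFactors = FALSE)
  }
  row_n <- rowSums(counts)
  structure(list(proportions = counts / row_n, counts = counts,
                 row_n = row_n, assignments = do.call(rbind, out)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 4, ...) {
  cat("Leave-one-out confusion matrix (rows = true group):\n")
  print(round(x$proportions, digits))
  invisible(x)
}

#' Write a confusion matrix as TSV
#' @param cm A `confusion_matrix`.
#' @param path File path.
#' @param panel_label Optional first-column label for multi-panel tables.
#' @export
write_confusion_tsv <- function(cm, path, panel_label = "panel") {
  df <- data.frame(panel = panel_label, true = rownames(cm$proportions),
                   n = as.integer(cm$row_n),
                   as.data.frame(cm$proportions), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
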