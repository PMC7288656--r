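# Maximum-likelihood admixture decomposition (unsupervised).
#
# Model: individual i carries ancestry fractions q_i over K ancestral
# populations with allele frequencies f_k; its dosage at locus l is
# Binomial(2, pi_il) with pi_il = sum_k q_ik f_kl.  The likelihood is
# maximized by EM (expected ancestry-count updates), which shares the
# model and the Delta-log-likelihood < 1e-4 termination rule with the
# block-relaxation optimizer of the ADMIXTURE program while guaranteeing
# a monotone log-likelihood.

F_EPS <- 1e-6

#' Admixture binomial log-likelihood
#'
#' LL = sum_i sum_l \[ g_il log(pi_il) + (2 - g_il) log(1 - pi_il) \],
#' with pi = Q F and missing genotypes skipped.  (The binomial coefficient
#' is a constant and omitted, as in ADMIXTURE.)
#'
#' @param gm A `genotype_matrix`.
#' @param q Row-stochastic individuals x K matrix.
#' @param f K x loci matrix of ancestral frequencies in (0, 1).
#' @return The log-likelihood.
#' @export
admixture_loglik <- function(gm, q, f) {
  g <- gm$codes
  assert_that(nrow(q) == nrow(g) && ncol(q) == nrow(f) &&
                ncol(f) == ncol(g), "dimension mismatch")
  f <- pmin(pmax(f, F_EPS), 1 - F_EPS)
  p <- q %*% f
  term <- g * log(p) + (2 - g) * log(1 - p)
  sum(term[!is.na(g)])
}

#' One EM step for the admixture model
#'
#' Standard expected-ancestry-count updates: each observed allele is
#' fractionally attributed to ancestry k by its responsibility; Q rows
#' become normalized expected ancestry counts over the individual's 2L
#' observed alleles, F the expected alt fraction per (ancestry, locus).
#' The log-likelihood never decreases.  F is clamped to
#' \[1e-6, 1 - 1e-6\] after each update.
#'
#' @inheritParams admixture_loglik
#' @return List `q`, `f` (updated state).
#' @export
admixture_em_step <- function(gm, q, f) {
  g <- gm$codes
  K <- ncol(q)
  f <- pmin(pmax(f, F_EPS), 1 - F_EPS)
  p <- q %*% f
  galt <- g
  gref <- 2 - g
  miss <- is.na(g)
  galt[miss] <- 0
  gref[miss] <- 0
  qn <- matrix(0, nrow(q), K, dimnames = dimnames(q))
  fn <- matrix(0, K, ncol(f), dimnames = dimnames(f))
  falt <- matrix(0, K, ncol(f))
  ftot <- matrix(0, K, ncol(f))
  for (k in seq_len(K)) {
    ra <- (q[, k] %o% f[k, ]) / p          # responsibility, alt alleles
    rr <- (q[, k] %o% (1 - f[k, ])) / (1 - p)
    ea <- galt * ra
    er <- gref * rr
    qn[, k] <- rowSums(ea + er)
    falt[k, ] <- colSums(ea)
    ftot[k, ] <- colSums(ea + er)
  }
  qn <- qn / rowSums(qn)
  fn <- ifelse(ftot > 0, falt / ftot, f)
  fn <- pmin(pmax(fn, F_EPS), 1 - F_EPS)
  dimnames(fn) <- dimnames(f)
  list(q = qn, f = fn)
}

#' Fit the admixture model for one K
#'
#' Random initialization under `seed` (Q rows ~ Dirichlet(1, ..., 1), F ~
#' Uniform(0.05, 0.95)), then EM until the log-likelihood increases by
#' less than `tol` (default 1e-4, the conventional termination rule) or
#' `max_iter` iterations.
#'
#' @param gm A `genotype_matrix` with n >= K individuals.
#' @param k Number of ancestral populations (>= 1).
#' @param seed Integer seed for the initialization.
#' @param max_iter,tol Termination controls.
#' @return List of class `admixture_fit`: `k`, `q`, `f`, `loglik_trace`,
#'   `loglik`, `converged`, `n_iterations`, `seed`.
#' @export
admixture_fit <- function(gm, k, seed = 1L, max_iter = 2000, tol = 1e-4) {
  n <- nrow(gm$codes)
  L <- ncol(gm$codes)
  assert_that(k >= 1, "K must be >= 1")
  assert_that(n >= k, "need at least K individuals (n=%d < K=%d)", n, k)
  set.seed(derive_seed(seed, 5))
  if (k == 1L) {
    q <- matrix(1, n, 1, dimnames = list(samples_of(gm), NULL))
    f <- matrix(pmin(pmax(colMeans(gm$codes, na.rm = TRUE) / 2, F_EPS),
                     1 - F_EPS), 1, L, dimnames = list(NULL, rsids_of(gm)))
  } else {
    q <- matrix(stats::rgamma(n * k, 1), n, k,
                dimnames = list(samples_of(gm), NULL))
    q <- q / rowSums(q)
    f <- matrix(stats::runif(k * L, 0.05, 0.95), k, L,
                dimnames = list(NULL, rsids_of(gm)))
  }
  trace <- admixture_loglik(gm, q, f)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    st <- admixture_em_step(gm, q, f)
    q <- st$q
    f <- st$f
    ll <- admixture_loglik(gm, q, f)
    trace <- c(trace, ll)
    if (ll - trace[iter] < tol) { converged <- TRUE; break }
  }
  structure(list(k = as.integer(k), q = q, f = f, loglik_trace = trace,
                 loglik = trace[length(trace)], converged = converged,
                 n_iterations = iter, seed = as.integer(seed)),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K=%d, n=%d, LL=%.2f, %d iterations (%s)\n",
              x$k, nrow(x$q), x$loglik, x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fit a range of K values, best of several seeds
#'
#' @param gm A `genotype_matrix`.
#' @param ks Integer vector of K values (default 2:6).
#' @param n_seeds Restarts per K (default 5); the fit with the best final
#'   log-likelihood is kept.
#' @param seed Master seed; restart seeds are derived from it.
#' @param ... Passed to [admixture_fit()].
#' @return Named list of `admixture_fit` objects ("K2", "K3", ...).
#' @export
run_k_range <- function(gm, ks = 2:6, n_seeds = 5, seed = 1L, ...) {
  out <- lapply(ks, function(k) {
    fits <- lapply(seq_len(n_seeds), function(s)
      admixture_fit(gm, k, seed = derive_seed(seed, 100 * k + s), ...))
    fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  })
  names(out) <- paste0("K", ks)
  out
}

#' Align ancestry columns to a reference Q matrix
#'
#' Admixture components are identified only up to label switching; this
#' greedily permutes columns of `q` (and rows of `f`) to best match
#' `q_ref`.
#'
#' @param fit An `admixture_fit` (or list with `q`, `f`).
#' @param q_ref Reference Q matrix with the same dimensions.
#' @return The fit with permuted columns and `permutation` recorded.
#' @export
align_ancestry <- function(fit, q_ref) {
  K <- ncol(fit$q)
  assert_that(ncol(q_ref) == K, "reference Q has different K")
  perms <- all_permutations(K)
  costs <- vapply(perms, function(pp)
    mean(abs(fit$q[, pp, drop = FALSE] - q_ref)), 0)
  best <- perms[[which.min(costs)]]
  fit$q <- fit$q[, best, drop = FALSE]
  fit$f <- fit$f[best, , drop = FALSE]
  fit$permutation <- best
  fit
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}

#' Write Q / F matrices in ADMIXTURE-compatible layout
#'
#' `.Q`: whitespace-delimited, one row per individual, K columns; `.P`:
#' one row per locus, K columns.
#'
#' @param fit An `admixture_fit`.
#' @param prefix Output path prefix (writes `<prefix>.Q`, `<prefix>.P`,
#'   `<prefix>.loglik.tsv`).
#' @export
write_admixture <- function(fit, prefix) {
  utils::write.table(format(fit$q, digits = 6), paste0(prefix, ".Q"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(format(t(fit$f), digits = 6), paste0(prefix, ".P"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(iteration = seq_along(fit$loglik_trace) - 1L,
               loglik = fit$loglik_trace),
    paste0(prefix, ".loglik.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(prefix)
}
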