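# Bayesian admixture clustering (STRUCTURE-style Gibbs sampler with
# independent allele frequencies, lambda = 1), marginal-likelihood
# estimation, and Evanno delta-K model selection.

#' Fit the admixture clustering model for a given K
#'
#' Gibbs sampler over allele-origin assignments z, cluster allele
#' frequencies P (Dirichlet(1) prior), and individual membership vectors
#' Q (Dirichlet(alpha) prior, with alpha updated by a Metropolis step
#' under a uniform prior on (0, 10]).  The marginal likelihood
#' ln Pr(X|K) is estimated as \code{mean(lnL) - var(lnL)/2} over
#' post-burn-in sweeps; Q and P are posterior means.
#'
#' Desk-scale defaults (burn-in = reps = 5000) are deliberately smaller
#' than the field-standard 50000; raise them for production data.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param K number of clusters (>= 1).
#' @param burnin,reps burn-in sweeps and retained sweeps.
#' @param seed RNG seed (full determinism given identical inputs).
#' @param alpha_init initial Dirichlet concentration for Q.
#' @return object of class \code{cluster_fit}: \code{K}, \code{Q}
#'   (individuals x K), \code{P} (per-locus K x alleles matrices, with
#'   allele sizes as column names), \code{lnpd}, \code{trace},
#'   \code{alpha_mean}, \code{settings}, \code{warnings}.
#' @export
fit_admixture <- function(g, K, burnin = 5000, reps = 5000, seed = 1,
                          alpha_init = 1) {
  stopifnot(K >= 1, burnin > 0, reps > 0)
  maps <- lapply(seq_along(g$loci), function(l)
    sort(unique(c(g$a1[, l], g$a2[, l]))))
  idx <- function(m, l) {
    out <- match(m[, l], maps[[l]]) - 1L
    out[is.na(out)] <- -1L
    out
  }
  A1 <- vapply(seq_along(g$loci), function(l) idx(g$a1, l),
               integer(nrow(g$a1)))
  A2 <- vapply(seq_along(g$loci), function(l) idx(g$a2, l),
               integer(nrow(g$a2)))
  if (is.null(dim(A1))) { A1 <- matrix(A1, nrow = 1); A2 <- matrix(A2, nrow = 1) }
  J <- vapply(maps, length, 0L)
  res <- with_seed(seed,
    .admixture_gibbs(A1, A2, J, as.integer(K), as.integer(burnin),
                     as.integer(reps), alpha_init, 0.25, 10.0))
  warn <- character(0)
  if (K > 1 && res$alpha_at_bound_frac > 0.5) {
    warn <- "alpha spent >50% of post-burn-in sweeps at its upper bound"
    warning(warn)
  }
  Q <- res$Q
  dimnames(Q) <- list(g$individual_ids, paste0("cluster", seq_len(K)))
  P <- res$P
  for (l in seq_along(P)) {
    dimnames(P[[l]]) <- list(paste0("cluster", seq_len(K)), maps[[l]])
  }
  names(P) <- g$loci
  structure(list(K = K, Q = Q, P = P, lnpd = res$lnpd,
                 mean_lnl = res$mean_lnl, var_lnl = res$var_lnl,
                 trace = res$trace, alpha_mean = res$alpha_mean,
                 settings = list(burnin = burnin, reps = reps, seed = seed,
                                 alpha_init = alpha_init),
                 warnings = warn),
            class = "cluster_fit")
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf("cluster_fit: K = %d, ln Pr(X|K) = %.2f (burnin %d, reps %d)\n",
              x$K, x$lnpd, x$settings$burnin, x$settings$reps))
  invisible(x)
}

#' Run replicate fits over a range of K
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param k_range integer vector of K values (e.g. \code{1:5}).
#' @param n_runs replicate runs per K (>= 2 for \code{\link{delta_k}}).
#' @param burnin,reps,seed passed to \code{\link{fit_admixture}};
#'   replicate r of K uses seed \code{seed + 1000 * K + r}.
#' @return data.frame with columns \code{K}, \code{run}, \code{lnpd}, and
#'   attribute \code{fits} (list of the underlying fits).
#' @export
admixture_scan <- function(g, k_range = 1:5, n_runs = 5, burnin = 5000,
                           reps = 5000, seed = 1) {
  rows <- list(); fits <- list()
  for (K in k_range) for (r in seq_len(n_runs)) {
    f <- fit_admixture(g, K, burnin, reps, seed = seed + 1000L * K + r)
    rows[[length(rows) + 1L]] <- data.frame(K = K, run = r, lnpd = f$lnpd)
    fits[[length(fits) + 1L]] <- f
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Evanno delta-K table
#'
#' \code{delta_k(K) = |mean_lnpd(K+1) - 2 mean_lnpd(K) + mean_lnpd(K-1)| /
#' sd_lnpd(K)}, using replicate means for the second difference and the
#' replicate standard deviation at K.  Defined only for interior K with
#' sd > 0; undefined entries are \code{NA} and flagged.
#'
#' @param runs data.frame with columns \code{K} and \code{lnpd} (replicate
#'   runs), e.g. from \code{\link{admixture_scan}}.
#' @return data.frame: K, mean_lnpd, sd_lnpd, lp (first difference), lpp
#'   (second difference), delta_k; attribute \code{best_k} = argmax.
#' @export
delta_k <- function(runs) {
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L) stop("need >= 3 consecutive K values")
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  m <- vapply(ks, function(k) mean(runs$lnpd[runs$K == k]), 0)
  s <- vapply(ks, function(k) sd(runs$lnpd[runs$K == k]), 0)
  if (any(is.na(s))) stop("need >= 2 replicate runs per K")
  n <- length(ks)
  lp <- c(NA, diff(m))
  lpp <- c(NA, m[3:n] - 2 * m[2:(n - 1)] + m[1:(n - 2)], NA)
  dk <- abs(lpp) / s
  dk[s == 0] <- NA
  if (any(s == 0 & !is.na(lpp)))
    warning("delta_k undefined where replicate sd = 0")
  out <- data.frame(K = ks, mean_lnpd = m, sd_lnpd = s, lp = lp,
                    lpp = lpp, delta_k = dk)
  interior <- which(!is.na(dk))
  attr(out, "best_k") <-
    if (length(interior)) ks[interior[which.max(dk[interior])]] else NA
  out
}

#' Mean membership proportions per locality
#'
#' @param fit a \code{cluster_fit}.
#' @param localities character vector of locality labels, one per
#'   individual (defaults to the genotype matrix used for the fit if
#'   supplied via \code{g}).
#' @param g optionally, the \code{\link{genotype_matrix}} the fit came
#'   from; its locality labels are used.
#' @return matrix localities x K; rows sum to 1.
#' @export
membership_by_locality <- function(fit, localities = NULL, g = NULL) {
  if (is.null(localities)) {
    if (is.null(g)) stop("supply localities or g")
    if (!identical(g$individual_ids, rownames(fit$Q)))
      stop("fit and genotype matrix do not share individuals")
    localities <- g$locality_ids
  }
  if (length(localities) != nrow(fit$Q))
    stop("one locality label per individual required")
  agg <- rowsum(fit$Q, localities)
  sweep(agg, 1, rowSums(agg), "/")
}

#' Match cluster labels of a membership matrix to a reference
#'
#' Label switching is handled only at evaluation time: finds the column
#' permutation of \code{Q} minimising the total absolute difference to
#' \code{Q_ref}; among equal-cost matchings the lexicographically smallest
#' permutation is chosen.
#'
#' @param Q,Q_ref membership matrices with identical dimensions.
#' @return list: \code{perm} (columns of Q in reference order),
#'   \code{Q} (permuted matrix), \code{cost}.
#' @export
match_cluster_labels <- function(Q, Q_ref) {
  stopifnot(all(dim(Q) == dim(Q_ref)))
  K <- ncol(Q)
  perms <- all_permutations(K)
  # all_permutations emits in lexicographic-insertion order; sort keys
  costs <- vapply(perms, function(p) sum(abs(Q[, p] - Q_ref)), 0)
  keys <- vapply(perms, function(p) paste(p, collapse = ","), "")
  ord <- order(costs, keys)
  best <- perms[[ord[1]]]
  list(perm = best, Q = Q[, best, drop = FALSE], cost = costs[ord[1]])
}

#' Agreement between hard assignments of two membership matrices
#' @param Q,Q_ref membership matrices (same shape); labels are matched
#'   with \code{\link{match_cluster_labels}} first.
#' @return fraction of individuals whose argmax cluster agrees.
#' @export
label_agreement <- function(Q, Q_ref) {
  m <- match_cluster_labels(Q, Q_ref)
  mean(max.col(m$Q) == max.col(Q_ref))
}
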