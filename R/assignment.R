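# Likelihood assignment of individuals to candidate source populations and
# first-generation migrant detection with a Monte Carlo null.

# per-population, per-locus allele count tables over the union of alleles
allele_count_tables <- function(g, grouping) {
  pops <- unique(grouping)
  lapply(seq_along(g$loci), function(l) {
    alleles <- sort(unique(c(g$a1[, l], g$a2[, l])))
    cnt <- matrix(0L, length(pops), length(alleles),
                  dimnames = list(pops, alleles))
    for (p in seq_along(pops)) {
      ix <- which(grouping == pops[p])
      x <- c(g$a1[ix, l], g$a2[ix, l])
      x <- x[!is.na(x)]
      if (length(x)) {
        t <- table(factor(x, levels = alleles))
        cnt[p, ] <- as.integer(t)
      }
    }
    cnt
  })
}

# log10 likelihood of one genotype (a, b; possibly NA) under counts cnt
# (vector over alleles at the locus), by method
geno_log10_lik <- function(cnt, ai, bi, method, floor, n_alleles_locus) {
  n <- sum(cnt)
  if (n == 0L) return(NA_real_)
  if (method == "frequency") {
    f <- cnt / n
    fa <- max(f[ai], floor)
    fb <- max(f[bi], floor)
    l <- if (ai == bi) fa * fb else 2 * fa * fb
    if (l <= 0) return(-Inf)
    log10(l)
  } else {  # rannala_mountain
    pr <- 1 / n_alleles_locus
    if (ai == bi) {
      l <- (cnt[ai] + pr) * (cnt[ai] + 1 + pr) / ((n + 1) * (n + 2))
    } else {
      l <- 2 * (cnt[ai] + pr) * (cnt[bi] + pr) / ((n + 1) * (n + 2))
    }
    log10(l)
  }
}

#' Likelihood assignment scores for every individual
#'
#' Two likelihood criteria are available:
#' \describe{
#'   \item{\code{frequency}}{product over loci of genotype probabilities
#'     from observed allele frequencies, with a factor 2 for
#'     heterozygotes; alleles unobserved in a reference population take a
#'     floor frequency (default 0.01, the GeneClass convention).}
#'   \item{\code{rannala_mountain}}{per-locus Dirichlet posterior
#'     predictive with prior 1/(number of alleles at the locus).}
#' }
#' With \code{leave_one_out} the individual is removed from its home
#' population's counts before computing its home likelihood.
#'
#' Scores are GeneClass-style percentages: the likelihoods of the
#' candidate populations for one individual are normalised to sum to 100.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param method \code{"frequency"} or \code{"rannala_mountain"}.
#' @param leave_one_out logical (default TRUE).
#' @param grouping optional group labels; defaults to localities.
#' @param floor zero-frequency floor for the frequency method.
#' @return data.frame with one row per individual x candidate population:
#'   \code{individual}, \code{home}, \code{population}, \code{log10_lik},
#'   \code{score}, \code{rank} (1 = most likely).
#' @export
assignment_scores <- function(g, method = c("frequency",
                                            "rannala_mountain"),
                              leave_one_out = TRUE, grouping = NULL,
                              floor = 0.01) {
  method <- match.arg(method)
  grouping <- grouping_from(g, grouping)
  pops <- unique(grouping)
  tabs <- allele_count_tables(g, grouping)
  nall <- vapply(tabs, function(t) sum(colSums(t) > 0L), 0L)
  out <- vector("list", length(g$individual_ids))
  for (i in seq_along(g$individual_ids)) {
    home <- grouping[i]
    ll <- setNames(numeric(length(pops)), pops)
    for (p in seq_along(pops)) {
      tot <- 0
      for (l in seq_along(g$loci)) {
        a <- g$a1[i, l]; b <- g$a2[i, l]
        if (is.na(a)) next
        alleles <- as.integer(colnames(tabs[[l]]))
        ai <- match(a, alleles); bi <- match(b, alleles)
        cnt <- tabs[[l]][p, ]
        if (leave_one_out && pops[p] == home) {
          cnt[ai] <- cnt[ai] - 1L
          cnt[bi] <- cnt[bi] - 1L
        }
        v <- geno_log10_lik(cnt, ai, bi, method, floor, nall[l])
        if (is.na(v)) next
        tot <- tot + v
      }
      ll[p] <- tot
    }
    lik <- 10^(ll - max(ll[is.finite(ll)]))
    score <- 100 * lik / sum(lik)
    out[[i]] <- data.frame(individual = g$individual_ids[i], home = home,
                           population = pops, log10_lik = unname(ll),
                           score = unname(score),
                           rank = rank(-ll, ties.method = "first"),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Rate of individuals whose top-ranked population is their home
#' @param scores output of \code{\link{assignment_scores}}.
#' @return numeric in [0, 1].
#' @export
self_assignment_rate <- function(scores) {
  top <- scores[scores$rank == 1L, ]
  mean(top$population == top$home)
}

# log10 Lambda = log10 L_home - log10 L_max for one genotype matrix row
# given per-pop log10 likelihoods
lambda_stat <- function(ll, home) ll[home] - max(ll)

#' Detect first-generation migrants
#'
#' For each individual the statistic \code{Lambda = L_home / L_max} is
#' computed on the log10 scale (home likelihood leave-one-out, by the
#' frequency criterion).  The null distribution is built per home
#' population by simulating \code{n_sim} genotypes from that population's
#' observed allele frequencies (alleles drawn independently per locus,
#' with replacement); the resident probability is the fraction of
#' simulated Lambda values at or below the observed one, and individuals
#' with \code{P < alpha} are flagged as putative migrants.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param n_sim simulated genotypes per home population (default 1000).
#' @param alpha type-I error for flagging (default 0.01).
#' @param seed RNG seed.
#' @param grouping optional group labels; defaults to localities.
#' @param floor zero-frequency floor (see
#'   \code{\link{assignment_scores}}).
#' @return data.frame: \code{individual}, \code{home}, \code{log10_lambda},
#'   \code{p_resident}, \code{flagged}, \code{best_population}.
#' @export
detect_first_gen_migrants <- function(g, n_sim = 1000, alpha = 0.01,
                                      seed = 1, grouping = NULL,
                                      floor = 0.01) {
  grouping <- grouping_from(g, grouping)
  pops <- unique(grouping)
  small <- pops[vapply(pops, function(p) sum(grouping == p), 0L) < 2L]
  if (length(small)) {
    warning("populations skipped (fewer than 2 individuals): ",
            paste(small, collapse = ", "))
  }
  tabs <- allele_count_tables(g, grouping)
  nall <- vapply(tabs, function(t) sum(colSums(t) > 0L), 0L)

  pop_ll <- function(a1, a2, home, loo_home) {
    ll <- setNames(numeric(length(pops)), pops)
    for (p in seq_along(pops)) {
      tot <- 0
      for (l in seq_along(g$loci)) {
        a <- a1[l]; b <- a2[l]
        if (is.na(a)) next
        alleles <- as.integer(colnames(tabs[[l]]))
        ai <- match(a, alleles); bi <- match(b, alleles)
        cnt <- tabs[[l]][p, ]
        if (loo_home && pops[p] == home) {
          cnt[ai] <- cnt[ai] - 1L
          cnt[bi] <- cnt[bi] - 1L
        }
        v <- geno_log10_lik(cnt, ai, bi, "frequency", floor, nall[l])
        if (is.na(v)) next
        tot <- tot + v
      }
      ll[p] <- tot
    }
    ll
  }

  with_seed(seed, {
    # null Lambda distributions per home population
    null_lambda <- lapply(pops, function(p) {
      freqs <- lapply(tabs, function(t) {
        cnt <- t[p, ]
        if (sum(cnt) == 0) NULL else cnt / sum(cnt)
      })
      vapply(seq_len(n_sim), function(s) {
        a1 <- a2 <- rep(NA_integer_, length(g$loci))
        for (l in seq_along(g$loci)) {
          f <- freqs[[l]]
          if (is.null(f)) next
          alleles <- as.integer(names(f))
          a1[l] <- sample(alleles, 1L, prob = f)
          a2[l] <- sample(alleles, 1L, prob = f)
        }
        ll <- pop_ll(a1, a2, p, loo_home = FALSE)
        lambda_stat(ll, p)
      }, 0)
    })
    names(null_lambda) <- pops

    rows <- lapply(seq_along(g$individual_ids), function(i) {
      home <- grouping[i]
      if (sum(grouping == home) < 2L) return(NULL)
      ll <- pop_ll(g$a1[i, ], g$a2[i, ], home, loo_home = TRUE)
      lam <- lambda_stat(ll, home)
      p_res <- mean(null_lambda[[home]] <= lam)
      data.frame(individual = g$individual_ids[i], home = home,
                 log10_lambda = unname(lam), p_resident = p_res,
                 flagged = p_res < alpha,
                 best_population = pops[which.max(ll)],
                 row.names = NULL)
    })
    do.call(rbind, rows)
  })
}
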