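# Independent oracles and fixture builders.  Every oracle here is coded
# directly from the textbook formula or by exhaustive enumeration, on a
# different code path from the package implementation it checks.

# -- fixture builders --------------------------------------------------------

# genotype matrix from a list of populations; each population is a list of
# c(a, b) genotype pairs per locus: pops[[p]][[ind]] = matrix loci x 2
toy_genotypes <- function(pops) {
  ids <- locs <- character(0)
  a1 <- a2 <- NULL
  for (p in names(pops)) {
    for (i in seq_along(pops[[p]])) {
      m <- pops[[p]][[i]]
      ids <- c(ids, sprintf("%s_%d", p, i))
      locs <- c(locs, p)
      a1 <- rbind(a1, m[, 1])
      a2 <- rbind(a2, m[, 2])
    }
  }
  genotype_matrix(ids, locs, paste0("L", seq_len(ncol(a1))), a1, a2)
}

# single-locus genotype matrix from per-pop allele vectors (paired in order)
geno_1locus <- function(...) {
  pops <- list(...)
  toy_genotypes(lapply(pops, function(al) {
    stopifnot(length(al) %% 2 == 0)
    lapply(seq_len(length(al) / 2), function(i)
      matrix(c(al[2 * i - 1], al[2 * i]), 1, 2))
  }))
}

random_alignment <- function(n, L, seed) {
  with_seed(seed, {
    seq_alignment(paste0("s", seq_len(n)),
                  vapply(seq_len(n), function(i)
                    paste(sample(c("A", "C", "G", "T"), L, TRUE),
                          collapse = ""), ""))
  })
}

# -- Weir-Cockerham (1984) two-population, two-allele oracle -----------------
# direct transcription of the single-allele theta formulas for r = 2
wc_theta_oracle_biallelic <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  comp_one <- function(p1, p2, h1, h2) {
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a, b, cc)
  }
  # sum components over the two alleles of the biallelic locus
  v <- comp_one(p1, p2, h1, h2) + comp_one(1 - p1, 1 - p2, h1, h2)
  v[1] / sum(v)
}

# -- Slatkin-type R_ST oracle: direct one-way ANOVA sums ---------------------
rst_oracle_1locus <- function(sizes1, sizes2) {
  x <- c(sizes1, sizes2)
  g <- rep(1:2, c(length(sizes1), length(sizes2)))
  N <- length(x); r <- 2
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - mean(x))^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  msb <- ssb / (r - 1); msw <- ssw / (N - r)
  n0 <- (N - sum(table(g)^2) / N) / (r - 1)
  sa <- (msb - msw) / n0
  sa / (sa + msw)
}

# -- Hurlbert rarefaction by exhaustive subsample enumeration ----------------
rarefaction_oracle <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  subs <- combn(length(genes), g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# -- Mantel P by exhaustive enumeration --------------------------------------
mantel_oracle <- function(A, B) {
  n <- nrow(A)
  ut <- upper.tri(A)
  r_obs <- cor(A[ut], B[ut])
  perms <- phylogap_all_perms(n)
  rs <- vapply(perms, function(p) cor(A[ut], B[p, p][ut]), 0)
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

phylogap_all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in phylogap_all_perms(n - 1)) for (k in seq_len(n))
    out[[length(out) + 1]] <- append(p, n, after = k - 1)
  out
}

# -- Tamura-Nei (1993) closed form, independent implementation ---------------
tn93_oracle <- function(s1, s2) {
  x <- strsplit(s1, "")[[1]]; y <- strsplit(s2, "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  pi_ <- table(factor(c(x, y), levels = c("A", "C", "G", "T"))) / (2 * n)
  gA <- pi_["A"]; gC <- pi_["C"]; gG <- pi_["G"]; gT <- pi_["T"]
  gR <- gA + gG; gY <- gC + gT
  pair <- paste0(pmin(x, y), pmax(x, y))
  P1 <- mean(pair == "AG")               # purine transitions
  P2 <- mean(pair == "CT")               # pyrimidine transitions
  Q <- mean(x != y) - P1 - P2            # transversions
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  as.numeric(-k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
             k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
             k3 * log(1 - Q / (2 * gR * gY)))
}

# -- statistical-parsimony limit, straight-line recomputation ----------------
parsimony_limit_oracle <- function(L, conf) {
  probs <- cumprod(1 - seq_len(L - 1) / L)   # probs[j] = P(j+1 steps)
  j <- 1L
  while (j < L && probs[j] >= conf) j <- j + 1L
  j
}

# -- grid least-cost oracle: Bellman-Ford value iteration --------------------
lcp_oracle <- function(res, sources, targets, neighborhood = 8) {
  v <- res$values
  nr <- nrow(v); nc <- ncol(v)
  dist <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(sources)))
    dist[sources[i, 1], sources[i, 2]] <- 0
  offs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (neighborhood == 8)
    offs <- rbind(offs, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(v[r, c]) || !is.finite(dist[r, c])) next
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(v[r2, c2])) next
        mult <- if (all(offs[k, ] != 0)) sqrt(2) else 1
        cand <- dist[r, c] + (v[r, c] + v[r2, c2]) / 2 * mult
        if (cand < dist[r2, c2] - 1e-12) {
          dist[r2, c2] <- cand
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  min(dist[as.matrix(targets)])
}

# exhaustive simple-path least-cost enumeration (small grids only)
lcp_exhaustive <- function(res, source, target) {
  v <- res$values
  nr <- nrow(v); nc <- ncol(v)
  best <- Inf
  offs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  visit <- function(r, c, cost, seen) {
    if (cost >= best) return(invisible())
    if (r == target[1] && c == target[2]) {
      best <<- min(best, cost)
      return(invisible())
    }
    for (k in seq_len(nrow(offs))) {
      r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(v[r2, c2]) || seen[r2, c2]) next
      mult <- if (all(offs[k, ] != 0)) sqrt(2) else 1
      seen[r2, c2] <- TRUE
      visit(r2, c2, cost + (v[r, c] + v[r2, c2]) / 2 * mult, seen)
      seen[r2, c2] <- FALSE
    }
  }
  seen <- matrix(FALSE, nr, nc)
  seen[source[1], source[2]] <- TRUE
  visit(source[1], source[2], 0, seen)
  best
}

# -- AUC by explicit all-pairs comparison ------------------------------------
auc_oracle <- function(pres, bg) {
  cmp <- outer(pres, bg, function(p, b) (p > b) + 0.5 * (p == b))
  mean(cmp)
}
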