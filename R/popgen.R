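# Classical microsatellite statistics: Weir-Cockerham theta, Slatkin R_ST,
# Wright's Nm, rarefied allelic richness + permutation test, great-circle
# distances, Mantel isolation-by-distance.

#' Construct a labeled symmetric pairwise matrix
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @param labels row/column labels.
#' @param statistic one of \code{"fst"}, \code{"rst"}, \code{"p_dist"},
#'   \code{"tn93"}, \code{"km"}.
#' @return object of class \code{pairwise_matrix}.
#' @export
pairwise_matrix <- function(values, labels,
                            statistic = c("fst", "rst", "p_dist", "tn93",
                                          "km")) {
  statistic <- match.arg(statistic)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (length(labels) != nrow(values)) stop("labels length mismatch")
  if (!isTRUE(all.equal(values, t(values), check.attributes = FALSE,
                        tolerance = 1e-10)))
    stop("matrix must be symmetric")
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(labels = as.character(labels), values = values,
                 statistic = statistic),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix (%s), %d labels\n", x$statistic,
              length(x$labels)))
  print(round(x$values, 4))
  invisible(x)
}

#' Export a pairwise matrix as labeled CSV
#' @param x a \code{pairwise_matrix}.
#' @param path output CSV.
#' @export
write_pairwise_csv <- function(x, path) {
  write.csv(as.data.frame(x$values), path, row.names = TRUE)
  invisible(path)
}

# per-locus allele frequencies, observed-heterozygote frequencies and
# sample sizes for one population at one locus
locus_pop_summary <- function(g, locus, idx) {
  x1 <- g$a1[idx, locus]; x2 <- g$a2[idx, locus]
  keep <- !is.na(x1)
  x1 <- x1[keep]; x2 <- x2[keep]
  n <- length(x1)                      # genotyped individuals
  if (n == 0L) return(NULL)
  alleles <- sort(unique(c(x1, x2)))
  cnt <- vapply(alleles, function(a) sum(x1 == a) + sum(x2 == a), 0L)
  het <- vapply(alleles, function(a) sum((x1 == a) != (x2 == a)), 0L)
  list(n = n, alleles = alleles, p = cnt / (2 * n), h = het / n,
       sizes = c(x1, x2))
}

grouping_from <- function(g, grouping) {
  if (is.null(grouping)) grouping <- g$locality_ids
  if (length(grouping) != length(g$individual_ids))
    stop("grouping must have one label per individual")
  as.character(grouping)
}

# Weir & Cockerham (1984) variance components for one locus, two or more
# populations; returns c(a, b, c) summed over alleles.
wc_components <- function(summaries) {
  summaries <- Filter(Negate(is.null), summaries)
  r <- length(summaries)
  if (r < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  ns <- vapply(summaries, `[[`, 0, "n")
  if (any(ns < 1L)) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  alleles <- sort(unique(unlist(lapply(summaries, `[[`, "alleles"))))
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    p <- vapply(summaries, function(s) {
      i <- match(al, s$alleles); if (is.na(i)) 0 else s$p[i] }, 0)
    h <- vapply(summaries, function(s) {
      i <- match(al, s$alleles); if (is.na(i)) 0 else s$h[i] }, 0)
    pbar <- sum(ns * p) / (r * nbar)
    s2 <- sum(ns * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * h) / (r * nbar)
    if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

theta_pair <- function(g, idx1, idx2) {
  comp <- vapply(seq_along(g$loci), function(l) {
    wc_components(list(locus_pop_summary(g, l, idx1),
                       locus_pop_summary(g, l, idx2)))
  }, c(a = 0, b = 0, c = 0))
  ok <- !is.na(comp["a", ])
  if (!any(ok)) return(NA_real_)
  num <- sum(comp["a", ok])
  den <- sum(comp["a", ok] + comp["b", ok] + comp["c", ok])
  if (den == 0) return(0)
  num / den
}

#' Pairwise multi-locus Weir-Cockerham F_ST
#'
#' Computes the Weir & Cockerham (1984) theta estimator for every pair of
#' groups, combining loci by summing variance components (the Arlequin
#' convention).  Missing genotypes are dropped per locus (pairwise
#' deletion).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param grouping character vector assigning each individual to a group;
#'   defaults to the locality labels.
#' @return a \code{\link{pairwise_matrix}} with statistic \code{"fst"};
#'   pairs where no locus is informative are \code{NA}.
#' @export
fst_pairwise <- function(g, grouping = NULL) {
  grouping <- grouping_from(g, grouping)
  pops <- unique(grouping)
  if (length(pops) < 2L) stop("need at least 2 groups")
  m <- matrix(0, length(pops), length(pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- theta_pair(g, which(grouping == pops[i]),
                                     which(grouping == pops[j]))
  }
  pairwise_matrix(m, pops, "fst")
}

# one-way gene-level ANOVA variance components on allele sizes for a locus
size_variance_components <- function(size_groups) {
  size_groups <- Filter(function(s) length(s) > 0L, size_groups)
  r <- length(size_groups)
  if (r < 2L) return(c(sa = NA_real_, sw = NA_real_))
  ns <- lengths(size_groups)
  N <- sum(ns)
  if (N - r < 1L) return(c(sa = NA_real_, sw = NA_real_))
  means <- vapply(size_groups, mean, 0)
  grand <- sum(unlist(size_groups)) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(size_groups, function(s) sum((s - mean(s))^2), 0))
  msb <- ssb / (r - 1)
  msw <- ssw / (N - r)
  n0 <- (N - sum(ns^2) / N) / (r - 1)
  c(sa = (msb - msw) / n0, sw = msw)
}

#' Pairwise multi-locus R_ST (Slatkin 1995)
#'
#' Variance-component analogue of F_ST on allele repeat sizes: the
#' among-group component of a gene-level one-way ANOVA over the total,
#' with loci combined by summing components.
#'
#' @inheritParams fst_pairwise
#' @return a \code{\link{pairwise_matrix}} with statistic \code{"rst"}.
#' @export
rst_pairwise <- function(g, grouping = NULL) {
  grouping <- grouping_from(g, grouping)
  pops <- unique(grouping)
  if (length(pops) < 2L) stop("need at least 2 groups")
  m <- matrix(0, length(pops), length(pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    idx <- list(which(grouping == pops[i]), which(grouping == pops[j]))
    comp <- vapply(seq_along(g$loci), function(l) {
      sizes <- lapply(idx, function(ix) {
        s <- locus_pop_summary(g, l, ix)
        if (is.null(s)) numeric(0) else s$sizes
      })
      size_variance_components(sizes)
    }, c(sa = 0, sw = 0))
    ok <- !is.na(comp["sa", ])
    if (!any(ok)) { m[i, j] <- m[j, i] <- NA_real_; next }
    den <- sum(comp["sa", ok] + comp["sw", ok])
    m[i, j] <- m[j, i] <- if (den == 0) 0 else sum(comp["sa", ok]) / den
  }
  pairwise_matrix(m, pops, "rst")
}

#' Wright's island-model migrant number
#'
#' \code{Nm = (1 - F) / (4 F)} where \code{F} is a fixation index
#' (F_ST or R_ST).
#'
#' @param F fixation index in (0, 1]; vectorised.
#' @return migrants per generation.
#' @export
nm_from_fixation <- function(F) {
  if (any(!is.finite(F)) || any(F <= 0))
    stop("F must be > 0: F <= 0 implies unbounded gene flow (Nm undefined)")
  if (any(F > 1)) stop("F must be <= 1")
  (1 - F) / (4 * F)
}

#' Inverse of \code{\link{nm_from_fixation}}
#' @param nm migrants per generation (>= 0).
#' @return fixation index \code{1 / (4 nm + 1)}.
#' @export
fixation_from_nm <- function(nm) 1 / (4 * nm + 1)

#' Rarefied allelic richness
#'
#' Hurlbert rarefaction of allele counts to a common number of genes
#' \code{g} per population x locus:
#' \code{AR = sum_i [1 - choose(N - N_i, g) / choose(N, g)]}.
#'
#' @param gm a \code{\link{genotype_matrix}}.
#' @param g rarefaction size in genes; defaults to the smallest
#'   per-population gene count over all loci.
#' @param grouping optional group labels (default: localities).
#' @return object of class \code{richness_table}: list with \code{richness}
#'   (populations x loci), \code{mean} per population, and \code{g}.
#' @export
allelic_richness <- function(gm, g = NULL, grouping = NULL) {
  grouping <- grouping_from(gm, grouping)
  pops <- unique(grouping)
  counts <- lapply(pops, function(p) {
    lapply(seq_along(gm$loci), function(l) {
      s <- locus_pop_summary(gm, l, which(grouping == p))
      if (is.null(s)) integer(0) else
        as.integer(round(s$p * 2 * s$n))
    })
  })
  genes <- vapply(counts, function(cl) min(vapply(cl, sum, 0L)), 0L)
  if (is.null(g)) g <- min(genes)
  if (g < 1) stop("g must be >= 1")
  if (any(genes < g)) {
    lim <- pops[which.min(genes)]
    stop("rarefaction size g = ", g, " exceeds the gene count of ",
         "population '", lim, "' (", min(genes), ")")
  }
  rich <- matrix(NA_real_, length(pops), length(gm$loci),
                 dimnames = list(pops, gm$loci))
  for (i in seq_along(pops)) for (l in seq_along(gm$loci)) {
    cnt <- counts[[i]][[l]]
    if (sum(cnt) >= g)
      rich[i, l] <- suppressWarnings(
        as.numeric(vegan::rarefy(matrix(cnt, 1), sample = g)))
  }
  structure(list(richness = rich, mean = rowMeans(rich, na.rm = TRUE),
                 g = g),
            class = "richness_table")
}

#' @export
print.richness_table <- function(x, ...) {
  cat(sprintf("richness_table: rarefied to g = %d genes\n", x$g))
  print(round(cbind(x$richness, mean = x$mean), 3))
  invisible(x)
}

#' Permutation test for allelic-richness differences among clusters
#'
#' Statistic: population-weighted variance of cluster means of
#' per-population mean richness.  Populations are permuted across clusters;
#' the reported two-sided P is the proportion of permutations whose
#' statistic is at least the observed one (the variance statistic is
#' two-sided in the sense that any divergence among cluster means, in
#' either direction, increases it).
#'
#' @param rt a \code{richness_table}.
#' @param clusters character vector: cluster label per population (named or
#'   in \code{rownames(rt$richness)} order).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with \code{statistic}, \code{p_value}, \code{n_perm}.
#' @export
richness_permutation_test <- function(rt, clusters, n_perm = 1000,
                                      seed = 1) {
  pops <- rownames(rt$richness)
  if (!is.null(names(clusters))) clusters <- clusters[pops]
  clusters <- as.character(clusters)
  if (length(clusters) != length(pops))
    stop("clusters must give one label per population")
  if (length(unique(clusters)) < 2L) stop("need >= 2 clusters")
  if (n_perm < 100) warning("n_perm < 100: P estimate will be coarse")
  ar <- rt$mean
  stat <- function(cl) {
    m <- tapply(ar, cl, mean)
    w <- tapply(ar, cl, length)
    gm <- sum(w * m) / sum(w)
    sum(w * (m - gm)^2) / sum(w)
  }
  obs <- stat(clusters)
  set.seed(seed)
  perm <- replicate(n_perm, stat(sample(clusters)))
  p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_perm = n_perm)
}

#' Great-circle distances between localities
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param loc locality table (data.frame with \code{locality_id},
#'   \code{latitude}, \code{longitude}).
#' @return a \code{\link{pairwise_matrix}} with statistic \code{"km"}.
#' @export
geographic_distance_km <- function(loc) {
  loc <- validate_localities(loc)
  n <- nrow(loc)
  m <- matrix(0, n, n)
  pts <- cbind(loc$longitude, loc$latitude)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <-
      geosphere::distHaversine(pts[i, ], pts[j, ], r = 6371.0088)
  }
  pairwise_matrix(m, loc$locality_id, "km")
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the off-diagonal entries of a genetic and a
#' geographic distance matrix, with significance from joint row/column
#' permutation of the second matrix.  Three transforms of the classical
#' IBD regressions are supported: \code{linear} (km vs genetic distance),
#' \code{log_distance} (ln km vs genetic distance), and
#' \code{fst_linearized} (ln km vs F/(1-F)).  When the number of distinct
#' permutations \code{n!} does not exceed \code{n_perm}, the permutation
#' distribution is enumerated exactly.
#'
#' @param genetic,geographic \code{\link{pairwise_matrix}} objects sharing
#'   labels.
#' @param transform one of \code{"linear"}, \code{"log_distance"},
#'   \code{"fst_linearized"}.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return list with \code{r}, \code{r_squared}, \code{p_value},
#'   \code{n_perm}, \code{exact}.
#' @export
mantel_test <- function(genetic, geographic,
                        transform = c("linear", "log_distance",
                                      "fst_linearized"),
                        n_perm = 1000, seed = 1) {
  transform <- match.arg(transform)
  if (!identical(genetic$labels, geographic$labels))
    stop("matrices must share labels in the same order")
  n <- length(genetic$labels)
  if (n < 4L) stop("need >= 4 populations")
  G <- genetic$values
  D <- geographic$values
  if (transform != "linear") {
    if (any(D[upper.tri(D)] <= 0))
      stop("log transform undefined: nonpositive geographic distance")
    D <- log(D); diag(D) <- 0
  }
  if (transform == "fst_linearized") {
    sat <- G >= 1
    if (any(sat[upper.tri(sat)])) {
      warning("pairs with F = 1 excluded from fst_linearized transform")
      G[sat] <- NA
    }
    G <- G / (1 - G); diag(G) <- 0
  }
  ut <- upper.tri(G)
  r_for <- function(perm) {
    Dp <- D[perm, perm]
    ok <- ut & !is.na(G) & !is.na(Dp)
    cor(G[ok], Dp[ok])
  }
  obs <- r_for(seq_len(n))
  nfact <- factorial(n)
  if (nfact <= n_perm) {
    perms <- all_permutations(n)
    rs <- vapply(perms, r_for, 0)
    p <- mean(rs >= obs - 1e-12)
    exact <- TRUE
    n_used <- nfact
  } else {
    set.seed(seed)
    rs <- replicate(n_perm, r_for(sample.int(n)))
    p <- (1 + sum(rs >= obs - 1e-12)) / (n_perm + 1)
    exact <- FALSE
    n_used <- n_perm
  }
  list(r = obs, r_squared = obs^2, p_value = p, n_perm = n_used,
       exact = exact)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}
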