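# Sequence distances, molecular-clock dating, haplotype collapsing, a
# statistical-parsimony network, and standard diversity indices.

aln_to_dnabin <- function(aln) {
  ape::as.DNAbin(alignment_matrix(aln))
}

dist_to_pairwise <- function(d, ids, tag) {
  m <- as.matrix(d)
  dimnames(m) <- list(ids, ids)
  if (any(!is.finite(m))) {
    warning("undefined distances (no comparable sites or saturation) ",
            "flagged as NA")
    m[!is.finite(m)] <- NA_real_
  }
  diag(m) <- 0
  pairwise_matrix(m, ids, tag)
}

#' Uncorrected p-distances
#'
#' Proportion of differing sites among pairwise-comparable sites (gaps
#' and Ns excluded per pair).
#'
#' @param aln a \code{\link{seq_alignment}}.
#' @return a \code{\link{pairwise_matrix}} with statistic \code{"p_dist"}.
#' @export
p_distance <- function(aln) {
  if (length(aln$ids) < 2L) stop("need >= 2 sequences")
  d <- ape::dist.dna(aln_to_dnabin(aln), model = "raw",
                     pairwise.deletion = TRUE)
  dist_to_pairwise(d, aln$ids, "p_dist")
}

#' Tamura-Nei (1993) distances
#'
#' Closed-form TN93 distance (two transition rates, unequal base
#' frequencies; no gamma correction).  Base frequencies are estimated
#' from each pair over its comparable sites (pairwise deletion).
#' Saturated pairs whose log arguments leave the domain are flagged
#' \code{NA}.
#'
#' @param aln a \code{\link{seq_alignment}}.
#' @return a \code{\link{pairwise_matrix}} with statistic \code{"tn93"}.
#' @export
tn93_distance <- function(aln) {
  n <- length(aln$ids)
  if (n < 2L) stop("need >= 2 sequences")
  m <- alignment_matrix(aln)
  acgt <- c("A", "C", "G", "T")
  valid <- matrix(m %in% acgt, nrow(m), ncol(m))
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    out[i, j] <- out[j, i] <- tn93_pair(m[i, ], m[j, ],
                                        valid[i, ] & valid[j, ])
  dist_to_pairwise(out, aln$ids, "tn93")
}

# TN93 closed form for one pair; NaN on log-domain failure (saturation)
tn93_pair <- function(x, y, ok) {
  x <- x[ok]; y <- y[ok]
  ns <- length(x)
  if (ns == 0L) return(NaN)
  f <- table(factor(c(x, y), levels = c("A", "C", "G", "T"))) / (2 * ns)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- x != y
  pair <- paste0(pmin(x, y), pmax(x, y))
  P1 <- mean(pair == "AG")            # purine transitions
  P2 <- mean(pair == "CT")            # pyrimidine transitions
  Q <- mean(diff) - P1 - P2           # transversions
  if (mean(diff) == 0) return(0)
  if (gR == 0 || gY == 0) return(NaN)
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  a3 <- 1 - Q / (2 * gR * gY)
  if (a3 <= 0) return(NaN)
  t1 <- t2 <- 0
  if (k1 > 0) {
    a1 <- 1 - P1 / k1 - Q / (2 * gR)
    if (a1 <= 0) return(NaN)
    t1 <- -k1 * log(a1)
  } else if (P1 > 0) return(NaN)
  if (k2 > 0) {
    a2 <- 1 - P2 / k2 - Q / (2 * gY)
    if (a2 <= 0) return(NaN)
    t2 <- -k2 * log(a2)
  } else if (P2 > 0) return(NaN)
  unname(t1 + t2 - k3 * log(a3))
}

#' Mean within- and between-group distances
#'
#' @param pm a \code{\link{pairwise_matrix}} over sequences.
#' @param groups character vector: group label per sequence.
#' @return list of two matrices: \code{between} (group x group mean
#'   cross-pair distance; diagonal NA) and \code{within} (named vector of
#'   within-group means; NA for singleton groups).
#' @export
group_mean_distance <- function(pm, groups) {
  if (length(groups) != length(pm$labels))
    stop("one group label per sequence required")
  gs <- unique(groups)
  between <- matrix(NA_real_, length(gs), length(gs),
                    dimnames = list(gs, gs))
  within <- setNames(rep(NA_real_, length(gs)), gs)
  for (i in seq_along(gs)) {
    ix <- which(groups == gs[i])
    if (length(ix) > 1L) {
      v <- pm$values[ix, ix][upper.tri(matrix(0, length(ix), length(ix)))]
      within[i] <- mean(v, na.rm = TRUE)
    }
    for (j in seq_len(i - 1L)) {
      jx <- which(groups == gs[j])
      between[i, j] <- between[j, i] <-
        mean(pm$values[ix, jx], na.rm = TRUE)
    }
  }
  list(between = between, within = within)
}

#' Molecular-clock divergence time
#'
#' \code{T = p / (2 r)}: an uncorrected p-distance divided by the
#' pairwise rate, i.e. twice the per-lineage substitution rate
#' (default 0.007/site/Myr per lineage, so 0.014/Myr pairwise).
#'
#' @param p p-distance(s), >= 0; vectorised.
#' @param rate_per_lineage substitutions/site/Myr along one lineage.
#' @return time(s) in Myr.
#' @export
divergence_time <- function(p, rate_per_lineage = 0.007) {
  stopifnot(all(p >= 0, na.rm = TRUE), rate_per_lineage > 0)
  p / (2 * rate_per_lineage)
}

#' Collapse an alignment into haplotypes
#'
#' Identical sequences share one haplotype.  Numbering is canonical
#' (by decreasing count, ties broken by sequence string), so the result
#' is invariant to input order and collapsing is idempotent.
#'
#' @param aln a \code{\link{seq_alignment}}.
#' @param groups optional character vector of group/locality labels per
#'   sequence.
#' @return object of class \code{haplotype_table}: data.frame-like list
#'   with \code{haplotype}, \code{sequence}, \code{count}, \code{members}
#'   (list column), \code{groups} (list column).
#' @export
haplotype_table <- function(aln, groups = NULL) {
  if (!is.null(groups) && length(groups) != length(aln$ids))
    stop("one group label per sequence required")
  key <- aln$sequences
  uniq <- unique(key)
  cnt <- vapply(uniq, function(s) sum(key == s), 0L, USE.NAMES = FALSE)
  ord <- order(-cnt, uniq)
  uniq <- uniq[ord]; cnt <- cnt[ord]
  members <- lapply(uniq, function(s) aln$ids[key == s])
  grp <- if (is.null(groups)) vector("list", length(uniq))
         else lapply(uniq, function(s) unique(groups[key == s]))
  structure(list(haplotype = paste0("H", seq_along(uniq)),
                 sequence = uniq, count = cnt, members = members,
                 groups = grp, n_sequences = length(aln$ids),
                 length = aln$length),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d haplotypes from %d sequences\n",
              length(x$haplotype), x$n_sequences))
  for (i in seq_along(x$haplotype))
    cat(sprintf("  %s (n=%d): %s\n", x$haplotype[i], x$count[i],
                paste(head(x$members[[i]], 4), collapse = ", ")))
  invisible(x)
}

#' Standard sequence diversity indices
#'
#' Haplotype (gene) diversity \code{Hd = n (1 - sum p_i^2) / (n - 1)}
#' over haplotype frequencies, nucleotide diversity \code{pi} as the mean
#' pairwise p-distance, polymorphic site count, with sampling standard
#' deviations by Nei's (1987) formulas.
#'
#' @param aln a \code{\link{seq_alignment}}.
#' @return object of class \code{diversity_report}: \code{n}, \code{h}
#'   (haplotypes), \code{s} (polymorphic sites), \code{hd}, \code{hd_sd},
#'   \code{pi}, \code{pi_sd}.
#' @export
diversity_indices <- function(aln) {
  n <- length(aln$ids)
  m <- alignment_matrix(aln)
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  s <- sum(vapply(seq_len(ncol(m)), function(j) {
    b <- m[valid[, j], j]
    length(unique(b)) > 1L
  }, TRUE))
  ht <- haplotype_table(aln)
  h <- length(ht$haplotype)
  if (n < 2L) {
    return(structure(list(n = n, h = h, s = s, hd = NA_real_,
                          hd_sd = NA_real_, pi = NA_real_,
                          pi_sd = NA_real_),
                     class = "diversity_report"))
  }
  p <- ht$count / n
  sum2 <- sum(p^2); sum3 <- sum(p^3)
  hd <- n * (1 - sum2) / (n - 1)
  hd_var <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum3 - sum2^2) + sum2 - sum2^2)
  pd <- p_distance(aln)
  pi <- mean(pd$values[upper.tri(pd$values)], na.rm = TRUE)
  L <- aln$length
  pi_var <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  structure(list(n = n, h = h, s = s, hd = hd,
                 hd_sd = sqrt(max(hd_var, 0)), pi = pi,
                 pi_sd = sqrt(max(pi_var, 0))),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf("N = %d, h = %d, s = %d, Hd = %.3f +/- %.3f, pi = %.4f +/- %.4f\n",
              x$n, x$h, x$s, x$hd, x$hd_sd, x$pi, x$pi_sd))
  invisible(x)
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps j for which the probability of
#' parsimony is at least \code{confidence}.  The parsimony probability
#' for j steps over L sites is computed under a finite-sites,
#' uniform-hit model: j mutations thrown uniformly over L sites are
#' parsimonious when no site is hit twice, giving
#' \code{P(j) = prod_{i=1}^{j-1} (1 - i/L)}.  The limit grows with L and
#' shrinks as the confidence is raised, matching the behaviour of the
#' classical 95\% parsimony criterion used for haplotype networks.
#'
#' @param length alignment length in sites.
#' @param confidence required parsimony probability (default 0.95).
#' @return integer maximum connectable steps (>= 1).
#' @export
parsimony_connection_limit <- function(length, confidence = 0.95) {
  stopifnot(length > 0, confidence > 0, confidence < 1)
  j <- 1L
  repeat {
    p_next <- prod(1 - seq_len(j) / length)   # P(j + 1 steps parsimonious)
    if (p_next < confidence) break
    j <- j + 1L
  }
  j
}

# mutational-step distance between two haplotype sequences: number of
# differing pairwise-comparable sites
hap_steps <- function(s1, s2) {
  x <- strsplit(s1, "")[[1]]; y <- strsplit(s2, "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  sum(x[ok] != y[ok])
}

#' Build a statistical-parsimony haplotype network
#'
#' Minimum-spanning network over haplotypes with mutational-step edge
#' weights: edge weights are considered in increasing order and every
#' edge of the current weight that joins two different components (as
#' they stood before this weight class) is kept, so ties create
#' reticulations.  Edges longer than the connection \code{limit} are
#' omitted, which may leave disconnected subnetworks.  Edges of length
#' > 1 carry \code{n_intermediates = steps - 1} unobserved intermediate
#' haplotypes.
#'
#' @param ht a \code{\link{haplotype_table}}.
#' @param limit maximum connectable steps (e.g. from
#'   \code{\link{parsimony_connection_limit}}).
#' @return an \code{igraph} graph; vertices carry \code{name} and
#'   \code{count}, edges carry \code{steps} and \code{n_intermediates}.
#' @export
build_haplotype_network <- function(ht, limit) {
  stopifnot(limit >= 1)
  n <- length(ht$haplotype)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ht$haplotype)
  g <- igraph::set_vertex_attr(g, "count", value = ht$count)
  if (n < 2L) return(g)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    d[i, j] <- d[j, i] <- hap_steps(ht$sequence[i], ht$sequence[j])
  for (w in sort(unique(d[lower.tri(d)]))) {
    if (w > limit) break
    if (w < 1L) next   # haplotypes differing only at ambiguous sites
    comp <- igraph::components(g)$membership
    for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
      if (d[i, j] == w && comp[i] != comp[j]) {
        g <- igraph::add_edges(g, c(i, j),
                               steps = w, n_intermediates = w - 1L)
      }
    }
  }
  g
}
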