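mutate_at <- function(s, pos, to) {
  x <- strsplit(s, "")[[1]]
  x[pos] <- to
  paste(x, collapse = "")
}

test_that("p-distances match site-by-site brute force", {
  aln <- random_alignment(4, 300, seed = 8)
  pm <- p_distance(aln)
  m <- alignment_matrix(aln)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(pm$values[i, j], mean(m[i, ] != m[j, ]),
                 tolerance = 1e-12)
  }
  expect_equal(diag(pm$values), rep(0, 4), ignore_attr = TRUE)
  # identical sequences
  same <- seq_alignment(c("a", "b"), rep(aln$sequences[1], 2))
  expect_equal(p_distance(same)$values[1, 2], 0)
  # 9 differences over 487 sites
  s1 <- random_alignment(1, 487, seed = 10)$sequences
  x <- strsplit(s1, "")[[1]]
  pos <- 20 * (1:9)
  x[pos] <- c("A", "C", "G", "T")[(match(x[pos], c("A", "C", "G", "T"))) %% 4 + 1]
  two <- seq_alignment(c("a", "b"), c(s1, paste(x, collapse = "")))
  expect_equal(p_distance(two)$values[1, 2], 9 / 487, tolerance = 1e-12)
  # gap/N sites are excluded pairwise
  g1 <- "ACGTACGTAC"
  g2 <- "ACGTANG-AC"   # one N, one gap, zero real differences
  pg <- p_distance(seq_alignment(c("x", "y"), c(g1, g2)))
  expect_equal(pg$values[1, 2], 0)
})

test_that("TN93 matches an independent closed-form implementation", {
  # transversion-only, equal-frequency pair
  base <- paste(rep("ACGT", 100), collapse = "")
  x <- strsplit(base, "")[[1]]
  swap <- c(A = "C", C = "A", G = "T", T = "G")   # all transversions
  pos <- 4 * (1:20)
  x[pos] <- swap[x[pos]]
  aln <- seq_alignment(c("a", "b"), c(base, paste(x, collapse = "")))
  expect_equal(tn93_distance(aln)$values[1, 2],
               tn93_oracle(base, paste(x, collapse = "")),
               tolerance = 1e-9)
  # mixed transitions/transversions on simulated sequences
  sc <- scenario(n_clusters = 2, localities_per_cluster = 1,
                 mtdna_per_cluster = 2, tip_depth = 0.5, seed = 44)
  sim <- simulate_mtdna(sc)
  tn <- tn93_distance(sim)
  or <- outer(seq_along(sim$ids), seq_along(sim$ids), Vectorize(
    function(i, j) if (i == j) 0 else
      tn93_oracle(sim$sequences[i], sim$sequences[j])))
  expect_equal(unname(tn$values), or, tolerance = 1e-9)
  # cross-check against ape on a two-sequence alignment, where ape's
  # alignment-wide base frequencies coincide with the pair's
  pair <- seq_alignment(sim$ids[c(1, 3)], sim$sequences[c(1, 3)])
  ape_d <- ape::dist.dna(ape::as.DNAbin(alignment_matrix(pair)),
                         model = "TN93", pairwise.deletion = TRUE)
  expect_equal(tn93_distance(pair)$values[1, 2], as.numeric(ape_d),
               tolerance = 1e-9)
  # correction property: TN93 >= p everywhere defined
  pd <- p_distance(sim)
  expect_true(all(tn$values >= pd$values - 1e-12, na.rm = TRUE))
  expect_equal(tn93_distance(seq_alignment(c("a", "b"),
                                           rep(base, 2)))$values[1, 2], 0)
})

test_that("group mean distances average the right pairs", {
  a <- "AAAAAAAAAA"
  aln <- seq_alignment(
    c("g1_1", "g1_2", "g2_1", "g2_2"),
    c(a, mutate_at(a, 1, "C"), mutate_at(a, 1:2, "G"),
      mutate_at(a, 1:3, "T")))
  gm <- group_mean_distance(p_distance(aln), c("g1", "g1", "g2", "g2"))
  # within g1: 1 diff/10; within g2: sites 1-2 G vs T, site 3 A vs T
  expect_equal(unname(gm$within["g1"]), 0.1)
  expect_equal(unname(gm$within["g2"]), 0.3)
  # hand-counted cross pairs: 0.2, 0.3, 0.2, 0.3
  expect_equal(gm$between["g1", "g2"], 0.25)
})

test_that("divergence times follow the pairwise molecular clock", {
  expect_equal(divergence_time(0), 0)
  expect_equal(round(divergence_time(0.078), 2), 5.57)
  expect_equal(round(divergence_time(0.020), 2), 1.43)
  # linear in p, and honours a non-default rate
  p <- c(0.01, 0.02, 0.04)
  expect_equal(divergence_time(2 * p), 2 * divergence_time(p))
  expect_equal(divergence_time(0.078, rate_per_lineage = 0.0069),
               0.078 / 0.0138)
})

test_that("diversity indices reproduce the closed forms", {
  a <- paste(rep("ACGT", 10), collapse = "")   # 40 sites
  ten <- seq_alignment(paste0("n", 1:10), rep(a, 10))
  d <- diversity_indices(ten)
  expect_equal(d$h, 1L)
  expect_equal(d$s, 0L)
  expect_equal(d$hd, 0)
  expect_equal(d$pi, 0)
  # 2 sequences differing at 9 of 487 sites
  s1 <- random_alignment(1, 487, seed = 12)$sequences
  x <- strsplit(s1, "")[[1]]
  pos <- 50 * (1:9)
  x[pos] <- c("A", "C", "G", "T")[match(x[pos], c("A", "C", "G", "T")) %% 4 + 1]
  two <- seq_alignment(c("a", "b"), c(s1, paste(x, collapse = "")))
  d2 <- diversity_indices(two)
  expect_equal(d2$hd, 1)
  expect_equal(d2$hd_sd, 0.5)
  expect_equal(d2$pi, 9 / 487, tolerance = 1e-12)
  expect_equal(round(d2$pi, 4), 0.0185)
  expect_equal(d2$s, 9L)
  # 4 sequences in a 2 + 2 haplotype split: Hd = (4/3)(1 - 0.5)
  four <- seq_alignment(paste0("x", 1:4),
                        c(a, a, mutate_at(a, 3, "T"), mutate_at(a, 3, "T")))
  expect_equal(diversity_indices(four)$hd, 2 / 3, tolerance = 1e-12)
  # single sequence: degenerate report flagged with NAs
  one <- diversity_indices(seq_alignment("z", a))
  expect_true(is.na(one$hd) && is.na(one$pi))
  expect_equal(one$h, 1L)
})

test_that("haplotype collapsing is canonical, order-invariant, idempotent", {
  a <- paste(rep("AC", 10), collapse = "")
  seqs <- c(a, a, mutate_at(a, 2, "G"), a, mutate_at(a, 2, "G"),
            mutate_at(a, 5, "T"))
  aln <- seq_alignment(paste0("s", 1:6), seqs)
  ht <- haplotype_table(aln)
  expect_equal(sum(ht$count), 6L)
  expect_equal(ht$count, c(3L, 2L, 1L))
  perm <- c(6, 3, 1, 5, 2, 4)
  ht2 <- haplotype_table(seq_alignment(paste0("s", perm), seqs[perm]))
  expect_identical(ht2$sequence, ht$sequence)
  expect_identical(ht2$count, ht$count)
  # collapsing representatives again is the identity on haplotypes
  ht3 <- haplotype_table(seq_alignment(ht$haplotype, ht$sequence))
  expect_identical(sort(ht3$sequence), sort(ht$sequence))
})

test_that("the parsimony connection limit behaves like the 95% criterion", {
  expect_equal(parsimony_connection_limit(487, 0.95),
               parsimony_limit_oracle(487, 0.95))
  expect_equal(parsimony_connection_limit(100, 0.95),
               parsimony_limit_oracle(100, 0.95))
  # relaxing the confidence never shrinks the limit
  lims <- vapply(c(0.99, 0.95, 0.9, 0.5), function(cf)
    parsimony_connection_limit(487, cf), 0L)
  expect_true(all(diff(lims) >= 0))
  # doubling the sequence length never decreases the limit
  expect_gte(parsimony_connection_limit(974), parsimony_connection_limit(487))
  expect_gte(parsimony_connection_limit(200), 1)
})

test_that("the haplotype network is a minimum-spanning network", {
  a <- paste(rep("A", 20), collapse = "")
  # three haplotypes at pairwise steps (1, 1, 2): the 2-step edge is
  # redundant under Kruskal and must be excluded
  aln <- seq_alignment(c("h1", "h2", "h3"),
                       c(a, mutate_at(a, 1, "C"),
                         mutate_at(a, c(1, 2), c("C", "G"))))
  net <- build_haplotype_network(haplotype_table(aln), limit = 10)
  expect_equal(igraph::ecount(net), 2)
  expect_true(all(igraph::E(net)$steps == 1))
  # two haplotypes one step apart: single unit edge
  two <- seq_alignment(c("a", "b"), c(a, mutate_at(a, 5, "G")))
  n2 <- build_haplotype_network(haplotype_table(two), limit = 7)
  expect_equal(igraph::ecount(n2), 1)
  expect_equal(igraph::E(n2)$steps, 1)
  expect_equal(igraph::E(n2)$n_intermediates, 0)
  # ties create reticulations: four haplotypes on a unit square
  sq <- seq_alignment(c("p", "q", "r", "s"),
                      c(a, mutate_at(a, 1, "C"), mutate_at(a, 2, "G"),
                        mutate_at(a, c(1, 2), c("C", "G"))))
  nsq <- build_haplotype_network(haplotype_table(sq), limit = 7)
  expect_equal(igraph::ecount(nsq), 4)
  # edges above the limit are omitted, disconnecting subnetworks
  far <- seq_alignment(c("u", "v"), c(a, mutate_at(a, 1:10, "C")))
  nf <- build_haplotype_network(haplotype_table(far), limit = 7)
  expect_equal(igraph::ecount(nf), 0)
  expect_equal(igraph::components(nf)$no, 2)
})

test_that("deep synthetic clades split into separate subnetworks", {
  sc <- scenario(n_clusters = 3, localities_per_cluster = 1,
                 mtdna_per_cluster = 6, tip_depth = c(0.15, 0.15, 0.15),
                 split_times = list(basal = 5, south_deep = 3.6,
                                    south_shallow = 3),
                 seed = 51)
  aln <- simulate_mtdna(sc)
  grp <- sub("_[0-9]+$", "", aln$ids)
  ht <- haplotype_table(aln, grp)
  lim <- parsimony_connection_limit(aln$length)
  net <- build_haplotype_network(ht, lim)
  comp <- igraph::components(net)$membership
  # every component is pure: no component mixes generating clades
  for (cid in unique(comp)) {
    members <- unlist(ht$groups[comp == cid])
    expect_equal(length(unique(members)), 1L)
  }
  expect_gte(igraph::components(net)$no, 3)
})
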