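test_that("private alleles drive assignment to the right source", {
  # pop A fixed for 100/120, pop B fixed for 104/126; the probe carries
  # A-private alleles at both loci
  pops <- list(
    A = replicate(6, rbind(c(100, 100), c(120, 120)), simplify = FALSE),
    B = replicate(6, rbind(c(104, 104), c(126, 126)), simplify = FALSE))
  pops$B[[6]] <- rbind(c(100, 100), c(120, 120))   # probe sampled in B
  g <- toy_genotypes(pops)
  for (m in c("frequency", "rannala_mountain")) {
    sc <- assignment_scores(g, method = m, leave_one_out = TRUE)
    probe <- sc[sc$individual == "B_6" & sc$rank == 1, ]
    expect_equal(probe$population, "A")
  }
})

test_that("frequency likelihood uses the heterozygote multinomial factor", {
  # reference pop with allele counts 2 x 100, 2 x 102 (freqs 0.5/0.5);
  # probe is heterozygous 100/102
  g <- geno_1locus(ref = c(100, 100, 102, 102),
                   home = c(100, 102, 100, 100))
  sc <- assignment_scores(g, method = "frequency", leave_one_out = FALSE)
  got <- sc[sc$individual == "home_1" & sc$population == "ref", "log10_lik"]
  expect_equal(got, log10(2 * 0.5 * 0.5), tolerance = 1e-12)
  # Rannala-Mountain Dirichlet posterior predictive with prior 1/J, J = 2
  sc2 <- assignment_scores(g, method = "rannala_mountain",
                           leave_one_out = FALSE)
  got2 <- sc2[sc2$individual == "home_1" & sc2$population == "ref",
              "log10_lik"]
  expect_equal(got2, log10(2 * (2 + 0.5) * (2 + 0.5) / (5 * 6)),
               tolerance = 1e-12)
  # scores are percentages over candidate populations
  one <- sc[sc$individual == "home_1", ]
  expect_equal(sum(one$score), 100)
})

test_that("scores are invariant to locus and individual order", {
  sc0 <- scenario(n_clusters = 2, localities_per_cluster = 2,
                  individuals_per_locality = 6, seed = 17)
  g <- simulate_microsatellites(sc0)$genotypes
  s1 <- assignment_scores(g, method = "frequency")
  perm <- c(4, 2, 6, 1, 3, 5)
  g2 <- genotype_matrix(g$individual_ids, g$locality_ids, g$loci[perm],
                        g$a1[, perm], g$a2[, perm])
  s2 <- assignment_scores(g2, method = "frequency")
  expect_equal(s1$log10_lik, s2$log10_lik, tolerance = 1e-12)
  ip <- sample(seq_along(g$individual_ids))
  g3 <- genotype_matrix(g$individual_ids[ip], g$locality_ids[ip], g$loci,
                        g$a1[ip, ], g$a2[ip, ])
  s3 <- assignment_scores(g3, method = "frequency")
  m1 <- s1[order(s1$individual, s1$population), c("log10_lik", "score")]
  m3 <- s3[order(s3$individual, s3$population), c("log10_lik", "score")]
  expect_equal(m1$log10_lik, m3$log10_lik, tolerance = 1e-12)
})

test_that("duplicating an individual into a pool never lowers that pool's likelihood", {
  sc0 <- scenario(n_clusters = 2, localities_per_cluster = 1,
                  individuals_per_locality = 8, seed = 29)
  g <- simulate_microsatellites(sc0)$genotypes
  s <- assignment_scores(g, method = "frequency", leave_one_out = FALSE)
  target <- unique(g$locality_ids)[2]
  i <- 1L   # an individual from the first population
  before <- s[s$individual == g$individual_ids[i] &
                s$population == target, "log10_lik"]
  g2 <- genotype_matrix(c(g$individual_ids, "dup"),
                        c(g$locality_ids, target), g$loci,
                        rbind(g$a1, g$a1[i, ]), rbind(g$a2, g$a2[i, ]))
  s2 <- assignment_scores(g2, method = "frequency", leave_one_out = FALSE)
  after <- s2[s2$individual == g$individual_ids[i] &
                s2$population == target, "log10_lik"]
  expect_gte(after, before)
})

test_that("self-assignment is high between strongly diverged populations", {
  sc0 <- scenario(n_clusters = 2, localities_per_cluster = 2,
                  individuals_per_locality = 12, seed = 37)
  g <- simulate_microsatellites(sc0)$genotypes
  cl <- ifelse(grepl("^North", g$locality_ids), "North", "South")
  s <- assignment_scores(g, method = "frequency", grouping = cl)
  expect_gte(self_assignment_rate(s), 0.8)
})

test_that("a typical resident of fixed populations has log10 Lambda = 0", {
  pops <- list(
    A = replicate(5, rbind(c(100, 100), c(120, 120)), simplify = FALSE),
    B = replicate(5, rbind(c(104, 104), c(126, 126)), simplify = FALSE))
  g <- toy_genotypes(pops)
  mig <- detect_first_gen_migrants(g, n_sim = 100, seed = 3)
  expect_true(all(mig$log10_lambda == 0))
  expect_true(all(!mig$flagged))
})

test_that("a transplanted individual between diverged pools is flagged", {
  sc0 <- scenario(n_clusters = 2, localities_per_cluster = 1,
                  individuals_per_locality = 15, seed = 41)
  g <- simulate_microsatellites(sc0)$genotypes
  # move the first northern individual into the southern sample
  locs <- g$locality_ids
  south <- unique(locs)[2]
  locs[1] <- south
  g2 <- genotype_matrix(g$individual_ids, locs, g$loci, g$a1, g$a2)
  mig <- detect_first_gen_migrants(g2, n_sim = 500, alpha = 0.01,
                                   seed = 13)
  expect_true(mig$flagged[mig$individual == g$individual_ids[1]])
  expect_equal(mig$best_population[mig$individual == g$individual_ids[1]],
               unique(g$locality_ids)[1])
})

test_that("tiny home populations are skipped with a warning", {
  pops <- list(
    A = replicate(4, rbind(c(100, 100)), simplify = FALSE),
    B = list(rbind(c(104, 104))))
  g <- toy_genotypes(pops)
  expect_warning(mig <- detect_first_gen_migrants(g, n_sim = 50, seed = 1),
                 "skipped")
  expect_false("B_1" %in% mig$individual)
})
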