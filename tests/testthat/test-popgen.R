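test_that("theta is ~0 for a panmictic split and 1 at fixation", {
  # one pool of genotypes split arbitrarily into two groups
  g <- with_seed(4, {
    alleles <- sample(100:109, 400, replace = TRUE,
                      prob = c(4, 3, 3, 2, 2, 1, 1, 1, 1, 2))
    geno_1locus(A = alleles[1:200], B = alleles[201:400])
  })
  th <- fst_pairwise(g)$values[1, 2]
  expect_lt(abs(th), 0.02)
  # fixed for different alleles at every locus (rows = loci)
  gfix <- toy_genotypes(list(
    A = replicate(5, rbind(c(100, 100), c(120, 120)), simplify = FALSE),
    B = replicate(5, rbind(c(104, 104), c(126, 126)), simplify = FALSE)))
  expect_equal(fst_pairwise(gfix)$values[1, 2], 1)
  expect_equal(rst_pairwise(gfix)$values[1, 2], 1)
})

test_that("theta matches an independently coded Weir-Cockerham oracle", {
  # pop1: alleles 8 x 100, 2 x 102 (two heterozygotes);
  # pop2: 2 x 100, 8 x 102
  g <- geno_1locus(
    p1 = c(100, 100, 100, 100, 100, 100, 100, 102, 100, 102),
    p2 = c(102, 102, 102, 102, 102, 102, 102, 100, 102, 100))
  got <- fst_pairwise(g)$values[1, 2]
  want <- wc_theta_oracle_biallelic(n1 = 5, n2 = 5, p1 = 0.8, p2 = 0.2,
                                    h1 = 0.4, h2 = 0.4)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("R_ST matches a direct variance-component oracle and is affine-invariant", {
  s1 <- c(100, 100, 102, 104, 104, 106)
  s2 <- c(110, 112, 112, 114, 116, 110)
  g <- geno_1locus(p1 = s1, p2 = s2)
  got <- rst_pairwise(g)$values[1, 2]
  expect_equal(got, rst_oracle_1locus(s1, s2), tolerance = 1e-12)
  # affine transform of all sizes at the locus leaves R_ST unchanged
  g2 <- geno_1locus(p1 = 3 * s1 + 7, p2 = 3 * s2 + 7)
  expect_equal(rst_pairwise(g2)$values[1, 2], got, tolerance = 1e-12)
  # relabeling alleles leaves F_ST unchanged (identity-based statistic)
  relab <- c("100" = 1L, "102" = 9L, "104" = 4L, "106" = 2L,
             "110" = 8L, "112" = 3L, "114" = 5L, "116" = 7L)
  g3 <- geno_1locus(p1 = relab[as.character(s1)],
                    p2 = relab[as.character(s2)])
  expect_equal(fst_pairwise(g3)$values[1, 2],
               fst_pairwise(g)$values[1, 2], tolerance = 1e-12)
  # samples from one allele-size distribution give R_ST ~ 0
  g4 <- with_seed(6, geno_1locus(p1 = sample(100:108, 200, TRUE),
                                 p2 = sample(100:108, 200, TRUE)))
  expect_lt(abs(rst_pairwise(g4)$values[1, 2]), 0.02)
})

test_that("Wright's Nm follows the island-model closed form", {
  expect_equal(nm_from_fixation(0.2), 1.0)
  expect_equal(nm_from_fixation(0.0300), 8.0833, tolerance = 1e-4)
  expect_equal(nm_from_fixation(0.7810), 0.0701, tolerance = 1e-4)
  expect_error(nm_from_fixation(0), "undefined|> 0")
  expect_error(nm_from_fixation(-0.1), "undefined|> 0")
  # inverse identity on (0, 1]
  f <- c(0.001, 0.05, 0.25, 0.5, 1)
  expect_equal(fixation_from_nm(nm_from_fixation(f)), f)
})

test_that("rarefied allelic richness matches exhaustive enumeration", {
  # monomorphic locus: AR = 1 for any g
  gmono <- geno_1locus(p1 = rep(100, 8), p2 = rep(100, 8))
  expect_equal(unname(allelic_richness(gmono, g = 4)$richness[, 1]),
               c(1, 1))
  # g = N recovers the observed allele count
  g1 <- geno_1locus(p1 = c(100, 100, 100, 102, 102, 104),
                    p2 = c(100, 100, 100, 102, 102, 104))
  rt <- allelic_richness(g1, g = 6)
  expect_equal(unname(rt$richness["p1", 1]), 3)
  # N = 6 genes (A,A,A,B,B,C), g = 4: exhaustive subsample oracle
  expect_equal(unname(allelic_richness(g1, g = 4)$richness["p1", 1]),
               rarefaction_oracle(c(3, 2, 1), 4), tolerance = 1e-12)
  # oversized g names the limiting population
  expect_error(allelic_richness(g1, g = 7), "p1|p2")
})

test_that("richness permutation test behaves at both extremes", {
  flat <- structure(list(richness = matrix(3, 8, 2,
                                           dimnames = list(paste0("pop", 1:8),
                                                           c("L1", "L2"))),
                         mean = rep(3, 8), g = 10),
                    class = "richness_table")
  names(flat$mean) <- paste0("pop", 1:8)
  cl <- rep(c("a", "b"), each = 4)
  names(cl) <- paste0("pop", 1:8)
  expect_equal(richness_permutation_test(flat, cl, 500, seed = 1)$p_value, 1)
  # clusters offset by 2.0 richness units, 10 populations each
  rich <- with_seed(7, c(rnorm(10, 4, 0.3), rnorm(10, 6, 0.3)))
  rt <- structure(list(richness = matrix(rich, 20, 1,
                                         dimnames = list(paste0("pop", 1:20),
                                                         "L1")),
                       mean = setNames(rich, paste0("pop", 1:20)), g = 10),
                  class = "richness_table")
  cl2 <- setNames(rep(c("a", "b"), each = 10), paste0("pop", 1:20))
  res <- richness_permutation_test(rt, cl2, n_perm = 999, seed = 5)
  expect_lt(res$p_value, 0.01)
  # determinism
  res2 <- richness_permutation_test(rt, cl2, n_perm = 999, seed = 5)
  expect_identical(res$p_value, res2$p_value)
  expect_warning(richness_permutation_test(rt, cl2, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("great-circle distances use the haversine closed form", {
  loc <- data.frame(locality_id = c("o", "e", "n"),
                    latitude = c(0, 0, 10), longitude = c(0, 1, -85))
  km <- geographic_distance_km(loc)
  expect_equal(km$values["o", "o"], 0)
  expect_equal(km$values["o", "e"], 6371.0088 * pi / 180, tolerance = 1e-6)
  expect_equal(km$values["o", "e"], 111.195, tolerance = 1e-3)
  # symmetry on random points
  pts <- with_seed(3, data.frame(locality_id = paste0("p", 1:6),
                                 latitude = runif(6, -60, 60),
                                 longitude = runif(6, -170, 170)))
  m <- geographic_distance_km(pts)$values
  expect_identical(m, t(m))
})

test_that("Mantel test equals exact enumeration on 4 populations", {
  with_seed(9, {
    A <- matrix(0, 4, 4); A[upper.tri(A)] <- runif(6)
    A <- A + t(A)
    B <- matrix(0, 4, 4); B[upper.tri(B)] <- runif(6)
    B <- B + t(B)
  })
  pa <- pairwise_matrix(A, paste0("p", 1:4), "rst")
  pb <- pairwise_matrix(B, paste0("p", 1:4), "km")
  got <- mantel_test(pa, pb, "linear", n_perm = 1000, seed = 1)
  want <- mantel_oracle(A, B)
  expect_true(got$exact)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_equal(got$r_squared, got$r^2)
  # self-comparison: perfect correlation at the smallest achievable P
  self <- mantel_test(pa, pa, "linear", n_perm = 1000, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p_value, 1 / factorial(4), tolerance = 1e-12)
})

test_that("Mantel transforms behave and exclude saturated pairs", {
  with_seed(2, {
    G <- matrix(0, 5, 5); G[upper.tri(G)] <- runif(10, 0, 0.5)
    G <- G + t(G)
    D <- matrix(0, 5, 5); D[upper.tri(D)] <- runif(10, 1, 500)
    D <- D + t(D)
  })
  pg <- pairwise_matrix(G, paste0("p", 1:5), "rst")
  pd <- pairwise_matrix(D, paste0("p", 1:5), "km")
  r_log <- mantel_test(pg, pd, "log_distance", n_perm = 200, seed = 1)
  expect_true(is.finite(r_log$r))
  G2 <- G; G2[1, 2] <- G2[2, 1] <- 1
  pg2 <- pairwise_matrix(G2, paste0("p", 1:5), "rst")
  expect_warning(mantel_test(pg2, pd, "fst_linearized", n_perm = 200,
                             seed = 1), "excluded")
})
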