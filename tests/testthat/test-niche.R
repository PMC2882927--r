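# small helper landscape: one informative gradient plus a noise layer
toy_stack <- function(nr = 20, nc = 30, seed = 1) {
  with_seed(seed, {
    grad <- matrix(rep(seq(0, 10, length.out = nc), each = nr), nr, nc)
    noise <- matrix(rnorm(nr * nc), nr, nc)
    climate_stack(grad = raster_grid(grad), noise = raster_grid(noise))
  })
}

test_that("uniform presences give the maximum-entropy (uniform) model", {
  stk <- toy_stack(seed = 2)
  bg <- stack_cells(stk)
  m <- fit_maxent(bg, stk, beta = 1)
  expect_lt(max(abs(m$lambda)), 1e-8)
  expect_equal(m$h, log(nrow(bg)), tolerance = 1e-9)
  lv <- predict_logistic(m, stk)
  expect_equal(range(lv$values), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("the fitted distribution is normalised and LV is monotone in q", {
  stk <- toy_stack(seed = 3)
  pres <- which(stk$grad$values > 8, arr.ind = TRUE)
  m <- fit_maxent(pres, stk, beta = 1)
  lv <- predict_logistic(m, stk)
  # recover q from LV and check it sums to 1 over the background
  q <- lv$values / ((1 - lv$values) * exp(m$h))
  expect_equal(sum(q, na.rm = TRUE), 1, tolerance = 1e-8)
  # monotone transform: ordering by q equals ordering by LV
  ord_q <- order(q[!is.na(q)])
  ord_lv <- order(lv$values[!is.na(lv$values)])
  expect_identical(ord_q, ord_lv)
  # projection onto the training stack equals the training prediction
  lv2 <- predict_logistic(m, stk)
  expect_identical(lv$values, lv2$values)
})

test_that("a planted suitability band is recovered", {
  stk <- toy_stack(nr = 25, nc = 40, seed = 5)
  truth <- exp(-((stk$grad$values - 7) / 1)^2)
  pres <- which(truth > 0.7, arr.ind = TRUE)
  pres <- pres[with_seed(8, sample.int(nrow(pres), 40)), ]
  m <- fit_maxent(pres, stk, beta = 1)
  lv <- predict_logistic(m, stk)
  # the predicted optimum lies inside the planted band
  top <- which(lv$values == max(lv$values, na.rm = TRUE), arr.ind = TRUE)
  expect_true(all(abs(stk$grad$values[top] - 7) < 1))
  expect_gte(auc_presence_background(lv, pres, stack_cells(stk)), 0.9)
})

test_that("doubling the regularisation shrinks the coefficients", {
  stk <- toy_stack(seed = 6)
  pres <- which(stk$grad$values > 8, arr.ind = TRUE)
  l1 <- vapply(c(0.5, 1, 2, 4), function(b)
    sum(abs(fit_maxent(pres, stk, beta = b)$lambda)), 0)
  expect_true(all(diff(l1) < 1e-8))
})

test_that("binomial threshold test has its closed forms", {
  # raster with exactly half the cells at 1, half at 0
  r <- raster_grid(matrix(rep(c(1, 0), each = 50), 10, 10))
  pres <- which(r$values == 1, arr.ind = TRUE)[1:10, ]
  bt <- binomial_threshold_test(r, pres, 0.5)
  expect_equal(bt$a, 0.5)
  expect_equal(bt$k, 10)
  expect_equal(bt$p_value, 0.5^10, tolerance = 1e-12)
  # a threshold below every value makes the random model certain
  rpos <- raster_grid(matrix(rep(c(1, 0.2), each = 50), 10, 10))
  bt0 <- binomial_threshold_test(rpos, pres, 1e-9)
  expect_equal(bt0$a, 1)
  expect_equal(bt0$p_value, 1)
  expect_error(binomial_threshold_test(r, pres[0, ], 0.5), "no test")
})

test_that("rank AUC equals the all-pairs oracle", {
  with_seed(9, {
    v <- matrix(runif(400), 20, 20)
    r <- raster_grid(v)
    pres <- cbind(sample(1:20, 20, TRUE), sample(1:20, 20, TRUE))
    bg <- cbind(sample(1:20, 20, TRUE), sample(1:20, 20, TRUE))
  })
  got <- auc_presence_background(r, pres, bg)
  expect_equal(got, auc_oracle(v[pres], v[bg]), tolerance = 1e-12)
  # perfectly separated sets
  sep <- raster_grid(matrix(c(rep(0, 50), rep(1, 50)), 10, 10))
  p1 <- which(sep$values == 1, arr.ind = TRUE)
  b0 <- which(sep$values == 0, arr.ind = TRUE)
  expect_equal(auc_presence_background(sep, p1, b0), 1)
  # presences drawn from the background distribution are ~ random
  with_seed(10, {
    rnull <- raster_grid(matrix(runif(2500), 50, 50))
    cells <- which(!is.na(rnull$values), arr.ind = TRUE)
    prand <- cells[sample.int(nrow(cells), 500), ]
  })
  expect_lt(abs(auc_presence_background(rnull, prand, cells) - 0.5), 0.05)
})

test_that("suitable area counts thresholded cells times cell area", {
  v <- matrix(0.05, 10, 10)
  v[1, 1:7] <- c(0.1, 0.3, 0.5, 0.11, 0.99, 0.10001, 0.1)
  r <- raster_grid(v)
  expect_equal(suitable_area(r, 0.1, 100), 700)
  expect_equal(suitable_area(r, 0.999, 100), 0)
  # invariant to changes strictly below the threshold
  v2 <- v; v2[v2 < 0.1] <- 0.001
  expect_equal(suitable_area(raster_grid(v2), 0.1, 100), 700)
  # mask restricts the count
  mask <- matrix(FALSE, 10, 10); mask[1, 1:3] <- TRUE
  expect_equal(suitable_area(r, 0.1, 100, mask), 300)
})

test_that("paired gap comparison matches hand arithmetic", {
  a <- raster_grid(matrix(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.1), 2, 3))
  b <- raster_grid(matrix(c(0.4, 0.45, 0.72, 0.55, 0.8, 0.2), 2, 3))
  mask <- matrix(TRUE, 2, 3); mask[2, 3] <- FALSE
  res <- compare_gap_suitability(a, b, mask)
  d <- c(0.5 - 0.4, 0.6 - 0.45, 0.7 - 0.72, 0.8 - 0.55, 0.9 - 0.8)
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$n, 5)
  # identical rasters: t = 0, P = 1
  same <- compare_gap_suitability(a, a, mask)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_gap_suitability(a, b, matrix(FALSE, 2, 3)), "pixels")
})

test_that("the paired t statistic tracks its sampling law", {
  delta <- 0.1; sigma <- 0.05; n <- 100
  ts <- vapply(1:50, function(s) with_seed(100 + s, {
    base <- runif(n, 0.2, 0.8)
    a <- raster_grid(matrix(base + delta + rnorm(n, 0, sigma), 10, 10))
    b <- raster_grid(matrix(base, 10, 10))
    compare_gap_suitability(a, b, matrix(TRUE, 10, 10))$t
  }), 0)
  expect_lt(abs(mean(ts) - delta / (sigma / sqrt(n))),
            0.2 * delta / (sigma / sqrt(n)))
})
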