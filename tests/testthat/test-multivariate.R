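bray_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

test_that("Bray-Curtis matches the hand formula", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(as.numeric(bray_curtis(m)), 4 / 12)
  ## identical samples -> 0; disjoint supports -> 1
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 2), c(1, 2)))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 0), c(0, 2)))), 1)
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 2))), "non-negative")
  ## a pair of all-zero samples has an undefined dissimilarity
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 2))),
               "zero joint total")
})

test_that("Bray-Curtis agrees with brute force over small integer grids", {
  grid <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      x <- grid[i, ]; y <- grid[j, ]
      if (sum(x) + sum(y) == 0) next
      if (sum(x) == 0 || sum(y) == 0) next  # vegdist rows must be non-empty
      expect_equal(as.numeric(bray_curtis(rbind(x, y))), bray_oracle(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("NMDS reaches near-zero stress on an embeddable configuration", {
  set.seed(9)
  pts <- cbind(rnorm(25), rnorm(25))
  d <- dist(pts)
  ord <- nmds(d, k = 2, restarts = 5, seed = 1)
  expect_lt(ord$stress, 0.01)
  expect_true(all(ord$restart_stress >= ord$stress - 1e-12))
  ## stress never increases along the descent trace
  expect_true(all(diff(ord$trace) <= 1e-8))
  ## determinism
  ord2 <- nmds(d, k = 2, restarts = 5, seed = 1)
  expect_identical(ord$points, ord2$points)
  expect_identical(ord$stress, ord2$stress)
  expect_error(nmds(dist(pts[1:2, ]), k = 2), "k must be smaller")
})

test_that("NMDS scores are centred and stress lies in [0, 1]", {
  st <- default_study()
  prep <- prep_study(st)
  ord <- nmds(bray_curtis(prep$table), k = 2, restarts = 3, seed = 2)
  expect_true(ord$stress >= 0 && ord$stress <= 1)
  expect_lt(max(abs(colMeans(ord$points))), 1e-8)
  expect_true(all(diff(ord$trace) <= 1e-8))
})

test_that("redundancy R2 follows the least-squares and Ezekiel formulas", {
  set.seed(3)
  X <- matrix(rnorm(20), 10, 2)
  Y <- matrix(rnorm(50), 10, 5)
  r <- redundancy_rsq(Y, X)
  ## oracle: per-column lm R2 pooled by sum of squares
  Yc <- scale(Y, scale = FALSE)
  fit <- lm.fit(cbind(1, X), Yc)
  r2_orc <- 1 - sum(fit$residuals^2) / sum(Yc^2)
  expect_equal(r$r2, r2_orc, tolerance = 1e-12)
  expect_equal(r$adj_r2, 1 - (1 - r$r2) * 9 / 7, tolerance = 1e-12)
  ## vegan as an independent implementation
  skip_if_not_installed("vegan")
  vr <- vegan::RsquareAdj(vegan::rda(Y ~ X))
  expect_equal(r$r2, vr$r.squared, tolerance = 1e-10)
  expect_equal(r$adj_r2, vr$adj.r.squared, tolerance = 1e-10)
  ## exact linear response -> R2 = 1
  Ylin <- X %*% matrix(1:10, 2, 5)
  expect_equal(redundancy_rsq(Ylin, X)$r2, 1, tolerance = 1e-12)
  expect_error(redundancy_rsq(Y, cbind(X, X[, 1])), "rank-deficient")
})

test_that("an adjusted R2 of a pure-noise predictor is non-positive on average", {
  set.seed(4)
  adj <- replicate(200, {
    redundancy_rsq(matrix(rnorm(60), 20, 3), matrix(rnorm(40), 20, 2))$adj_r2
  })
  expect_lt(mean(adj), 0.02)
  expect_gt(mean(adj < 0), 0.3)
})

test_that("variation partitioning fractions obey inclusion-exclusion", {
  set.seed(5)
  Y <- matrix(rnorm(200), 20, 10)
  X1 <- data.frame(a = rnorm(20)); X2 <- data.frame(b = rnorm(20))
  X3 <- data.frame(c = rnorm(20))
  vp <- varpart_blocks(Y, list(s = X1, g = X2, p = X3), n_perm = 0)
  ## all fractions + residual account for exactly 1
  expect_equal(unname(sum(vp$fractions)), 1, tolerance = 1e-10)
  ## the residual complements the all-blocks adjusted R2
  expect_equal(unname(vp$fractions[["residual"]]),
               1 - redundancy_rsq(Y, cbind(X1, X2, X3))$adj_r2,
               tolerance = 1e-12)
  ## two blocks: the textbook identities a = R(AB)-R(B), b = R(AB)-R(A),
  ## shared = R(A)+R(B)-R(AB)
  vp2 <- varpart_blocks(Y, list(s = X1, g = X2), n_perm = 0)
  RA <- redundancy_rsq(Y, X1)$adj_r2
  RB <- redundancy_rsq(Y, X2)$adj_r2
  RAB <- redundancy_rsq(Y, cbind(X1, X2))$adj_r2
  expect_equal(unname(vp2$fractions["s"]), RAB - RB, tolerance = 1e-12)
  expect_equal(unname(vp2$fractions["g"]), RAB - RA, tolerance = 1e-12)
  expect_equal(unname(vp2$fractions[["s&g"]]), RA + RB - RAB,
               tolerance = 1e-12)
  expect_equal(unname(vp2$fractions[["residual"]]), 1 - RAB,
               tolerance = 1e-12)
})

test_that("variation partitioning agrees with the vegan implementation", {
  set.seed(7)
  Y <- matrix(abs(rnorm(300)), 30, 10)
  X1 <- matrix(rnorm(60), 30, 2); X2 <- matrix(rnorm(30), 30, 1)
  X3 <- matrix(rnorm(30), 30, 1)
  vp <- varpart_blocks(Y, list(A = X1, B = X2, C = X3), n_perm = 0)
  vv <- vegan::varpart(Y, X1, X2, X3)
  ind <- vv$part$indfract$Adj.R.square
  ## unique fractions [a], [b], [c] and residual [h] are unambiguous
  expect_equal(unname(vp$fractions["A"]), ind[1], tolerance = 1e-10)
  expect_equal(unname(vp$fractions["B"]), ind[2], tolerance = 1e-10)
  expect_equal(unname(vp$fractions["C"]), ind[3], tolerance = 1e-10)
  expect_equal(unname(vp$fractions["residual"]), ind[8], tolerance = 1e-10)
  ## the shared fractions match as a set
  expect_equal(sort(unname(vp$fractions[4:7])), sort(ind[4:7]),
               tolerance = 1e-10)
})

test_that("permutation F tests are sound at the extremes and reproducible", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  Yfit <- X %*% matrix(rnorm(10), 2, 5)  # perfect fit
  pf1 <- permutation_f_test(Yfit, X, n_perm = 99, seed = 1)
  expect_equal(pf1$p, 1 / 100)
  Y <- matrix(rnorm(100), 20, 5)
  a <- permutation_f_test(Y, X, n_perm = 199, seed = 5)
  b <- permutation_f_test(Y, X, n_perm = 199, seed = 5)
  expect_identical(a$p, b$p)
  expect_error(permutation_f_test(Y, X, n_perm = 10), "at least 99")
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(10)
  ps <- replicate(60, {
    Y <- matrix(rnorm(48), 16, 3)
    X <- matrix(rnorm(16), 16, 1)
    permutation_f_test(Y, X, n_perm = 99,
                       seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.15)
})
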