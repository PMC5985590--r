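test_that("PCA separates strong clusters and reconstructs the data at full rank", {
  set.seed(1)
  pfA <- runif(200, 0.1, 0.9)
  pfB <- 1 - pfA  # strongly diverged
  G <- rbind(matrix(rbinom(15 * 200, 2, rep(pfA, each = 15)), 15),
             matrix(rbinom(15 * 200, 2, rep(pfB, each = 15)), 15))
  lab <- rep(0:1, each = 15)
  p <- genotype_pca(G, K = 5)
  expect_gt(abs(cor(p$scores[, 1], lab)), 0.99)
  expect_true(all(diff(p$eigenvalues) <= 1e-9))
  expect_lte(sum(p$varfrac), 1 + 1e-9)

  # permutation equivariance
  o <- sample(30)
  p2 <- genotype_pca(G[o, ], K = 5)
  expect_equal(p2$scores[, 1], p$scores[o, 1], tolerance = 1e-8)

  # SVD completeness: full-rank reconstruction
  set.seed(2)
  X <- matrix(rbinom(20 * 50, 2, 0.5), 20)
  pf <- genotype_pca(X, K = 20)
  mu <- colMeans(X); sdv <- sqrt(mu / 2 * (1 - mu / 2))
  use <- sdv > 0
  Xs <- sweep(sweep(X[, use], 2, mu[use]), 2, sdv[use], "/")
  expect_equal(pf$scores %*% t(pf$loadings), Xs, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(genotype_pca(X[, 1:5], K = 10), "K")
})

test_that("Tracy-Widom axis test is calibrated, powered, and monotone", {
  set.seed(3)
  ps <- replicate(40, {
    G <- matrix(rbinom(50 * 250, 2, rep(runif(250, 0.1, 0.9), each = 50)), 50)
    p <- genotype_pca(G, K = 4)
    tracy_widom_pvalues(p$eigenvalues, p$n, p$m)$p[1]
  })
  expect_lte(mean(ps < 0.05), 0.10)

  hits <- replicate(20, {
    pfA <- runif(300, 0.2, 0.8)
    pfB <- pmin(0.95, pmax(0.05, pfA + rnorm(300, 0, 0.15)))
    G <- rbind(matrix(rbinom(30 * 300, 2, rep(pfA, each = 30)), 30),
               matrix(rbinom(30 * 300, 2, rep(pfB, each = 30)), 30))
    p <- genotype_pca(G, K = 4)
    tw <- tracy_widom_pvalues(p$eigenvalues, p$n, p$m)
    c(tw$p[1] < 1e-6, tw$p[2] > 0.05)
  })
  expect_gte(mean(hits[1, ]), 0.8)
  expect_gte(mean(hits[2, ]), 0.8)

  ev <- c(3, 1.2, 1.1, 1, 0.9, 0.8)
  p_lo <- tracy_widom_pvalues(ev, 50, 1000)$p[1]
  ev[1] <- 6
  p_hi <- tracy_widom_pvalues(ev, 50, 1000)$p[1]
  expect_lt(p_hi, p_lo)
  expect_error(tracy_widom_pvalues(2, 50, 100), "2 positive eigenvalues")
})

test_that("IBS matches the hand formula and flags identical individuals", {
  d <- rbind(a = c(0, 1, 2, 2, 0), b = c(0, 1, 2, 2, 0), c = c(2, 1, 0, 0, 2))
  r <- pairwise_ibs(d)
  expect_equal(r$ibs[1, 2], 1)
  expect_true(any(r$flagged[, 1] == 1 & r$flagged[, 2] == 2))
  # complementary homozygotes: IBS 0 against a/b at the homozygous sites
  expect_equal(r$ibs[1, 3], mean((2 - abs(d[1, ] - d[3, ])) / 2))
  set.seed(4)
  x <- rbind(rbinom(10, 2, 0.5), rbinom(10, 2, 0.5))
  expect_equal(pairwise_ibs(x)$ibs[1, 2], mean((2 - abs(x[1, ] - x[2, ])) / 2))
  expect_length(pairwise_ibs(x)$remove, 0)
})

test_that("Weir-Cockerham FST matches hand-computed components and boundary cases", {
  # two pops fixed for alternative alleles
  d <- matrix(c(rep(2, 20), rep(0, 20)), ncol = 1)
  pops <- rep(1:2, each = 20)
  expect_equal(wc_fst(d, pops, "per-snp"), 1)

  # identical allele counts in both pops: estimator non-positive
  d2 <- matrix(rep(c(0, 1, 2, 1), 10), ncol = 1)
  expect_lte(wc_fst(d2, rep(1:2, each = 20), "per-snp"), 0)

  # allele counts (12 ref / 8 alt) vs (5 ref / 15 alt), HW diploids
  g1 <- c(rep(0, 4), rep(1, 4), rep(2, 2))   # pop1: 8 alt alleles of 20
  g2 <- c(rep(2, 6), rep(1, 3), rep(0, 1))   # pop2: 15 alt alleles of 20
  d3 <- matrix(c(g1, g2), ncol = 1)
  pops3 <- rep(1:2, each = 10)
  ora <- oracle_wc_theta(d3[, 1], pops3)
  expect_equal(wc_fst(d3, pops3, "per-snp"), unname(ora["theta"]),
               tolerance = 1e-10)

  # monomorphic excluded, windowed ratio-of-sums
  set.seed(5)
  D <- cbind(d3, 0, matrix(rbinom(20 * 6, 2, 0.4), 20))
  w <- wc_fst(D, pops3, "windowed", window = 1000, step = 1000,
              pos = c(1, 2, 10:15), chrom = rep("c", 8))
  expect_equal(w$n_snps[1], 7)  # monomorphic column dropped
  expect_error(wc_fst(d3, rep(1, 20), "per-snp"), "2 populations")
})

test_that("pairwise-population FST agrees between modes on diverged pops", {
  set.seed(6)
  p1 <- runif(50, 0.2, 0.8); p2 <- pmin(0.95, p1 + 0.3)
  D <- rbind(matrix(rbinom(15 * 50, 2, rep(p1, each = 15)), 15),
             matrix(rbinom(15 * 50, 2, rep(p2, each = 15)), 15))
  pops <- rep(1:2, each = 15)
  pw <- wc_fst(D, pops, "pairwise-pop")
  expect_true(isSymmetric(pw))
  expect_gt(pw[1, 2], 0.05)
})

test_that("Mantel test recovers perfect association and matches direct correlation", {
  set.seed(7)
  f <- matrix(runif(25, 0.01, 0.1), 5); f <- (f + t(f)) / 2; diag(f) <- 0
  lin <- f / (1 - f)
  r <- mantel_ibd(f, lin, n_perm = 9999, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 10000)

  d <- matrix(runif(25, 1, 100), 5); d <- (d + t(d)) / 2; diag(d) <- 0
  r2 <- mantel_ibd(f, d, n_perm = 99, seed = 2)
  lo <- lower.tri(f)
  expect_equal(r2$r, cor(lin[lo], d[lo]))
  expect_error(mantel_ibd(matrix(1:4, 2), matrix(0, 2, 2)), "symmetric")
})

test_that("Mantel permutation p agrees with vegan on a shared example", {
  skip_if_not_installed("vegan")
  set.seed(8)
  f <- matrix(runif(36, 0.01, 0.2), 6); f <- (f + t(f)) / 2; diag(f) <- 0
  d <- as.matrix(dist(runif(6, 0, 10)))
  ours <- mantel_ibd(f, d, n_perm = 999, seed = 3, linearize = FALSE)
  veg <- vegan::mantel(as.dist(f), as.dist(d), permutations = 999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-10)
  expect_lt(abs(ours$p - veg$signif), 0.12)
})

test_that("centered kinship behaves as a GRM", {
  set.seed(9)
  d <- toy_genotypes(30, 200, seed = 9)
  K <- centered_kinship(d)
  expect_true(isSymmetric(K))
  # duplicated individuals share the maximal entries in their block
  d2 <- rbind(d, d[1, ])
  K2 <- centered_kinship(d2)
  expect_equal(K2[1, 31], K2[1, 1])
  # unrelated sample: off-diagonal mean near 0 within 3 SE
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 3 * sd(off) / sqrt(length(off)) + 0.05)
  # permutation equivariance
  o <- sample(30)
  expect_equal(centered_kinship(d[o, ]), K[o, o], tolerance = 1e-12)
})

test_that("LD decay fit recovers the generating parameter and is monotone", {
  set.seed(10)
  n <- 100
  dist_bp <- runif(800, 1, 5e4)
  Ctrue <- 2e-4
  r2 <- hill_weir <- aspensweep:::hill_weir_r2(Ctrue * dist_bp, n) +
    rnorm(800, 0, 0.02)
  fit <- ld_decay_fit(c(0, dist_bp), c(0.9, pmax(0, r2)), n = n)
  expect_lt(abs(fit$C_per_bp - Ctrue) / Ctrue, 0.2)
  dd <- seq(100, 5e4, length.out = 50)
  expect_true(all(diff(fit$fitted(dd)) < 0))
  expect_error(ld_decay_fit(1:5, runif(5), 10), "10 informative pairs")
})
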