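toy_hap <- function(A, pos = seq_len(ncol(A)), L = max(pos) + 1) {
  haplotype_matrix(A, pos, L)
}

test_that("EHH is 1 at the core, matches hand counts, and decays monotonically", {
  # 4 carriers forming two identical pairs at the adjacent site
  A <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 0, 0), c(1, 0, 1),
             c(0, 1, 0), c(0, 0, 1))
  h <- toy_hap(A, c(10, 20, 30), 40)
  e <- ehh(h, core = 1, allele = 1)
  expect_equal(e$ehh[1], 1)
  expect_equal(e$ehh[2], 1)           # all carriers share site 2
  expect_equal(e$ehh[3], (1 + 1) / 6)  # two homozygous pairs of C(4,2)
  # all carriers distinct at the adjacent site -> 0 beyond it
  B <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 0, 0, 1))
  h2 <- toy_hap(B)
  e2 <- ehh(h2, 1, 1)
  expect_equal(e2$ehh[3], 0)
  expect_equal(e2$ehh[4], 0)
  expect_error(ehh(toy_hap(B), 4, 1), "2 carriers")
})

test_that("EHH is non-increasing away from the core over random matrices", {
  set.seed(1)
  for (r in 1:10) {
    A <- matrix(rbinom(12 * 25, 1, 0.5), 12)
    core <- sample(5:20, 1)
    al <- sample(0:1, 1)
    if (sum(A[, core] == al) < 2) next
    e <- ehh(toy_hap(A), core, al)$ehh
    expect_true(all(diff(e[core:25]) <= 1e-12))
    expect_true(all(diff(rev(e[1:core])) <= 1e-12))
    for (j in c(core - 3, core + 3)) {
      if (j >= 1 && j <= 25)
        expect_equal(e[j], oracle_ehh(A, core, al, j))
    }
  }
})

test_that("unstandardized iHS matches the brute-force oracle on toys", {
  set.seed(2)
  checked <- 0
  for (r in 1:15) {
    A <- matrix(rbinom(8 * 30, 1, 0.5), 8)
    h <- toy_hap(A, sort(sample(1:300, 30)), 301)
    res <- ihs_unstandardized(h)
    for (j in which(!is.na(res$ihs))) {
      expect_equal(res$ihs[j], oracle_ihs(A, h$positions, j), tolerance = 1e-10)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 5)
})

test_that("iHS symmetry, sign flip under repolarization, and edge skipping", {
  # perfectly symmetric configuration: swapping 0/1 labels maps the carrier
  # classes onto each other, so the statistic must vanish
  A <- rbind(c(0, 1, 0, 1, 0), c(0, 0, 1, 1, 0), c(0, 0, 0, 1, 1),
             c(1, 1, 1, 0, 1), c(1, 0, 0, 0, 1), c(1, 1, 0, 0, 0))
  A <- rbind(A, 1 - A)  # enforce exact symmetry
  h <- toy_hap(A)
  r <- ihs_unstandardized(h, edge_rule = "truncate")
  expect_equal(r$ihs[1], 0, tolerance = 1e-12)

  set.seed(3)
  B <- matrix(rbinom(10 * 40, 1, 0.4), 10)
  hB <- toy_hap(B)
  hBf <- toy_hap(1 - B, hB$positions, hB$region_length)
  a <- ihs_unstandardized(hB, edge_rule = "truncate")$ihs
  b <- ihs_unstandardized(hBf, edge_rule = "truncate")$ihs
  expect_equal(a, -b, tolerance = 1e-10)

  # homogeneous carriers never drop below the cutoff -> edge skip
  C <- cbind(1, matrix(rep(c(1, 0), each = 6), 12, 10), 1)
  C[1:6, 1] <- 0; C[1:6, 12] <- 0
  hC <- toy_hap(cbind(rep(0:1, each = 6), C))
  rC <- ihs_unstandardized(hC)
  expect_true(any(rC$reason == "edge", na.rm = TRUE))
})

test_that("nSL matches brute force and ignores physical positions", {
  set.seed(4)
  A <- matrix(rbinom(10 * 25, 1, 0.5), 10)
  h1 <- toy_hap(A, 1:25, 26)
  h2 <- toy_hap(A, (1:25) * 10, 260)
  r1 <- nsl_unstandardized(h1)
  r2 <- nsl_unstandardized(h2)
  expect_equal(r1$nsl, r2$nsl)
  for (j in which(!is.na(r1$nsl))[1:5]) {
    expect_equal(r1$nsl[j], oracle_nsl(A, j), tolerance = 1e-10)
  }
  # symmetric configuration -> 0
  S <- rbind(A[1:5, ], 1 - A[1:5, ])
  rs <- nsl_unstandardized(toy_hap(S))
  expect_equal(rs$nsl[1], 0, tolerance = 1e-12)
})

test_that("frequency-bin standardization has unit moments per bin and matches the binning oracle", {
  set.seed(5)
  n <- 5000
  f <- runif(n)
  sc <- rnorm(n, mean = f, sd = 1 + f)
  z <- standardize_by_frequency(sc, f, n_bins = 100)
  bins <- pmin(floor(f * 100), 99)
  for (b in sample(unique(bins[!is.na(z)]), 20)) {
    i <- which(bins == b & !is.na(z))
    expect_equal(mean(z[i]), 0, tolerance = 1e-10)
    expect_equal(sd(z[i]), 1, tolerance = 1e-10)
  }
  # single-bin degenerate input reduces to a plain z-score
  f1 <- rep(0.505, 30)
  s1 <- rnorm(30)
  expect_equal(standardize_by_frequency(s1, f1),
               as.numeric(scale(s1)), tolerance = 1e-10)
  # bins with < 2 values are NA
  expect_true(all(is.na(standardize_by_frequency(c(1, 2), c(0.1, 0.9)))))
})

test_that("H statistics match hand counts and are invariant to relabeling", {
  A <- matrix(rbinom(10 * 20, 1, 0.5), 10)
  while (any(duplicated(A))) A <- matrix(rbinom(10 * 20, 1, 0.5), 10)
  h <- toy_hap(A)
  r <- h_statistics(h, snp_window = 20, window = NULL)
  expect_equal(r$H1[1], 0.1)
  expect_equal(r$H12[1], 0.12)
  expect_equal(r$H2[1], 0.09)
  expect_equal(r$H2H1[1], 0.9)

  ident <- matrix(1, 8, 20)
  ri <- h_statistics(toy_hap(ident), snp_window = 20, window = NULL)
  expect_equal(ri$H1[1], 1); expect_equal(ri$H12[1], 1)
  expect_equal(ri$H2[1], 0); expect_equal(ri$H2H1[1], 0)

  o <- sample(10)
  ro <- h_statistics(toy_hap(A[o, ]), snp_window = 20, window = NULL)
  expect_equal(ro$H1, r$H1)
})

test_that("windowed pi handles exact counts, identical haplotypes and coverage masks", {
  A <- rbind(rep(0, 5), c(1, 1, 1, 0, 0))
  h <- haplotype_matrix(A, c(100, 200, 300, 400, 500), 1000)
  w <- windowed_pi(h, window = 1000, step = 1000)
  expect_equal(w$pi[1], 3 / 1000)
  hi <- haplotype_matrix(matrix(0L, 4, 0), numeric(0), 1000)
  expect_equal(windowed_pi(hi, 1000, 1000)$pi[1], 0)
  wlow <- windowed_pi(h, 1000, 1000, callable = cbind(1, 50), min_callable = 0.1)
  expect_true(is.na(wlow$pi[1]))
})

test_that("neutral simulation pi matches the coalescent expectation", {
  set.seed(6)
  th <- 0.004
  pis <- replicate(200, {
    h <- simulate_neutral_haplotypes(th, 0.001, 5000, 12)
    sum(site_pi_cpp(h$alleles)) / 5000
  })
  expect_lt(abs(mean(pis) - th) / th, 0.1)
})

test_that("sweep haplotypes show the hard-sweep H and pi signature against neutral controls", {
  set.seed(7)
  m <- sweep_model(Ne = 20000, s = 0.1, T_fix = 5e-4, L = 3e4, n_hap = 20,
                   theta = 0.008 * 3e4, rho = 0.0018 * 3e4)
  center_stats <- function(h) {
    r <- h_statistics(h, snp_window = min(100, ncol(h$alleles)), window = NULL)
    mid <- which.min(abs(r$mid - 15000))
    w <- windowed_pi(h, 10000, 10000)
    c(H12 = r$H12[mid], H2H1 = r$H2H1[mid], pi = w$pi[2])
  }
  sw <- replicate(50, center_stats(simulate_sweep_haplotypes(m)))
  ne <- replicate(50, center_stats(
    simulate_neutral_haplotypes(0.008, 0.0018, 3e4, 20)))
  expect_lt(stats::wilcox.test(sw["H12", ], ne["H12", ],
                               alternative = "greater")$p.value, 0.01)
  expect_lt(stats::wilcox.test(sw["H2H1", ], ne["H2H1", ],
                               alternative = "less")$p.value, 0.01)
  expect_lt(stats::wilcox.test(sw["pi", ], ne["pi", ],
                               alternative = "less")$p.value, 0.01)
})

test_that("CLR: nesting at alpha -> infinity, null behavior, and grid oracle", {
  set.seed(8)
  n <- 8
  q <- c(4, 3, 2, 1.5, 1, 0.8, 0.6, 0.4)
  bg <- structure(list(counts = q, n = n), class = "background_sfs")
  counts <- sample(1:n, 30, TRUE, prob = q / sum(q))
  pos <- sort(sample(1e4, 30))
  h <- list(counts = counts, positions = pos, region_length = 1e4)

  # alpha so large no site is affected: CLR exactly 0
  sc_inf <- clr_scan(h, bg, spacing = 2500, alpha_grid = 1e6, exact = TRUE)
  expect_true(all(sc_inf$clr == 0))

  # transform at huge y returns the background itself (nesting)
  tr <- sweep_transform_cpp(q / sum(q), n, 50)
  expect_equal(tr, q / sum(q), tolerance = 1e-8)

  # exact scan equals an independent R evaluation on a 20-value alpha grid
  ag <- exp(seq(log(1e-5), log(1e-2), length.out = 20))
  sc <- clr_scan(h, bg, spacing = 2500, alpha_grid = ag, exact = TRUE)
  qs <- c(q[1:(n - 1)] + 0.5, q[n])  # scan applies half-count smoothing
  qn <- qs / sum(qs)
  lnq <- log(qn)
  for (gp in sc$grid_pos) {
    lam <- sapply(ag, function(a) {
      sum(sapply(seq_along(counts), function(s) {
        y <- a * abs(pos[s] - gp)
        pv <- oracle_sweep_transform(qn, n, y)
        log(pv[counts[s]]) - lnq[counts[s]]
      }))
    })
    expect_equal(sc$clr[sc$grid_pos == gp], 2 * max(0, max(lam)),
                 tolerance = 1e-6)
  }
})

test_that("CLR transform matches the dhyper oracle across escape intensities", {
  q <- c(5, 2, 1, 1, 0.5, 0.3)
  for (y in c(0, 0.05, 0.5, 2, 10)) {
    expect_equal(sweep_transform_cpp(q / sum(q), 6, y),
                 oracle_sweep_transform(q / sum(q), 6, y), tolerance = 1e-10)
  }
})

test_that("CLR is near zero under the null and interpolation tracks exact values", {
  set.seed(9)
  n <- 12
  bg <- background_sfs(unlist(lapply(1:5, function(i)
    colSums(simulate_neutral_haplotypes(0.005, 0.001, 2e4, n)$alleles))), n)
  meds <- replicate(20, {
    h <- simulate_neutral_haplotypes(0.005, 0.001, 2e4, n)
    median(clr_scan(h, bg, spacing = 4000)$clr)
  })
  expect_lt(median(meds), 3)
  h2 <- simulate_neutral_haplotypes(0.005, 0.001, 2e4, n, seed = 2)
  ex <- clr_scan(h2, bg, spacing = 5000, exact = TRUE)
  ap <- clr_scan(h2, bg, spacing = 5000, exact = FALSE)
  expect_equal(ap$clr, ex$clr, tolerance = 0.05)
})

test_that("window enrichment applies the SNP-count exclusion and ranks the sweep window", {
  set.seed(10)
  pos <- c(sample(1:7e5, 500), 7e5 + sample(1:7e5, 99))
  sc <- rnorm(599, 0, 0.5)
  we <- window_enrichment(sc, pos, window = 7e5, min_snps = 100)
  expect_equal(nrow(we), 1)  # 99-SNP window excluded
  expect_equal(we$prop[1], 0)

  pos2 <- sort(sample(1:(10 * 7e5), 4000))
  sc2 <- rnorm(4000, 0, 0.8)
  hot <- pos2 < 7e5
  sc2[hot] <- rnorm(sum(hot), 0, 3)
  we2 <- window_enrichment(sc2, pos2, window = 7e5, min_snps = 100)
  expect_equal(we2$quantile[1], max(we2$quantile))
})
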