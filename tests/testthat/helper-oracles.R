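# Independent oracle implementations used across the suite. These are written
# as plainly as possible (explicit loops, closed forms) and never call the
# package's own code paths for the quantity they check.

# exact heterozygote-excess tail by explicit enumeration of genotype tables
oracle_hwe_excess <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  w <- sapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  })
  sum(w[hs >= nAa]) / sum(w)
}

# direct greedy LD pruning reference: same rule, plain nested loops
oracle_ld_prune <- function(d, r2_threshold, window, step) {
  m <- ncol(d)
  maf <- pmin(colMeans(d) / 2, 1 - colMeans(d) / 2)
  removed <- rep(FALSE, m)
  starts <- unique(c(seq(1, max(1, m - window + 1), by = max(1, step)),
                     max(1, m - window + 1)))
  for (s in starts) {
    idx <- s:min(m, s + window - 1)
    repeat {
      live <- idx[!removed[idx]]
      if (length(live) < 2) break
      best <- 0; bi <- bj <- NA
      for (a in seq_along(live)) for (b in seq_along(live)) {
        if (b <= a) next
        r2 <- suppressWarnings(cor(d[, live[a]], d[, live[b]]))^2
        if (is.finite(r2) && r2 > best) { best <- r2; bi <- live[a]; bj <- live[b] }
      }
      if (best <= r2_threshold) break
      drop <- if (maf[bi] < maf[bj]) bi else if (maf[bj] < maf[bi]) bj else max(bi, bj)
      removed[drop] <- TRUE
    }
  }
  which(!removed)
}

# Weir & Cockerham (1984) variance components written out for one SNP
oracle_wc_theta <- function(d, pops) {
  lv <- unique(pops)
  r <- length(lv)
  ni <- sapply(lv, function(l) sum(pops == l))
  pi_ <- sapply(lv, function(l) mean(d[pops == l]) / 2)
  hi <- sapply(lv, function(l) mean(d[pops == l] == 1))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi_) / (r * nbar)
  s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# EHH by direct string comparison over carrier pairs
oracle_ehh <- function(A, core, allele, j) {
  car <- which(A[, core] == allele)
  rng <- min(core, j):max(core, j)
  key <- apply(A[car, rng, drop = FALSE], 1, paste, collapse = "")
  tab <- table(key)
  sum(choose(tab, 2)) / choose(length(car), 2)
}

# brute-force unstandardized iHS: trapezoid-integrated oracle EHH curves
oracle_ihs <- function(A, pos, core, cutoff = 0.05) {
  ihh_one <- function(allele) {
    tot <- 0
    for (dir in c(-1, 1)) {
      S <- ncol(A)
      prev_e <- 1; prev_d <- 0
      j <- core + dir
      while (j >= 1 && j <= S) {
        e <- oracle_ehh(A, core, allele, j)
        d <- abs(pos[j] - pos[core])
        tot <- tot + (d - prev_d) * (e + prev_e) / 2
        if (e < cutoff) break
        prev_e <- e; prev_d <- d
        j <- j + dir
      }
      if (j < 1 || j > S) return(NA)  # edge reached above cutoff
    }
    tot
  }
  a <- ihh_one(0); d <- ihh_one(1)
  if (is.na(a) || is.na(d) || a == 0 || d == 0) return(NA)
  log(a / d)
}

# brute-force nSL haplotype length over explicit pairs
oracle_nsl <- function(A, core) {
  mean_len <- function(allele) {
    car <- which(A[, core] == allele)
    if (length(car) < 2) return(NA)
    tot <- 0; np <- 0
    for (a in seq_along(car)) for (b in seq_along(car)) {
      if (b <= a) next
      i <- car[a]; j <- car[b]
      lo <- core; hi <- core
      while (lo - 1 >= 1 && A[i, lo - 1] == A[j, lo - 1]) lo <- lo - 1
      while (hi + 1 <= ncol(A) && A[i, hi + 1] == A[j, hi + 1]) hi <- hi + 1
      tot <- tot + (hi - lo + 1); np <- np + 1
    }
    tot / np
  }
  log(mean_len(0) / mean_len(1))
}

# dense MVN log-density via explicit inverse and determinant
oracle_ldmvn <- function(z, V) {
  -0.5 * (length(z) * log(2 * pi) + determinant(V)$modulus[1] +
            drop(t(z) %*% solve(V) %*% z))
}

# sweep-transformed spectrum by direct summation with dhyper
oracle_sweep_transform <- function(q, n, y) {
  q <- q / sum(q)
  pe <- 1 - exp(-y)
  p <- rep(0, n + 1)
  for (B in 0:n) {
    wB <- dbinom(B, n, pe)
    if (B == n) {
      p[2:(n + 1)] <- p[2:(n + 1)] + wB * q
    } else {
      m <- B + 1
      for (i in 0:m) {
        # P(i derived among m of n) given class probs q
        di <- sum(sapply(1:n, function(k) q[k] * dhyper(i, k, n - k, m)))
        if (di == 0) next
        if (i >= 1) p[i - 1 + (n - B) + 1] <- p[i - 1 + (n - B) + 1] + wB * di * i / m
        p[i + 1] <- p[i + 1] + wB * di * (1 - i / m)
      }
    }
  }
  jmax <- if (q[n] > 0) n else n - 1
  out <- p[2:(jmax + 1)]
  c(out / sum(out), rep(0, n - jmax))
}

# diffusion expectation of the conditional fixation time (generations) of an
# allele at frequency p destined to fix, genic selection per-copy s/2
oracle_cond_fixation_time <- function(N, s, p = 1 / (2 * N)) {
  sig <- 2 * N * s
  psi <- function(x) -expm1(-sig * x) / sig
  u <- function(x) expm1(-sig * x) / expm1(-sig)
  v <- function(x) x * (1 - x) / (2 * N)
  # (psi(1) - psi(x)) / G(x) written stably as -expm1(-sig*(1-x)) / sig
  t_low <- function(x) 2 * (psi(1) - psi(p)) * (expm1(sig * x) / sig) /
    (psi(1) * v(x)) * u(x) / u(p)
  t_high <- function(x) 2 * psi(p) * (-expm1(-sig * (1 - x)) / sig) /
    (psi(1) * v(x)) * u(x) / u(p)
  i1 <- stats::integrate(t_low, 0, p, rel.tol = 1e-8)$value
  i2 <- stats::integrate(t_high, p, 1, rel.tol = 1e-8)$value
  i1 + i2
}

# Henderson mixed-model equations for a one-random-factor model:
# y = X beta + Z u + e, u ~ N(0, s2u I), e ~ N(0, s2e I)
oracle_henderson_blup <- function(y, X, Z, s2u, s2e) {
  lambda <- s2e / s2u
  XtX <- crossprod(X); XtZ <- crossprod(X, Z)
  ZtZ <- crossprod(Z)
  lhs <- rbind(cbind(XtX, XtZ),
               cbind(t(XtZ), ZtZ + diag(lambda, ncol(Z))))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(lhs, rhs)
  sol[(ncol(X) + 1):length(sol)]
}

# tiny deterministic genotype fixture
toy_genotypes <- function(n = 20, m = 30, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  matrix(rbinom(n * m, 2, rep(p, each = n)), nrow = n)
}
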