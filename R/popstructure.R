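#' Genotype PCA on standardized dosages
#'
#' Columns are mean-imputed, centered and scaled by sqrt(p(1-p)) (the usual
#' drift-variance standardization), and decomposed by SVD. The sign of each
#' axis is fixed so that the SNP with the largest |loading| has a positive
#' loading.
#'
#' @param g a [genotype_matrix()] or dosage matrix.
#' @param K number of axes to return.
#' @return List of class `"genotype_pca"`: `scores` (n x K), `eigenvalues`
#'   (all non-trivial axes), `loadings` (m x K), `varfrac`, and the inputs'
#'   dimensions `n`, `m` (m counts the non-monomorphic SNPs used).
#' @export
genotype_pca <- function(g, K = 10) {
  d <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  n <- nrow(d)
  # per-SNP mean imputation
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d))
  if (length(idx)) d[idx] <- mu[(idx - 1) %/% n + 1]
  p <- colMeans(d) / 2
  sdv <- sqrt(p * (1 - p))
  use <- sdv > 0
  m <- sum(use)
  if (m < K) stopf("only %d informative SNPs for K = %d axes", m, K)
  X <- sweep(d[, use, drop = FALSE], 2, 2 * p[use])
  X <- sweep(X, 2, sdv[use], "/")
  sv <- svd(X, nu = min(n, K), nv = min(n, K))
  ev <- sv$d^2 / m
  K <- min(K, length(sv$d))
  scores <- sv$u[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K)
  loadings <- sv$v[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(scores = scores, eigenvalues = ev, loadings = loadings,
                 varfrac = ev / sum(ev), n = n, m = m),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("<genotype_pca> %d individuals, %d SNPs; leading varfrac %s\n",
              x$n, x$m, paste(sprintf("%.3f", head(x$varfrac, 3)), collapse = " ")))
  invisible(x)
}

# Tracy-Widom (beta = 1) distribution function via the shifted-gamma
# approximation of Chiani (2014): TW1 ~ Gamma(k, theta) - alpha.
ptw1 <- function(q, lower.tail = TRUE) {
  k <- 46.446; theta <- 0.186054; alpha <- 9.84801
  pgamma(q + alpha, shape = k, scale = theta, lower.tail = lower.tail)
}

#' Tracy-Widom significance of PCA axes
#'
#' Tests successive eigenvalues of a genotype PCA against the null of no
#' structure: for axis i the remaining eigenvalues are used to estimate an
#' effective marker count, the top remaining eigenvalue is standardized with
#' the Johnstone centering/scaling constants, and the p-value is taken from
#' the Tracy-Widom (beta = 1) distribution.
#'
#' @param eigenvalues non-increasing eigenvalue vector from [genotype_pca()].
#' @param n individuals, `m` markers.
#' @param m number of markers.
#' @return Data frame with `eigenvalue`, `twstat`, `p` per tested axis.
#' @export
tracy_widom_pvalues <- function(eigenvalues, n, m) {
  ev <- eigenvalues[eigenvalues > 1e-12]
  L <- length(ev)
  if (L < 2) stopf("need at least 2 positive eigenvalues")
  out <- data.frame(eigenvalue = ev, twstat = NA_real_, p = NA_real_)
  for (i in seq_len(L - 1)) {
    lam <- ev[i:L]
    k <- length(lam)
    # effective number of markers from the dispersion of the non-tested
    # eigenvalues (so inflating the tested one cannot deflate the reference)
    rest <- lam[-1]
    kr <- length(rest)
    neff <- ((kr + 2) * sum(rest)^2) / ((kr * sum(rest^2)) - sum(rest)^2)
    if (!is.finite(neff) || neff <= k) neff <- m
    l1 <- k * lam[1] / sum(lam)
    sq <- sqrt(neff - 1) + sqrt(k)
    mu <- sq^2 / neff
    sig <- (sq / neff) * (1 / sqrt(neff - 1) + 1 / sqrt(k))^(1 / 3)
    tw <- (l1 - mu) / sig
    out$twstat[i] <- tw
    out$p[i] <- ptw1(tw, lower.tail = FALSE)
  }
  out[seq_len(L - 1), ]
}

#' Pairwise identity-by-state matrix
#'
#' IBS between two individuals is the mean over non-missing sites of
#' (2 - |d_i - d_j|)/2. Pairs above `threshold` are flagged, and a greedy
#' minimal removal set (repeatedly dropping the individual involved in most
#' flagged pairs) is reported.
#'
#' @param g a [genotype_matrix()] or dosage matrix.
#' @param threshold flagging threshold (default 0.8).
#' @return List: `ibs` (n x n), `flagged` (two-column index matrix),
#'   `remove` (indices whose removal clears all flags).
#' @export
pairwise_ibs <- function(g, threshold = 0.8) {
  d <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  n <- nrow(d)
  ibs <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- abs(d[i, ] - d[j, ])
    ibs[i, j] <- ibs[j, i] <- mean((2 - v) / 2, na.rm = TRUE)
  }
  fl <- which(upper.tri(ibs) & ibs > threshold, arr.ind = TRUE)
  remove <- integer(0)
  left <- fl
  while (nrow(left) > 0) {
    worst <- as.integer(names(which.max(table(c(left)))))
    remove <- c(remove, worst)
    left <- left[left[, 1] != worst & left[, 2] != worst, , drop = FALSE]
  }
  list(ibs = ibs, flagged = fl, remove = sort(remove))
}

# Weir & Cockerham (1984) per-SNP variance components for diploid samples.
# Returns a, b, c component vectors over SNPs.
wc_components <- function(d, pops) {
  pops <- as.factor(pops)
  r <- nlevels(pops)
  m <- ncol(d)
  ni <- matrix(0, r, m)   # sampled diploids per pop per snp
  pi_ <- matrix(0, r, m)  # allele freq per pop
  hi <- matrix(0, r, m)   # het fraction per pop
  for (k in seq_len(r)) {
    dk <- d[pops == levels(pops)[k], , drop = FALSE]
    ni[k, ] <- colSums(!is.na(dk))
    pi_[k, ] <- colMeans(dk, na.rm = TRUE) / 2
    hi[k, ] <- colMeans(dk == 1, na.rm = TRUE)
  }
  nbar <- colMeans(ni)
  rr <- r
  nc <- (rr * nbar - colSums(ni^2) / (rr * nbar)) / (rr - 1)
  pbar <- colSums(ni * pi_) / (rr * nbar)
  s2 <- colSums(ni * (pi_ - rep(pbar, each = rr))^2) / ((rr - 1) * nbar)
  hbar <- colSums(ni * hi) / (rr * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((rr - 1) / rr) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((rr - 1) / rr) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  list(a = a, b = b, c = cc, polymorphic = poly)
}

#' Weir-Cockerham FST
#'
#' Per-SNP theta = a/(a+b+c) from the Weir & Cockerham (1984) variance
#' components; multi-locus estimates (pairwise-population and windowed modes)
#' use the ratio of summed components. Monomorphic sites are excluded.
#'
#' @param g a [genotype_matrix()] or dosage matrix.
#' @param pops population labels per individual.
#' @param mode `"per-snp"`, `"pairwise-pop"`, or `"windowed"`.
#' @param window,step window and step in bp for `mode = "windowed"` (defaults
#'   10 kbp / 5 kbp; windows are half-open `[start, start + window)`).
#' @param pos,chrom per-SNP coordinates, required for windowed mode (taken
#'   from `g` when it is a [genotype_matrix()]).
#' @return per-snp: numeric vector (NA at monomorphic sites); pairwise-pop:
#'   symmetric matrix of multi-locus estimates; windowed: data frame
#'   chrom/start/end/n_snps/fst (1-based inclusive coordinates).
#' @export
wc_fst <- function(g, pops, mode = c("per-snp", "pairwise-pop", "windowed"),
                   window = 10000, step = 5000, pos = NULL, chrom = NULL) {
  mode <- match.arg(mode)
  d <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  pops <- as.factor(pops)
  tab <- table(pops)
  if (length(tab) < 2 || any(tab < 2))
    stopf("need >= 2 populations with >= 2 samples each")
  if (mode == "per-snp") {
    w <- wc_components(d, pops)
    th <- w$a / (w$a + w$b + w$c)
    th[!w$polymorphic] <- NA
    return(th)
  }
  if (mode == "pairwise-pop") {
    lv <- levels(pops)
    r <- length(lv)
    out <- matrix(0, r, r, dimnames = list(lv, lv))
    for (i in seq_len(r - 1)) for (j in (i + 1):r) {
      sel <- pops %in% lv[c(i, j)]
      w <- wc_components(d[sel, , drop = FALSE], droplevels(pops[sel]))
      k <- w$polymorphic & is.finite(w$a)
      out[i, j] <- out[j, i] <- sum(w$a[k]) / sum((w$a + w$b + w$c)[k])
    }
    return(out)
  }
  if (is.null(pos)) {
    if (!inherits(g, "geno_matrix")) stopf("windowed mode needs pos")
    pos <- g$pos; chrom <- g$chrom
  }
  chrom <- chrom %||% rep("chr", length(pos))
  w <- wc_components(d, pops)
  tot <- w$a + w$b + w$c
  use <- w$polymorphic & is.finite(tot)
  res <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos[sel]
    starts <- seq(min(p) - (min(p) - 1) %% step, max(p), by = step)
    for (s0 in starts) {
      inwin <- sel & pos >= s0 & pos < s0 + window & use
      ns <- sum(inwin)
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = s0, end = s0 + window - 1, n_snps = ns,
        fst = if (ns > 0) sum(w$a[inwin]) / sum(tot[inwin]) else NA_real_)
    }
  }
  do.call(rbind, res)
}

#' Mantel test for isolation by distance
#'
#' Pearson correlation between linearized FST (`fst/(1-fst)`) and geographic
#' distance over off-diagonal pairs, with a permutation p-value
#' `(1 + #(r_perm >= r_obs)) / (1 + n_perm)`.
#'
#' @param fst_mat symmetric pairwise-population FST matrix.
#' @param dist_mat symmetric geographic distance matrix (km).
#' @param n_perm number of permutations (default 9999).
#' @param seed optional RNG seed.
#' @param linearize linearize FST before correlating (default TRUE).
#' @return List with `r` and `p`.
#' @export
mantel_ibd <- function(fst_mat, dist_mat, n_perm = 9999, seed = NULL,
                       linearize = TRUE) {
  if (!isSymmetric(unname(as.matrix(fst_mat))) ||
      !isSymmetric(unname(as.matrix(dist_mat))))
    stopf("matrices must be symmetric")
  A <- as.matrix(fst_mat)
  if (linearize) A <- A / (1 - A)
  B <- as.matrix(dist_mat)
  n <- nrow(A)
  lo <- lower.tri(A)
  r_obs <- cor(A[lo], B[lo])
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      while (all(p == seq_len(n))) p <- sample.int(n)  # identity is not a reshuffle
      if (cor(A[lo], B[p, p][lo]) >= r_obs) hits <- hits + 1L
    }
    list(r = r_obs, p = (1 + hits) / (1 + n_perm))
  })
}

#' Centered genomic relationship (kinship) matrix
#'
#' K = W W' / m with W the column-centered dosage matrix (mean-imputed).
#'
#' @param g a [genotype_matrix()] or dosage matrix.
#' @return n x n symmetric matrix.
#' @export
centered_kinship <- function(g) {
  d <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  n <- nrow(d)
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d))
  if (length(idx)) d[idx] <- mu[(idx - 1) %/% n + 1]
  W <- sweep(d, 2, colMeans(d))
  tcrossprod(W) / ncol(W)
}

# Hill-Weir expectation of r^2 at recombination parameter C with sample size n
hill_weir_r2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD decay curve
#'
#' Nonlinear least-squares fit of the Hill-Weir drift expectation of r^2
#' against physical distance, E[r^2] = f(C d) with the finite-sample
#' correction, estimating the per-bp recombination parameter C.
#'
#' @param distance pairwise distances (bp); zero-distance pairs are dropped.
#' @param r2 squared correlations per pair.
#' @param n sample size (number of sequences) behind the r^2 values.
#' @return List of class `"ld_decay_fit"`: `C_per_bp`, `fitted(d)` function,
#'   and the `nls` fit.
#' @export
ld_decay_fit <- function(distance, r2, n) {
  keep <- distance > 0 & is.finite(r2)
  distance <- distance[keep]; r2 <- r2[keep]
  if (length(r2) < 10) stopf("need at least 10 informative pairs")
  start <- list(Cbp = 1 / stats::median(distance))
  fit <- nls(r2 ~ hill_weir_r2(Cbp * distance, n),
             start = start, lower = c(Cbp = 1e-12), algorithm = "port")
  Cbp <- coef(fit)[["Cbp"]]
  structure(list(C_per_bp = Cbp,
                 fitted = function(d) hill_weir_r2(Cbp * d, n),
                 fit = fit),
            class = "ld_decay_fit")
}
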