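#' BLUP genetic values from replicated common-garden records
#'
#' Fits the phenology mixed model z = mu + site + block-in-site +
#' year-in-site + clone + error with clone random (REML) and predicts each
#' clone's genetic value as its BLUP. Records can be excluded (e.g. a
#' site-year hit by drought) through `exclude`.
#'
#' @param records data frame with columns `site`, `block`, `year`, `clone`,
#'   `z` (trait value).
#' @param exclude optional data frame of `site`/`year` combinations to drop.
#' @return Named numeric vector of per-clone genetic values (BLUPs, centered
#'   at 0), with attribute `"varcomp"` (clone and residual variances).
#' @export
blup_genetic_values <- function(records, exclude = NULL) {
  need <- c("site", "block", "year", "clone", "z")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("missing phenotype column(s): %s", paste(miss, collapse = ", "))
  if (!is.null(exclude))
    for (i in seq_len(nrow(exclude)))
      records <- records[!(records$site == exclude$site[i] &
                             records$year == exclude$year[i]), ]
  records$site <- factor(records$site)
  records$clone <- factor(records$clone)
  # nested fixed factors coded explicitly so single-level margins stay valid
  records$site_block <- droplevels(interaction(records$site, records$block))
  records$site_year <- droplevels(interaction(records$site, records$year))
  if (nlevels(records$clone) < 2)
    stopf("clone variance is not estimable from a single clone")
  fx <- "z ~ 1"
  if (nlevels(records$site) > 1) fx <- paste(fx, "+ site")
  if (nlevels(records$site_block) > nlevels(records$site))
    fx <- paste(fx, "+ site_block")
  if (nlevels(records$site_year) > nlevels(records$site))
    fx <- paste(fx, "+ site_year")
  fml <- stats::as.formula(paste(fx, "+ (1 | clone)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = records, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  b <- lme4::ranef(fit)$clone
  out <- setNames(b[[1]], rownames(b))
  vc <- as.data.frame(lme4::VarCorr(fit))
  attr(out, "varcomp") <- c(clone = vc$vcov[vc$grp == "clone"],
                            residual = vc$vcov[vc$grp == "Residual"])
  out
}

#' PCA-loading outlier scan
#'
#' Squared correlations between each SNP and the leading principal component,
#' rescaled by their genome-wide mean so the statistic has the chi-square(1)
#' expectation under no structure, with upper-tail chi-square(1) p-values.
#'
#' @param pca a [genotype_pca()] result (axis 1 is used).
#' @param g the [genotype_matrix()] (or dosage matrix) the PCA was run on;
#'   SNP-PC correlations are computed from it so monomorphic SNPs get p = NA.
#' @return data frame with `stat` and `p` per SNP.
#' @export
pca_outlier_scan <- function(pca, g) {
  if (!inherits(pca, "genotype_pca")) stopf("PC1 not available: run genotype_pca first")
  d <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  n <- nrow(d)
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d))
  if (length(idx)) d[idx] <- mu[(idx - 1) %/% n + 1]
  rho2 <- suppressWarnings(cor(d, pca$scores[, 1]))^2
  rho2 <- as.numeric(rho2)
  stat <- rho2 / mean(rho2, na.rm = TRUE)
  data.frame(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Latent-factor environmental association scan
#'
#' Ridge/SVD formulation of the latent-factor mixed model: K latent factors
#' are estimated from the SVD of the genotype matrix residualized on the
#' environmental score, each SNP is regressed on the score plus the factors,
#' and the environmental z-scores are recalibrated by genomic-control median
#' scaling before two-sided normal p-values are taken. `K = 0` reduces to
#' per-SNP simple regression.
#'
#' @param g a [genotype_matrix()] or dosage matrix.
#' @param env numeric environmental score per individual.
#' @param K number of latent factors (default 2).
#' @return data frame with `z` (recalibrated) and `p` per SNP; attribute
#'   `"lambda"` holds the genomic-control factor.
#' @export
latent_factor_scan <- function(g, env, K = 2) {
  d <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  n <- nrow(d)
  if (K >= n) stopf("K must be smaller than the number of individuals")
  stopifnot(length(env) == n)
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d))
  if (length(idx)) d[idx] <- mu[(idx - 1) %/% n + 1]
  env_c <- env - mean(env)
  Xc <- sweep(d, 2, colMeans(d))
  if (K > 0) {
    # residualize on env, then latent factors from the SVD
    beta_env <- crossprod(env_c, Xc) / sum(env_c^2)
    R <- Xc - tcrossprod(env_c, as.numeric(beta_env))
    U <- svd(R, nu = K, nv = 0)$u
    X <- cbind(1, env_c, U)
  } else {
    X <- cbind(1, env_c)
  }
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  B <- XtXi %*% crossprod(X, d)
  res <- d - X %*% B
  df <- n - ncol(X)
  s2 <- colSums(res^2) / df
  se <- sqrt(XtXi[2, 2] * s2)
  z <- as.numeric(B[2, ] / se)
  z[!is.finite(z)] <- NA
  lambda <- median(z^2, na.rm = TRUE) / qchisq(0.5, 1)
  zc <- z / sqrt(max(lambda, 1e-12))
  data.frame(z = zc, p = 2 * pnorm(-abs(zc)))
}

#' Kinship linear mixed-model GWAS
#'
#' Per-SNP univariate mixed model y = a + x b + u + e with u ~ N(0, sg^2 K).
#' K is eigendecomposed once; for every SNP the variance ratio
#' delta = se^2/sg^2 is profiled by 1-D optimization of the restricted
#' likelihood on the rotated data, and the Wald test b/se(b) gives the
#' p-value.
#'
#' @param g a [genotype_matrix()] or dosage matrix.
#' @param y phenotype (genetic values), finite.
#' @param K kinship matrix (positive semidefinite).
#' @return data frame of class `"assoc_result"`: `beta`, `se`, `maf`, `n`,
#'   `p` per SNP, plus `pve` from [pve()].
#' @export
lmm_gwas <- function(g, y, K) {
  d <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  n <- nrow(d)
  stopifnot(length(y) == n)
  if (any(!is.finite(y))) stopf("y must be finite")
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stopf("K is not positive semidefinite (smallest eigenvalue %.3g)", min(eg$values))
  lam <- pmax(eg$values, 0)
  Ut <- t(eg$vectors)
  yr <- as.numeric(Ut %*% y)
  onesr <- as.numeric(Ut %*% rep(1, n))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d))
  if (length(idx)) d[idx] <- mu[(idx - 1) %/% n + 1]
  Dr <- Ut %*% d
  f <- colMeans(d) / 2
  maf <- pmin(f, 1 - f)

  reml <- function(ldelta, X, yv) {
    delta <- exp(ldelta)
    w <- 1 / (lam + delta)
    XtWX <- crossprod(X * w, X)
    XtWy <- crossprod(X * w, yv)
    bh <- solve(XtWX, XtWy)
    r <- yv - X %*% bh
    rss <- max(sum(r^2 * w), 1e-300)
    p <- ncol(X)
    val <- -0.5 * ((n - p) * log(2 * pi * rss / (n - p)) + (n - p) +
                     sum(log(lam + delta)) + determinant(XtWX)$modulus[1])
    if (!is.finite(val)) -1e300 else val
  }
  m <- ncol(d)
  beta <- se <- pval <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    X <- cbind(onesr, Dr[, j])
    if (sd(d[, j]) == 0) next
    op <- optimize(function(l) reml(l, X, yr), interval = c(-12, 12), maximum = TRUE)
    delta <- exp(op$maximum)
    w <- 1 / (lam + delta)
    XtWX <- crossprod(X * w, X)
    bh <- solve(XtWX, crossprod(X * w, yr))
    r <- yr - X %*% bh
    s2 <- sum(r^2 * w) / (n - 2)
    covb <- s2 * solve(XtWX)
    beta[j] <- bh[2]
    se[j] <- sqrt(covb[2, 2])
    pval[j] <- 2 * pnorm(-abs(beta[j] / se[j]))
  }
  out <- data.frame(beta = beta, se = se, maf = maf, n = n, p = pval)
  out$pve <- ifelse(is.finite(beta) & maf > 0,
                    mapply(function(b, s, m_) if (m_ > 0) pve(b, s, m_, n) else NA_real_,
                           beta, se, maf),
                    NA_real_)
  class(out) <- c("assoc_result", class(out))
  out
}

#' Proportion of phenotypic variance explained by a SNP
#'
#' PVE = 2 b^2 f(1-f) / (2 b^2 f(1-f) + se(b)^2 2 N f(1-f)), the standard
#' summary-statistic variance share computed from the effect estimate, its
#' standard error, the minor allele frequency and the sample size.
#'
#' @param beta effect estimate.
#' @param se standard error of `beta`.
#' @param maf minor allele frequency, in (0, 0.5].
#' @param n sample size.
#' @return PVE in `[0, 1]`.
#' @export
pve <- function(beta, se, maf, n) {
  if (any(maf <= 0 | maf > 0.5)) stopf("MAF must be in (0, 0.5]")
  num <- 2 * beta^2 * maf * (1 - maf)
  num / (num + se^2 * 2 * n * maf * (1 - maf))
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 by the lambda-spline method (cubic
#' smoothing spline of pi0(lambda) evaluated at the largest lambda; falls
#' back to a fixed lambda = 0.5 for small inputs) and converts p-values to
#' monotone q-values.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values (same length), with attribute `"pi0"`.
#' @export
storey_qvalues <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  m <- sum(ok)
  pv <- p[ok]
  lambdas <- seq(0.05, 0.9, by = 0.05)
  if (m >= 100) {
    pi0l <- vapply(lambdas, function(l) mean(pv > l) / (1 - l), numeric(1))
    sp <- smooth.spline(lambdas, pi0l, df = 3)
    pi0 <- predict(sp, x = max(lambdas))$y
  } else {
    pi0 <- mean(pv > 0.5) / 0.5
  }
  pi0 <- min(max(pi0, 1e-3), 1)
  o <- order(pv, decreasing = TRUE)
  q <- pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]
  q <- pmin(1, cummin(q))
  qq <- numeric(m)
  qq[o] <- q
  out <- rep(NA_real_, length(p))
  out[ok] <- qq
  attr(out, "pi0") <- pi0
  out
}

#' Consensus candidates across scan methods
#'
#' SNPs flagged significant by at least `min_methods` of the scans are
#' candidates; candidates within `gap` bp of each other (same chromosome) are
#' merged into regions.
#'
#' @param flags logical matrix, SNPs x methods.
#' @param chrom,pos per-SNP coordinates.
#' @param min_methods consensus rule (default 2).
#' @param gap merge distance in bp (default 50 kbp).
#' @return List: `candidates` (SNP indices) and `regions` (data frame chrom,
#'   start, end, n_candidates, span), ordered by candidate count.
#' @export
consensus_candidates <- function(flags, chrom, pos, min_methods = 2, gap = 50000) {
  flags <- as.matrix(flags)
  nm <- rowSums(flags, na.rm = TRUE)
  cand <- which(nm >= min_methods)
  if (!length(cand))
    return(list(candidates = integer(0),
                regions = data.frame(chrom = character(0), start = numeric(0),
                                     end = numeric(0), n_candidates = integer(0),
                                     span = numeric(0))))
  df <- data.frame(i = cand, chrom = chrom[cand], pos = pos[cand])
  df <- df[order(df$chrom, df$pos), ]
  newreg <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                diff(df$pos) > gap)
  rid <- cumsum(newreg)
  regions <- do.call(rbind, lapply(split(df, rid), function(x)
    data.frame(chrom = x$chrom[1], start = min(x$pos), end = max(x$pos),
               n_candidates = nrow(x), span = max(x$pos) - min(x$pos) + 1)))
  regions <- regions[order(-regions$n_candidates), ]
  rownames(regions) <- NULL
  list(candidates = cand, regions = regions)
}

# log-density of a zero-mean MVN via Cholesky
ldmvnorm0 <- function(z, V) {
  ch <- chol(V)
  q <- backsolve(ch, z, transpose = TRUE)
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(q^2))
}

#' Small-scale causal fine-mapping from z-scores and LD
#'
#' Posterior over causal configurations: under configuration C the z-scores
#' are multivariate normal with covariance Sigma + Sigma diag(tau^2 1_C)
#' Sigma (non-centrality at causal SNPs propagated through LD). All
#' configurations with up to `max_causal` causal SNPs are enumerated with an
#' independent per-SNP causal prior, giving per-SNP inclusion posteriors and
#' the smallest SNP set containing all causal SNPs with probability
#' `confidence`.
#'
#' @param z per-SNP association z-scores.
#' @param ld SNP correlation (LD) matrix; a ridge of 1e-4 is added to the
#'   diagonal.
#' @param confidence causal-set confidence level rho* (default 0.99).
#' @param max_causal maximum causal SNPs per configuration (default 2).
#' @param prior per-SNP causal prior probability (default 0.01).
#' @param tau prior standard deviation of causal non-centrality (default 5).
#' @param max_snps enumeration guard; larger inputs must be pre-filtered.
#' @return List of class `"finemap"`: `set` (indices of the confidence set),
#'   `inclusion` (per-SNP posterior), `set_prob`, and the per-configuration
#'   posterior table.
#' @export
finemap_causal <- function(z, ld, confidence = 0.99, max_causal = 2,
                           prior = 0.01, tau = 5, max_snps = 25) {
  m <- length(z)
  if (m > max_snps)
    stopf("%d SNPs is too many for exhaustive enumeration; pre-filter to <= %d",
          m, max_snps)
  Sig <- as.matrix(ld) + diag(1e-4, m)
  configs <- list(integer(0))
  if (max_causal >= 1) configs <- c(configs, lapply(seq_len(m), function(i) i))
  if (max_causal >= 2 && m >= 2) {
    cmb <- utils::combn(m, 2)
    configs <- c(configs, lapply(seq_len(ncol(cmb)), function(k) cmb[, k]))
  }
  logpost <- vapply(configs, function(C) {
    V <- Sig
    if (length(C)) {
      S <- Sig[, C, drop = FALSE]
      V <- Sig + tau^2 * tcrossprod(S)
    }
    lp <- length(C) * log(prior) + (m - length(C)) * log(1 - prior)
    lp + ldmvnorm0(z, V)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  inclusion <- vapply(seq_len(m), function(i)
    sum(w[vapply(configs, function(C) i %in% C, logical(1))]), numeric(1))
  # smallest set S with P(all causal SNPs in S) >= confidence
  ord <- order(inclusion, decreasing = TRUE)
  set <- integer(0)
  prob_in <- function(S) sum(w[vapply(configs, function(C) all(C %in% S), logical(1))])
  for (i in ord) {
    set <- c(set, i)
    if (prob_in(set) >= confidence) break
  }
  structure(list(set = sort(set), inclusion = inclusion,
                 set_prob = prob_in(set),
                 posterior = data.frame(
                   config = vapply(configs, paste, character(1), collapse = ","),
                   prob = w)),
            class = "finemap")
}
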