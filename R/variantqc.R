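#' Site-level coverage/mappability filters
#'
#' Applies the four post-mapping site filters: total depth below `min_depth`
#' (strict) or above `max_depth` (strict), more than `max_mq0` reads with
#' mapping quality zero, repeat-masked sites, and sites on scaffolds shorter
#' than `min_scaffold`. Boundary values are kept.
#'
#' @param stats data frame with columns `depth`, `mq0`, `repeat_masked`
#'   (logical), `scaffold_length`.
#' @param min_depth,max_depth,max_mq0,min_scaffold thresholds; defaults 400,
#'   4500, 200 and 2000.
#' @param drop_repeats drop repeat-masked sites (default TRUE).
#' @return Logical keep-mask with attribute `"reason"`: per-site label of the
#'   first rule that fired (`NA` for kept sites).
#' @export
filter_sites <- function(stats, min_depth = 400, max_depth = 4500,
                         max_mq0 = 200, drop_repeats = TRUE,
                         min_scaffold = 2000) {
  need <- c("depth", "mq0", "repeat_masked", "scaffold_length")
  miss <- setdiff(need, names(stats))
  if (length(miss)) stopf("missing site-stat column(s): %s", paste(miss, collapse = ", "))
  n <- nrow(stats)
  reason <- rep(NA_character_, n)
  reason[is.na(reason) & stats$depth < min_depth] <- "low_coverage"
  reason[is.na(reason) & stats$depth > max_depth] <- "high_coverage"
  reason[is.na(reason) & stats$mq0 > max_mq0] <- "excess_mq0"
  if (drop_repeats) reason[is.na(reason) & stats$repeat_masked] <- "repeat"
  reason[is.na(reason) & stats$scaffold_length < min_scaffold] <- "short_scaffold"
  keep <- is.na(reason)
  attr(keep, "reason") <- reason
  keep
}

#' Exact one-sided test for heterozygote excess
#'
#' Conditional on the observed allele counts, computes the exact probability
#' of seeing at least as many heterozygotes as observed under Hardy-Weinberg
#' equilibrium (the Levene/Haldane conditional distribution, upper tail only).
#' Monomorphic sites return p = 1 by convention.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return One-sided p-value for heterozygote excess.
#' @export
hwe_excess_het_test <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stopf("genotype counts must be non-negative")
  n <- nAA + nAa + naa
  if (n == 0) stopf("no genotypes")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  # heterozygote counts share the parity of min(nA, na)
  hmin <- min(nA, na)
  hs <- seq(hmin %% 2, hmin, by = 2)
  # log P(h) up to a constant: conditional distribution of het count
  lp <- lgamma(n + 1) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((na - hs) / 2 + 1) + hs * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  sum(p[hs >= nAa])
}

#' Polarize one site against two outgroups
#'
#' Rule 1: if the more distant outgroup (P. trichocarpa analog) is homozygous
#' and its allele matches one of the ingroup alleles, that allele is
#' ancestral. Rule 2 (fallback): the same criterion applied to the closer
#' outgroup (P. tremuloides analog). Otherwise the ancestral state is missing.
#'
#' @param ingroup_alleles character vector of the two ingroup alleles.
#' @param trichocarpa,tremuloides outgroup genotypes as length-2 character
#'   vectors (or NULL/NA when missing).
#' @return The ancestral allele, or `NA_character_`.
#' @export
polarize_site <- function(ingroup_alleles, trichocarpa = NULL, tremuloides = NULL) {
  hom_match <- function(gt) {
    if (is.null(gt) || length(gt) != 2 || any(is.na(gt))) return(NA_character_)
    if (gt[1] != gt[2]) return(NA_character_)
    if (gt[1] %in% ingroup_alleles) gt[1] else NA_character_
  }
  anc <- hom_match(trichocarpa)
  if (!is.na(anc)) return(anc)
  hom_match(tremuloides)
}

#' SNP-level filters
#'
#' Applies, in order: biallelic-SNP restriction (non-biallelic flags in
#' `annotations`), distance-to-indel > `indel_dist`, genotype masking at
#' GQ < `min_gq` (when a GQ array is supplied), per-site call rate >=
#' `min_call_rate` (counted after GQ masking), heterozygote-excess exact HWE
#' p >= `hwe_p`, and MAF > `min_maf`.
#'
#' @param g a [genotype_matrix()].
#' @param annotations data frame with per-site columns `indel_dist` (bp to the
#'   nearest indel, `Inf` when none) and optionally `biallelic` (logical).
#' @param gq optional matrix of genotype qualities matching `g$dosages`.
#' @param indel_dist,min_gq,min_call_rate,hwe_p,min_maf thresholds; defaults
#'   5, 10, 0.7, 1e-8, 0.05.
#' @return The filtered [genotype_matrix()], with attribute `"report"`: counts
#'   removed per rule.
#' @export
filter_snps <- function(g, annotations, gq = NULL, indel_dist = 5, min_gq = 10,
                        min_call_rate = 0.7, hwe_p = 1e-8, min_maf = 0.05) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!"indel_dist" %in% names(annotations))
    stopf("missing annotation column: indel_dist")
  d <- g$dosages
  if (!is.null(gq)) d[gq < min_gq] <- NA
  m <- ncol(d)
  drop <- rep(NA_character_, m)
  if ("biallelic" %in% names(annotations))
    drop[is.na(drop) & !annotations$biallelic] <- "not_biallelic"
  drop[is.na(drop) & annotations$indel_dist <= indel_dist] <- "near_indel"
  callrate <- colMeans(!is.na(d))
  drop[is.na(drop) & callrate < min_call_rate] <- "low_call_rate"
  hwe <- vapply(seq_len(m), function(j) {
    x <- d[, j]
    hwe_excess_het_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                        sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  drop[is.na(drop) & hwe < hwe_p] <- "excess_het"
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  drop[is.na(drop) & !(maf > min_maf)] <- "low_maf"
  keep <- is.na(drop)
  out <- genotype_matrix(d[, keep, drop = FALSE], g$chrom[keep], g$pos[keep],
                         g$ref[keep], g$alt[keep], g$aa[keep])
  attr(out, "report") <- table(factor(drop[!keep],
                                      levels = c("not_biallelic", "near_indel",
                                                 "low_call_rate", "excess_het",
                                                 "low_maf")))
  out
}

#' Greedy windowed LD pruning
#'
#' Slides windows of `window` SNPs (step `step`) and, within each window,
#' repeatedly removes one SNP from the pair with the highest squared
#' correlation above `r2_threshold`; ties are broken by removing the SNP with
#' the lower MAF, then the higher column index. Deterministic given input
#' order.
#'
#' @param g a [genotype_matrix()] (or plain dosage matrix).
#' @param r2_threshold squared-correlation threshold (default 0.2).
#' @param window window size in SNPs (default 50).
#' @param step window step in SNPs (default `window`/2).
#' @return Integer vector of kept column indices.
#' @export
ld_prune <- function(g, r2_threshold = 0.2, window = 50, step = window / 2) {
  d <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  m <- ncol(d)
  if (m == 0) return(integer(0))
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  removed <- rep(FALSE, m)
  starts <- unique(c(seq(1, max(1, m - window + 1), by = max(1, step)),
                     max(1, m - window + 1)))
  for (s in starts) {
    idx <- s:min(m, s + window - 1)
    idx <- idx[!removed[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(cor(d[, idx, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 0
    while (TRUE) {
      mx <- max(r2)
      if (mx <= r2_threshold) break
      w <- which(r2 == mx, arr.ind = TRUE)[1, ]
      pair <- idx[c(w[1], w[2])]
      # drop lower MAF; ties -> higher index
      drop_i <- if (maf[pair[1]] < maf[pair[2]]) 1L
                else if (maf[pair[1]] > maf[pair[2]]) 2L
                else which.max(pair)
      kill <- which(idx == pair[drop_i])
      removed[pair[drop_i]] <- TRUE
      r2[kill, ] <- 0
      r2[, kill] <- 0
    }
  }
  which(!removed)
}
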