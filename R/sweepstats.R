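#' Extended haplotype homozygosity around a core SNP
#'
#' EHH at a flanking site is the probability that two random carriers of the
#' core allele are identical at every site between the core and that site
#' (inclusive); it is 1 at the core and non-increasing outward.
#'
#' @param h a [haplotype_matrix()].
#' @param core core site index (1-based column).
#' @param allele core allele, 0 (ancestral) or 1 (derived).
#' @return List of class `"ehh_curve"`: `ehh` (per-site values, NA beyond
#'   full refinement is filled with 0), `positions`, `core`, `allele`,
#'   `n_carriers`.
#' @export
ehh <- function(h, core, allele = 1) {
  stopifnot(inherits(h, "hap_matrix"))
  nc <- sum(h$alleles[, core] == allele, na.rm = TRUE)
  if (nc < 2) stopf("need >= 2 carriers of allele %d at the core", allele)
  v <- ehh_curve_cpp(h$alleles, core - 1L, as.integer(allele))
  structure(list(ehh = v, positions = h$positions, core = core,
                 allele = allele, n_carriers = nc),
            class = "ehh_curve")
}

# integrate an EHH curve on one side of the core: trapezoid vs physical
# distance, truncated at the first site where EHH < cutoff (that trapezoid is
# included). Returns NA if the curve is still above the cutoff at the edge
# (edge_rule "skip") unless edge_rule is "truncate".
ihh_side <- function(ehh_v, pos, core, dir, cutoff, edge_rule) {
  S <- length(pos)
  idx <- if (dir > 0) core:S else core:1
  e <- ehh_v[idx]
  e[1] <- 1
  d <- abs(pos[idx] - pos[core])
  below <- which(e < cutoff)
  if (!length(below)) {
    if (edge_rule == "skip") return(NA_real_)
    last <- length(e)
  } else last <- below[1]
  if (last < 2) return(0)
  sum(diff(d[1:last]) * (head(e[1:last], -1) + tail(e[1:last], -1)) / 2)
}

#' Unstandardized iHS
#'
#' For each SNP with both alleles at frequency > `min_maf`, integrates the
#' EHH curves of the ancestral and derived alleles over physical distance
#' (trapezoid rule, truncated where EHH < `cutoff`) and reports
#' ln(iHH_ancestral / iHH_derived). SNPs whose EHH is still above the cutoff
#' at the region edge are skipped (NA with a reason) under the default edge
#' rule.
#'
#' @param h a [haplotype_matrix()] (polarized: 1 = derived).
#' @param min_maf frequency filter (default 0.05).
#' @param cutoff EHH truncation level (default 0.05).
#' @param edge_rule `"skip"` (default) or `"truncate"` at region edges.
#' @param sites optional subset of site indices to score.
#' @return data frame: `site`, `position`, `freq` (derived), `ihs`
#'   (unstandardized), `reason` for NA entries.
#' @export
ihs_unstandardized <- function(h, min_maf = 0.05, cutoff = 0.05,
                               edge_rule = c("skip", "truncate"), sites = NULL) {
  stopifnot(inherits(h, "hap_matrix"))
  edge_rule <- match.arg(edge_rule)
  A <- h$alleles
  f <- colMeans(A)
  sites <- sites %||% seq_len(ncol(A))
  out <- data.frame(site = sites, position = h$positions[sites],
                    freq = f[sites], ihs = NA_real_,
                    reason = NA_character_)
  for (k in seq_along(sites)) {
    j <- sites[k]
    if (f[j] <= min_maf || f[j] >= 1 - min_maf) {
      out$reason[k] <- "maf"
      next
    }
    ihh <- numeric(2)
    bad <- FALSE
    for (al in 0:1) {
      e <- ehh_curve_cpp(A, j - 1L, al)
      l <- ihh_side(e, h$positions, j, -1, cutoff, edge_rule)
      r <- ihh_side(e, h$positions, j, +1, cutoff, edge_rule)
      if (is.na(l) || is.na(r)) { bad <- TRUE; break }
      ihh[al + 1] <- l + r
    }
    if (bad) { out$reason[k] <- "edge"; next }
    if (any(ihh == 0)) { out$reason[k] <- "zero_ihh"; next }
    out$ihs[k] <- log(ihh[1] / ihh[2])
  }
  out
}

#' Unstandardized nSL
#'
#' Same log-ratio structure as iHS but the haplotype length of a carrier pair
#' is measured in the number of consecutive segregating sites shared around
#' the core, so no physical or genetic map enters.
#'
#' @inheritParams ihs_unstandardized
#' @return data frame: `site`, `position`, `freq`, `nsl`, `reason`.
#' @export
nsl_unstandardized <- function(h, min_maf = 0.05, sites = NULL) {
  stopifnot(inherits(h, "hap_matrix"))
  A <- h$alleles
  f <- colMeans(A)
  sites <- sites %||% seq_len(ncol(A))
  out <- data.frame(site = sites, position = h$positions[sites],
                    freq = f[sites], nsl = NA_real_, reason = NA_character_)
  for (k in seq_along(sites)) {
    j <- sites[k]
    if (f[j] <= min_maf || f[j] >= 1 - min_maf) { out$reason[k] <- "maf"; next }
    sla <- nsl_mean_length_cpp(A, j - 1L, 0L)
    sld <- nsl_mean_length_cpp(A, j - 1L, 1L)
    if (!is.finite(sla) || !is.finite(sld) || sla == 0 || sld == 0) {
      out$reason[k] <- "degenerate"; next
    }
    out$nsl[k] <- log(sla / sld)
  }
  out
}

#' Standardize scores within derived-allele frequency bins
#'
#' Scores are grouped into `n_bins` equal-width derived-frequency bins
#' (`floor(freq * n_bins)`, top edge folded into the last bin); within each
#' bin the mean is subtracted and the SD divided out. Bins with fewer than 2
#' values give NA.
#'
#' @param scores raw statistic per SNP.
#' @param freq derived-allele frequency per SNP.
#' @param n_bins number of bins (default 100).
#' @return Standardized scores.
#' @export
standardize_by_frequency <- function(scores, freq, n_bins = 100) {
  bin <- pmin(floor(freq * n_bins), n_bins - 1)
  out <- rep(NA_real_, length(scores))
  for (b in unique(bin)) {
    i <- which(bin == b & !is.na(scores))
    if (length(i) < 2) next
    s <- sd(scores[i])
    if (s == 0) next
    out[i] <- (scores[i] - mean(scores[i])) / s
  }
  out
}

#' Haplotype homozygosity statistics (H1, H12, H2, H2/H1)
#'
#' Haplotype frequencies p1 >= p2 >= ... are computed in sliding windows of
#' `snp_window` SNPs (step `snp_step`); H1 = sum p_i^2, H12 = (p1 + p2)^2 +
#' sum_{i>=3} p_i^2, H2 = H1 - p1^2. The per-SNP-window values (anchored at
#' the window's midpoint position) are then averaged in physical windows of
#' `window` bp sliding by `step` bp.
#'
#' @param h a [haplotype_matrix()].
#' @param snp_window SNPs per haplotype window (default 200).
#' @param snp_step step between SNP windows (default `snp_window/8`).
#' @param window,step physical averaging window and step in bp (defaults
#'   10 kbp / 5 kbp); set `window = NULL` to return the raw SNP-window values.
#' @return data frame: start, end, mid, n_windows (or n_snps), H1, H12, H2,
#'   H2H1.
#' @export
h_statistics <- function(h, snp_window = 200, snp_step = max(1, snp_window %/% 8),
                         window = 10000, step = 5000) {
  stopifnot(inherits(h, "hap_matrix"))
  A <- h$alleles
  S <- ncol(A)
  if (nrow(A) < 2) stopf("need >= 2 haplotypes")
  snp_window <- min(snp_window, S)
  starts <- unique(c(seq(1, max(1, S - snp_window + 1), by = snp_step),
                     max(1, S - snp_window + 1)))
  raw <- do.call(rbind, lapply(starts, function(s0) {
    j <- s0:(s0 + snp_window - 1)
    key <- apply(A[, j, drop = FALSE], 1, paste, collapse = "")
    pfr <- sort(as.numeric(table(key)) / nrow(A), decreasing = TRUE)
    H1 <- sum(pfr^2)
    H12 <- if (length(pfr) >= 2) (pfr[1] + pfr[2])^2 + sum(pfr[-(1:2)]^2) else H1
    H2 <- H1 - pfr[1]^2
    data.frame(mid = mean(range(h$positions[j])), H1 = H1, H12 = H12,
               H2 = H2, H2H1 = H2 / H1)
  }))
  if (is.null(window)) return(raw)
  ws <- seq(1, max(1, h$region_length - 1), by = step)
  out <- do.call(rbind, lapply(ws, function(s0) {
    k <- raw$mid >= s0 & raw$mid < s0 + window
    data.frame(start = s0, end = min(s0 + window - 1, h$region_length),
               n_windows = sum(k),
               H1 = if (any(k)) mean(raw$H1[k]) else NA_real_,
               H12 = if (any(k)) mean(raw$H12[k]) else NA_real_,
               H2 = if (any(k)) mean(raw$H2[k]) else NA_real_,
               H2H1 = if (any(k)) mean(raw$H2H1[k]) else NA_real_)
  }))
  out
}

#' Windowed nucleotide diversity
#'
#' Mean pairwise difference per covered bp in sliding windows. Windows whose
#' callable fraction falls below `min_callable` are set NA.
#'
#' @param h a [haplotype_matrix()].
#' @param window,step window and step in bp (defaults 10 kbp / 5 kbp).
#' @param callable optional two-column matrix of callable intervals
#'   (start, end); by default the whole region is callable.
#' @param min_callable minimum callable fraction per window (default 0.1).
#' @return data frame: start, end, n_snps, callable_bp, pi.
#' @export
windowed_pi <- function(h, window = 10000, step = 5000, callable = NULL,
                        min_callable = 0.1) {
  stopifnot(inherits(h, "hap_matrix"))
  persite <- site_pi_cpp(h$alleles)
  ws <- seq(1, max(1, h$region_length - 1), by = step)
  cov_bp <- function(s0, e0) {
    if (is.null(callable)) return(e0 - s0 + 1)
    sum(pmax(0, pmin(callable[, 2], e0) - pmax(callable[, 1], s0) + 1))
  }
  do.call(rbind, lapply(ws, function(s0) {
    e0 <- min(s0 + window - 1, h$region_length)
    k <- h$positions >= s0 & h$positions <= e0
    cb <- cov_bp(s0, e0)
    ok <- cb / (e0 - s0 + 1) >= min_callable
    data.frame(start = s0, end = e0, n_snps = sum(k), callable_bp = cb,
               pi = if (ok && cb > 0) sum(persite[k]) / cb else NA_real_)
  }))
}

#' Background site-frequency spectrum
#'
#' Counts of derived-allele frequency classes 1..n-1 (plus the fixed-derived
#' class n when substitutions are supplied) over a collection of polarized
#' sites, used as the null spectrum of [clr_scan()].
#'
#' @param counts vector of per-site derived-allele counts (values 1..n).
#' @param n sample size (haplotypes).
#' @param n_fixed number of fixed-derived substitution sites to add to class
#'   n (default 0).
#' @return Object of class `"background_sfs"`: `counts` (length n), `n`.
#' @export
background_sfs <- function(counts, n, n_fixed = 0) {
  if (any(counts < 1 | counts > n)) stopf("derived counts must lie in 1..n")
  tab <- tabulate(counts, nbins = n)
  tab[n] <- tab[n] + n_fixed
  if (sum(tab) == 0) stopf("empty background spectrum")
  structure(list(counts = tab, n = n), class = "background_sfs")
}

#' Composite likelihood ratio sweep scan
#'
#' At each grid position the composite likelihood of the observed derived
#' frequency classes under a sweep centered there (background spectrum
#' distorted by per-lineage escape probability 1 - exp(-alpha d)) is
#' maximized over the sweep intensity alpha and contrasted with the
#' background likelihood: CLR = 2 (ln L_sweep - ln L_background) >= 0.
#'
#' @param h a [haplotype_matrix()], or a list with `counts` (derived counts,
#'   1..n), `positions` and `n`.
#' @param background a [background_sfs()]. Classes absent from the background
#'   receive a small floor before normalization.
#' @param spacing grid spacing in bp (default 2 kbp).
#' @param alpha_grid sweep-intensity grid (per bp); default 64 log-spaced
#'   values in `[1e-8, 1e-2]`.
#' @param exact compute the spectrum transform exactly per site (slow; used
#'   by tests) instead of interpolating a precomputed table.
#' @param grid optional explicit grid positions.
#' @return data frame: `grid_pos`, `clr`, `alpha_hat`.
#' @export
clr_scan <- function(h, background, spacing = 2000, alpha_grid = NULL,
                     exact = FALSE, grid = NULL) {
  stopifnot(inherits(background, "background_sfs"))
  n <- background$n
  if (inherits(h, "hap_matrix")) {
    counts <- colSums(h$alleles)
    pos <- h$positions
    L <- h$region_length
    if (nrow(h$alleles) != n)
      stopf("background spectrum is for n = %d but data has %d haplotypes",
            n, nrow(h$alleles))
  } else {
    counts <- h$counts; pos <- h$positions
    L <- h$region_length %||% max(pos)
  }
  keep <- counts >= 1 & counts <= n
  counts <- counts[keep]; pos <- pos[keep]
  o <- order(pos)
  counts <- counts[o]; pos <- pos[o]
  q <- background$counts
  if (sum(q) == 0) stopf("empty background spectrum")
  fixed_class <- q[n] > 0
  # half-count smoothing: classes unobserved in a finite background keep a
  # plausible (not vanishing) probability, so a stray data site cannot hand
  # the sweep model an unbounded likelihood gain
  q[seq_len(n - 1)] <- q[seq_len(n - 1)] + 0.5
  if (!fixed_class) {
    if (any(counts == n)) stopf("data contains fixed-derived sites but the background has no fixed class")
    q[n] <- 0
  }
  q <- q / sum(q)
  grid <- grid %||% seq(spacing / 2, L, by = spacing)
  alpha_grid <- alpha_grid %||% exp(seq(log(1e-8), log(1e-2), length.out = 64))
  res <- clr_scan_cpp(as.integer(counts), as.numeric(pos), n, q,
                      as.numeric(grid), as.numeric(alpha_grid),
                      exact, 20, 160L)
  data.frame(grid_pos = grid, clr = res$clr, alpha_hat = res$alpha_hat)
}

#' Windowed enrichment of extreme standardized scores
#'
#' Splits each chromosome into non-overlapping windows of `window` bp,
#' computes the proportion of SNPs with |score| > `threshold` per window
#' (windows with fewer than `min_snps` scored SNPs are excluded) and ranks
#' windows by empirical genome-wide quantile.
#'
#' @param scores standardized scores per SNP (NA ignored).
#' @param pos per-SNP positions.
#' @param chrom per-SNP chromosome (default single chromosome).
#' @param window window size in bp (default 700 kbp).
#' @param threshold |score| cutoff (default 2).
#' @param min_snps minimum scored SNPs per window (default 100).
#' @return data frame: chrom, start, end, n_snps, prop, quantile (empirical
#'   rank among retained windows), q95/q99 attributes with the marked
#'   thresholds.
#' @export
window_enrichment <- function(scores, pos, chrom = NULL, window = 700000,
                              threshold = 2, min_snps = 100) {
  chrom <- chrom %||% rep("chr", length(pos))
  ok <- !is.na(scores)
  res <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch & ok
    if (!any(sel)) next
    p <- pos[sel]; s <- scores[sel]
    w <- (p - 1) %/% window
    for (wi in unique(w)) {
      i <- w == wi
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = wi * window + 1, end = (wi + 1) * window,
        n_snps = sum(i), prop = mean(abs(s[i]) > threshold))
    }
  }
  out <- do.call(rbind, res)
  out <- out[out$n_snps >= min_snps, , drop = FALSE]
  if (nrow(out)) {
    out$quantile <- ecdf(out$prop)(out$prop)
    attr(out, "q95") <- as.numeric(quantile(out$prop, 0.95))
    attr(out, "q99") <- as.numeric(quantile(out$prop, 0.99))
  }
  rownames(out) <- NULL
  out
}
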