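# Watterson's theta and Tajima's D helpers
watterson_theta <- function(S, n) S / sum(1 / seq_len(n - 1))

tajima_d <- function(pi_total, S, n) {
  if (S < 2) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Summary statistics of a haplotype region for ABC
#'
#' Fixed-order summary vector: per-bp pi, Watterson's theta and Tajima's D in
#' 5 equal physical subwindows (15 values); H1, H12 and H2/H1 in the central
#' subwindow; the number of distinct haplotypes; and the largest
#' |unstandardized iHS| among the `n_ihs` polymorphic SNPs nearest the region
#' center (EHH integrals truncated at the region edge). Regions with fewer
#' than 2 segregating sites return all-NA with attribute `degenerate = TRUE`.
#'
#' @param h a [haplotype_matrix()].
#' @param n_ihs number of central SNPs scored for iHS (default 3).
#' @return Named numeric vector of 20 summaries.
#' @export
summarize_region <- function(h, n_ihs = 3) {
  stopifnot(inherits(h, "hap_matrix"))
  n <- nrow(h$alleles)
  L <- h$region_length
  nm <- c(paste0(rep(c("pi", "thetaw", "tajd"), each = 5), "_w", 1:5),
          "H1_c", "H12_c", "H2H1_c", "n_haplotypes", "max_abs_ihs")
  S <- ncol(h$alleles)
  if (S < 2) {
    out <- setNames(rep(NA_real_, 20), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  persite <- site_pi_cpp(h$alleles)
  br <- seq(0, L, length.out = 6)
  wi <- pmin(5, pmax(1, findInterval(h$positions, br, rightmost.closed = TRUE)))
  wlen <- diff(br)
  stats3 <- vapply(1:5, function(w) {
    k <- wi == w
    Sw <- sum(k)
    c(pi = sum(persite[k]) / wlen[w],
      thetaw = if (Sw > 0) watterson_theta(Sw, n) / wlen[w] else 0,
      tajd = tajima_d(sum(persite[k]) * 1, Sw, n))
  }, numeric(3))
  kc <- wi == 3
  if (sum(kc) >= 1) {
    key <- apply(h$alleles[, kc, drop = FALSE], 1, paste, collapse = "")
    pfr <- sort(as.numeric(table(key)) / n, decreasing = TRUE)
    H1 <- sum(pfr^2)
    H12 <- if (length(pfr) >= 2) (pfr[1] + pfr[2])^2 + sum(pfr[-(1:2)]^2) else H1
    H2 <- H1 - pfr[1]^2
    H2H1 <- H2 / H1
  } else H1 <- H12 <- H2H1 <- NA_real_
  nhap <- length(unique(apply(h$alleles, 1, paste, collapse = "")))
  f <- colMeans(h$alleles)
  poly <- which(f > 0.05 & f < 0.95)
  ihs_max <- NA_real_
  if (length(poly)) {
    ctr <- poly[order(abs(h$positions[poly] - L / 2))]
    ctr <- ctr[seq_len(min(n_ihs, length(ctr)))]
    v <- ihs_unstandardized(h, edge_rule = "truncate", sites = ctr)$ihs
    if (any(is.finite(v))) ihs_max <- max(abs(v), na.rm = TRUE)
  }
  vec <- c(as.numeric(t(stats3)), H1, H12, H2H1, nhap, ihs_max)
  # tajd NA (empty window) encoded as 0: an empty window is uninformative
  vec[is.na(vec)] <- 0
  setNames(vec, nm)
}

#' ABC prior specification
#'
#' Independent log10-uniform priors for the sweep's time since fixation T
#' (units of 4*Ne generations) and selection coefficient s.
#'
#' @param log10_T,log10_s prior ranges (default both `c(-4, -0.5)`).
#' @param n_sims number of reference simulations.
#' @return Object of class `"abc_priors"`.
#' @export
abc_priors <- function(log10_T = c(-4, -0.5), log10_s = c(-4, -0.5),
                       n_sims = 10000) {
  stopifnot(all(is.finite(c(log10_T, log10_s))),
            log10_T[1] < log10_T[2], log10_s[1] < log10_s[2])
  structure(list(log10_T = log10_T, log10_s = log10_s,
                 n_sims = as.integer(n_sims)),
            class = "abc_priors")
}

#' Build the ABC reference table
#'
#' Draws (s, T) from the priors, simulates one trajectory-conditioned sweep
#' per draw with the remaining parameters taken from `model`, and attaches
#' the [summarize_region()] summaries. Simulation failures are recorded, not
#' fatal.
#'
#' @param priors an [abc_priors()].
#' @param model a [sweep_model()] template (its `s` and `T_fix` are
#'   overwritten per draw).
#' @param seed optional RNG seed.
#' @param N_cap rescaling cap passed to [simulate_sweep_haplotypes()].
#' @return data frame: `s`, `T_fix`, 20 summary columns; attribute
#'   `"failures"` = fraction of failed simulations.
#' @export
build_reference_table <- function(priors, model, seed = NULL, N_cap = 5000) {
  stopifnot(inherits(priors, "abc_priors"), inherits(model, "sweep_model"))
  with_seed(seed, {
    ns <- priors$n_sims
    s_draw <- 10^runif(ns, priors$log10_s[1], priors$log10_s[2])
    T_draw <- 10^runif(ns, priors$log10_T[1], priors$log10_T[2])
    rows <- vector("list", ns)
    fail <- 0L
    for (i in seq_len(ns)) {
      mi <- model
      mi$s <- s_draw[i]
      mi$T_fix <- T_draw[i]
      sm <- tryCatch(
        summarize_region(simulate_sweep_haplotypes(mi, N_cap = N_cap)),
        error = function(e) NULL)
      if (is.null(sm) || isTRUE(attr(sm, "degenerate"))) {
        fail <- fail + 1L
        rows[i] <- list(NULL)
      } else rows[[i]] <- c(s = s_draw[i], T_fix = T_draw[i], sm)
    }
    ok <- !vapply(rows, is.null, logical(1))
    tab <- as.data.frame(do.call(rbind, rows[ok]))
    attr(tab, "failures") <- fail / ns
    tab
  })
}

#' Rejection ABC
#'
#' Standardizes all summaries by their reference-table SDs, accepts the
#' epsilon-quantile of draws nearest the observed summary in Euclidean
#' distance, and reports posterior medians and equal-tailed 95% credible
#' intervals for s and T.
#'
#' @param observed named summary vector from [summarize_region()].
#' @param table reference table from [build_reference_table()].
#' @param eps acceptance quantile (default 0.005).
#' @return Object of class `"abc_fit"`: `accepted` (data frame of accepted
#'   s, T draws), `median` and `ci95` for both parameters, `eps`,
#'   `n_accepted`, and the accepted distances.
#' @export
abc_reject <- function(observed, table, eps = 0.005) {
  sumcols <- setdiff(names(table), c("s", "T_fix"))
  X <- as.matrix(table[, sumcols, drop = FALSE])
  obs <- observed[sumcols]
  use <- is.finite(obs) & apply(X, 2, function(c) all(is.finite(c)))
  X <- X[, use, drop = FALSE]
  obs <- obs[use]
  sds <- apply(X, 2, sd)
  sds[sds == 0] <- 1
  D <- sweep(sweep(X, 2, obs), 2, sds, "/")
  dist <- sqrt(rowSums(D^2))
  n_acc <- max(1, ceiling(eps * nrow(X)))
  if (n_acc < 20)
    stopf("eps = %g accepts only %d draws (< 20); increase eps or the table size",
          eps, n_acc)
  keep <- order(dist)[seq_len(n_acc)]
  acc <- table[keep, c("s", "T_fix")]
  structure(list(
    accepted = acc,
    median = c(s = median(acc$s), T_fix = median(acc$T_fix)),
    ci95 = rbind(s = quantile(acc$s, c(0.025, 0.975)),
                 T_fix = quantile(acc$T_fix, c(0.025, 0.975))),
    eps = eps, n_accepted = n_acc, distances = dist[keep]),
    class = "abc_fit")
}

#' @export
print.abc_fit <- function(x, ...) {
  cat(sprintf("<abc_fit> %d accepted draws (eps = %g)\n", x$n_accepted, x$eps))
  cat(sprintf("  s: median %.4g, 95%% CI [%.4g, %.4g]\n",
              x$median["s"], x$ci95["s", 1], x$ci95["s", 2]))
  cat(sprintf("  T: median %.4g, 95%% CI [%.4g, %.4g] (4Ne generations)\n",
              x$median["T_fix"], x$ci95["T_fix", 1], x$ci95["T_fix", 2]))
  invisible(x)
}

#' Convert a sweep age from coalescent units to years
#'
#' @param T_fix age in units of 4*Ne generations.
#' @param Ne diploid effective size.
#' @param generation_time years per generation (default 15).
#' @return Age in years.
#' @export
sweep_age_years <- function(T_fix, Ne, generation_time = 15) {
  T_fix * 4 * Ne * generation_time
}

#' Sweep footprint-size experiment
#'
#' Simulates `n_reps` completed sweeps plus `n_neutral` matched neutral
#' replicates, scans each with [clr_scan()] against a background spectrum
#' pooled from the neutral replicates, declares grid points significant above
#' the `sig_quantile` quantile of the pooled neutral CLR values, and measures
#' per sweep replicate the maximal contiguous span of significant grid
#' points.
#'
#' @param model a [sweep_model()] describing the sweep replicates.
#' @param n_reps number of sweep replicates (default 100).
#' @param n_neutral number of neutral replicates (default `n_reps`).
#' @param spacing CLR grid spacing in bp (default 2 kbp).
#' @param sig_quantile neutral CLR quantile defining significance
#'   (default 0.99).
#' @param seed optional RNG seed.
#' @param N_cap rescaling cap for the sweep simulations.
#' @return List of class `"footprint_experiment"`: `spans` (bp, per sweep
#'   replicate), `neutral_spans`, `q95` (95% quantile of the sweep spans),
#'   `threshold`, `unstable` flag for `n_reps < 20`.
#' @export
footprint_experiment <- function(model, n_reps = 100, n_neutral = n_reps,
                                 spacing = 2000, sig_quantile = 0.99,
                                 seed = NULL, N_cap = 5000) {
  stopifnot(inherits(model, "sweep_model"))
  with_seed(seed, {
    theta_bp <- 4 * model$Ne * model$mu
    rho_bp <- 4 * model$Ne * model$r
    neutral <- lapply(seq_len(n_neutral), function(i)
      simulate_neutral_haplotypes(theta_bp, rho_bp, model$L, model$n_hap))
    counts <- unlist(lapply(neutral, function(h) colSums(h$alleles)))
    bg <- background_sfs(counts, model$n_hap)
    max_span <- function(scan, thr) {
      sig <- scan$clr > thr
      if (!any(sig)) return(0)
      r <- rle(sig)
      max(r$lengths[r$values]) * spacing
    }
    neutral_clr <- lapply(neutral, function(h) clr_scan(h, bg, spacing = spacing))
    thr <- quantile(unlist(lapply(neutral_clr, `[[`, "clr")), sig_quantile)
    sweeps <- lapply(seq_len(n_reps), function(i)
      clr_scan(simulate_sweep_haplotypes(model, N_cap = N_cap), bg,
               spacing = spacing))
    spans <- vapply(sweeps, max_span, numeric(1), thr = thr)
    nspans <- vapply(neutral_clr, max_span, numeric(1), thr = thr)
    structure(list(spans = spans, neutral_spans = nspans,
                   q95 = as.numeric(quantile(spans, 0.95)),
                   threshold = as.numeric(thr),
                   unstable = n_reps < 20),
              class = "footprint_experiment")
  })
}

#' @export
print.footprint_experiment <- function(x, ...) {
  cat(sprintf("<footprint_experiment> %d sweep replicates; CLR threshold %.2f\n",
              length(x$spans), x$threshold))
  cat(sprintf("  significant-span quantiles (bp): 50%% %.0f, 95%% %.0f\n",
              median(x$spans), x$q95))
  if (x$unstable) cat("  warning: < 20 replicates, quantiles unstable\n")
  invisible(x)
}
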