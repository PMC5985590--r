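#' Selective-sweep simulation model
#'
#' Parameter bundle for the trajectory-conditioned sweep simulator and the ABC
#' prior space. Defaults follow the northern-sweep dating setup: diploid
#' effective size 92,000, mutation rate 3.75e-8 and recombination rate
#' 0.729e-8 per bp per generation over a 25-kbp region, selection coefficient
#' 0.016 (homozygote advantage; heterozygote 1 + s/2), and time since fixation
#' expressed in units of 4*Ne generations. Because published scaled rates for
#' this design are not mutually consistent with the per-bp rates, `theta` and
#' `rho` (region totals, 4\*Ne\*mu\*L and 4\*Ne\*r\*L) may be supplied directly
#' and override `mu`/`r`.
#'
#' @param Ne diploid effective population size.
#' @param mu,r per-bp per-generation mutation and recombination rates.
#' @param L region length (bp).
#' @param s selection coefficient of the derived homozygote, in (0, 1].
#' @param T_fix time since fixation of the beneficial allele, in units of
#'   4*Ne generations. The default corresponds to ~19,000 years at a
#'   15-year generation time.
#' @param n_hap number of sampled haplotypes.
#' @param sweep_pos position of the selected site (bp), default region center.
#' @param theta,rho optional region-total scaled rates overriding `mu`/`r`.
#' @return An object of class `"sweep_model"`.
#' @export
sweep_model <- function(Ne = 92000, mu = 3.75e-8, r = 0.729e-8, L = 25000,
                        s = 0.016, T_fix = (18952 / 15) / (4 * 92000),
                        n_hap = 60, sweep_pos = L / 2,
                        theta = NULL, rho = NULL) {
  if (!is.null(theta)) mu <- theta / (4 * Ne * L)
  if (!is.null(rho)) r <- rho / (4 * Ne * L)
  if (Ne < 2) stopf("Ne must be >= 2")
  if (s <= 0 || s > 1) stopf("s must be in (0, 1]")
  if (T_fix < 0) stopf("T_fix must be >= 0")
  if (sweep_pos < 1 || sweep_pos > L) stopf("sweep_pos must lie in [1, L]")
  if (4 * Ne * mu * L <= 0) stopf("theta = 4*Ne*mu*L must be positive")
  if (4 * Ne * r * L < 0) stopf("rho = 4*Ne*r*L must be non-negative")
  structure(list(Ne = Ne, mu = mu, r = r, L = L, s = s, T_fix = T_fix,
                 n_hap = as.integer(n_hap), sweep_pos = sweep_pos),
            class = "sweep_model")
}

#' @export
print.sweep_model <- function(x, ...) {
  cat(sprintf("<sweep_model> Ne=%g s=%g T_fix=%.4g (4Ne gens) L=%g bp n_hap=%d\n",
              x$Ne, x$s, x$T_fix, x$L, x$n_hap))
  cat(sprintf("  theta=%.4g rho=%.4g (region totals)\n",
              4 * x$Ne * x$mu * x$L, 4 * x$Ne * x$r * x$L))
  invisible(x)
}

# Desk-scale rescaling: choose a simulated population size preserving 4*Ne*s,
# theta and rho exactly (s, mu, r are scaled up by Ne/N_sim, time in 4Ne units
# is invariant). N_sim is lowered to the cap but raised again if the rescaled
# s would exceed s_max, keeping the per-copy selection coefficient sane.
rescale_model <- function(model, N_cap = 5000, s_max = 0.5, min_4Ns = 1) {
  four_Ns <- 4 * model$Ne * model$s
  if (four_Ns < min_4Ns)
    stopf("4*N*s = %.3g below the floor %.3g: selection signal would be lost in rescaling",
          four_Ns, min_4Ns)
  N_sim <- min(N_cap, model$Ne)
  if (four_Ns / (4 * N_sim) > s_max)
    N_sim <- min(model$Ne, ceiling(four_Ns / (4 * s_max)))
  fac <- model$Ne / N_sim
  list(N_sim = N_sim, s_sim = model$s * fac,
       mu_sim = model$mu * fac, r_sim = model$r * fac)
}

#' Wright-Fisher trajectory of a beneficial allele conditioned on fixation
#'
#' Simulates the allele-frequency path of a new mutation forward in time under
#' genotype fitnesses 1, 1 + s/2 and 1 + s (additive selection), by binomial
#' sampling of the next generation around the post-selection expected
#' frequency. Paths that lose the allele are rejected until one fixes. The
#' accepted path is returned backward in time: it starts at 1 (fixation),
#' ends at 1/(2*N_sim) (the origin) and is terminated by a 0.
#'
#' @param N_sim diploid population size of the (possibly rescaled) simulation.
#' @param s selection coefficient of the derived homozygote.
#' @param seed optional RNG seed.
#' @param max_attempts rejection budget before giving up.
#' @return An object of class `"trajectory"`: list with `freqs` (backward
#'   path) and `N_sim`.
#' @export
simulate_wf_trajectory <- function(N_sim, s, seed = NULL, max_attempts = 1e6) {
  if (N_sim < 2) stopf("N_sim must be >= 2")
  if (s <= 0) stopf("s must be positive")
  res <- with_seed(seed, wf_trajectory_cpp(N_sim, s, as.integer(max_attempts)))
  if (is.null(res$freqs))
    stopf("no trajectory fixed within the rejection budget of %d attempts", max_attempts)
  structure(list(freqs = res$freqs, N_sim = N_sim, attempts = res$attempts),
            class = "trajectory")
}

# map raw simulator coordinates (0 <= p < L, continuous) onto [1, L]
sim_positions <- function(p, L) 1 + p * (L - 1) / L

#' Simulate haplotypes under a completed selective sweep
#'
#' Structured-coalescent simulation conditioned on a Wright-Fisher fixation
#' trajectory: a neutral phase of duration `T_fix` (all lineages linked to the
#' fixed beneficial allele), then a discrete-generation structured phase in
#' which lineages coalesce within allelic classes at rates scaled by the class
#' frequency and recombine between classes, and finally the neutral ancestral
#' process. Mutations are dropped on branches at rate `mu`; output is a
#' polarized [haplotype_matrix()] of the polymorphic sites.
#'
#' @param model a [sweep_model()].
#' @param seed optional RNG seed.
#' @param N_cap cap on the rescaled population size (see Details in the
#'   methods vignette); `s`, `mu`, `r` are rescaled to preserve 4Ns, theta
#'   and rho.
#' @param s_max largest admissible rescaled selection coefficient; the cap is
#'   relaxed upward for strongly selected models.
#' @param min_4Ns rescaling floor on 4*N*s.
#' @param max_attempts trajectory rejection budget.
#' @return A [haplotype_matrix()].
#' @export
simulate_sweep_haplotypes <- function(model, seed = NULL, N_cap = 5000,
                                      s_max = 0.5, min_4Ns = 1,
                                      max_attempts = 1e6) {
  stopifnot(inherits(model, "sweep_model"))
  rs <- rescale_model(model, N_cap, s_max, min_4Ns)
  with_seed(seed, {
    traj <- simulate_wf_trajectory(rs$N_sim, rs$s_sim, max_attempts = max_attempts)
    res <- arg_sweep_cpp(model$n_hap, rs$N_sim, rs$mu_sim, rs$r_sim, model$L,
                         model$sweep_pos, traj$freqs,
                         model$T_fix * 4 * rs$N_sim)
    haplotype_matrix(res$haplotypes, sim_positions(res$positions, model$L), model$L)
  })
}

#' Simulate neutral haplotypes (coalescent with recombination)
#'
#' @param theta_per_bp scaled mutation rate 4*N*mu per bp.
#' @param rho_per_bp scaled recombination rate 4*N*r per bp.
#' @param L region length (bp), positive.
#' @param n_hap sample size (haplotypes).
#' @param seed optional RNG seed.
#' @param N_sim nominal diploid size used internally (results depend only on
#'   theta and rho).
#' @return A [haplotype_matrix()].
#' @export
simulate_neutral_haplotypes <- function(theta_per_bp, rho_per_bp, L, n_hap,
                                        seed = NULL, N_sim = 5000) {
  if (L <= 0) stopf("L must be positive")
  if (theta_per_bp < 0 || rho_per_bp < 0) stopf("rates must be non-negative")
  mu_bp <- theta_per_bp / (4 * N_sim)
  r_bp <- rho_per_bp / (4 * N_sim)
  res <- with_seed(seed, arg_neutral_cpp(n_hap, N_sim, mu_bp, r_bp, L))
  haplotype_matrix(res$haplotypes, sim_positions(res$positions, L), L)
}

#' Configuration for the synthetic study cohort
#'
#' Defaults emulate the design of the motivating study: 94 diploids from 12
#' populations along a ~10-degree latitudinal gradient, near-zero background
#' differentiation (Balding-Nichols FST 0.0021), a single sweep region whose
#' derived beneficial allele is restricted to the northern populations, a
#' logistic latitudinal cline at the causal SNP, and a bud-set phenotype in
#' which the causal SNP explains 65% of the genetic variance with partial
#' dominance (homozygous-derived trees set bud 28 days earlier; heterozygotes
#' show 0.75 of that shift).
#'
#' @param n_pops number of populations.
#' @param pop_sizes individuals per population (summing to the cohort size).
#' @param latitudes per-population latitude, strictly increasing (degrees N).
#' @param background_fst Balding-Nichols differentiation of background SNPs.
#' @param n_background number of background SNPs.
#' @param region_length sweep-region length (bp).
#' @param region_theta,region_rho_over_theta scaled diversity of the sweep
#'   region per bp and the genome-wide rho/theta ratio.
#' @param sweep_s,sweep_T_fix selection coefficient and time since fixation
#'   (4*Ne generations) of the planted northern sweep.
#' @param sweep_Ne effective size parameterizing the sweep region simulation.
#' @param north_pops indices of populations carrying the sweep.
#' @param causal_pve target proportion of genetic variance explained by the
#'   causal SNP on the additive (least-squares dosage) scale -- the scale a
#'   GWAS effect estimate measures; with partial dominance the genotype-class
#'   R^2 sits slightly above this value (0 disables the causal effect).
#' @param causal_effect bud-set shift (days) of the derived homozygote.
#' @param dominance dominance coefficient of the derived allele.
#' @param cline_slope logistic slope (per degree latitude) of the derived
#'   causal-allele cline; midpoint sits between the Mid populations.
#' @param grand_mean baseline bud-set day.
#' @param env_noise_sd noise added to the standardized-latitude environmental
#'   score.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_pops = 12,
                          pop_sizes = c(rep(8L, 10), 7L, 7L),
                          latitudes = seq(56.3, 65.8, length.out = n_pops),
                          background_fst = 0.0021,
                          n_background = 3000,
                          region_length = 5e4,
                          region_theta = 0.0081,
                          region_rho_over_theta = 0.229,
                          sweep_s = 0.016,
                          sweep_T_fix = (18952 / 15) / (4 * 92000),
                          sweep_Ne = 92000,
                          north_pops = 9:12,
                          causal_pve = 0.65,
                          causal_effect = -28,
                          dominance = 0.75,
                          cline_slope = 1.0,
                          grand_mean = 240,
                          env_noise_sd = 0.3) {
  stopifnot(length(pop_sizes) == n_pops, length(latitudes) == n_pops,
            all(diff(latitudes) > 0))
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a full synthetic study cohort with known ground truth
#'
#' Background SNPs are drawn under the Balding-Nichols model (per-population
#' allele frequencies Beta-distributed around an ancestral frequency with the
#' configured FST). The sweep region is simulated by
#' [simulate_sweep_haplotypes()] for the northern populations and by
#' [simulate_neutral_haplotypes()] for the remaining populations; the derived
#' causal allele follows a logistic latitudinal cline. The phenotypic genetic
#' value is grand mean + causal genotype effect (with partial dominance) +
#' polygenic term + residual, with variances solved so that the causal SNP
#' explains the configured proportion of variance. The environmental score is
#' standardized latitude plus noise.
#'
#' @param config a [cohort_config()].
#' @param seed optional RNG seed.
#' @return A list of class `"study_cohort"`: `genotypes` ([genotype_matrix()]
#'   over background + region SNPs), `region_haplotypes` ([haplotype_matrix()]
#'   over all cohort haplotypes for the sweep region), `metadata` (data frame:
#'   id, population, latitude, env_pc1, genetic_value), and `truth` (every
#'   generating parameter plus realized allele frequencies and realized PVE).
#' @export
simulate_study_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    cf <- config
    n <- sum(cf$pop_sizes)
    pop <- rep(seq_len(cf$n_pops), cf$pop_sizes)
    lat <- cf$latitudes[pop]
    north <- pop %in% cf$north_pops
    n_north <- sum(north); n_south <- n - n_north

    ## background SNPs: Balding-Nichols
    Fst <- cf$background_fst
    p_anc <- runif(cf$n_background, 0.1, 0.9)
    a <- p_anc * (1 - Fst) / Fst
    b <- (1 - p_anc) * (1 - Fst) / Fst
    pk <- matrix(rbeta(cf$n_pops * cf$n_background,
                       rep(a, each = cf$n_pops), rep(b, each = cf$n_pops)),
                 nrow = cf$n_pops)  # pops x snps
    G_bg <- matrix(rbinom(n * cf$n_background, 2, pk[pop, ]), nrow = n)
    maf_bg <- pmin(colMeans(G_bg) / 2, 1 - colMeans(G_bg) / 2)
    keep <- maf_bg > 0.05
    G_bg <- G_bg[, keep, drop = FALSE]

    ## sweep region haplotypes
    L <- cf$region_length
    theta <- cf$region_theta
    rho <- theta * cf$region_rho_over_theta
    model <- sweep_model(Ne = cf$sweep_Ne, L = L, s = cf$sweep_s,
                         T_fix = cf$sweep_T_fix, n_hap = 2 * n_north,
                         theta = theta * L, rho = rho * L)
    H_n <- simulate_sweep_haplotypes(model)
    H_s <- simulate_neutral_haplotypes(theta, rho, L, 2 * n_south)

    ## causal allele: logistic cline in latitude, midpoint between Mid pops
    mid_pops <- tail(setdiff(seq_len(cf$n_pops), cf$north_pops), 2)
    mid <- mean(cf$latitudes[mid_pops])
    f_cline <- 1 / (1 + exp(-cf$cline_slope * (cf$latitudes - mid)))
    f_ind <- f_cline[pop]
    hap_causal <- rbinom(2 * n, 1, rep(f_ind, each = 2))
    dos_causal <- hap_causal[seq(1, 2 * n, 2)] + hap_causal[seq(2, 2 * n, 2)]

    ## merge region site sets (union; absent group is ancestral), insert causal
    pos_n <- H_n$positions; pos_s <- H_s$positions
    cpos <- model$sweep_pos
    allpos <- sort(unique(c(pos_n, pos_s, cpos)))
    A <- matrix(0L, nrow = 2 * n, ncol = length(allpos))
    south_rows <- rep(!north, each = 2)
    A[!south_rows, match(pos_n, allpos)] <- H_n$alleles
    A[south_rows, match(pos_s, allpos)] <- H_s$alleles
    A[, match(cpos, allpos)] <- hap_causal
    H_region <- haplotype_matrix(A, allpos, L)
    causal_idx_hap <- match(cpos, allpos)

    ## region genotypes on integer coordinates (chr10-like offset)
    offset <- 16.5e6
    ipos <- floor(allpos) + offset
    keep_site <- !duplicated(ipos)
    # the causal column must survive integer-coordinate deduplication
    clash <- ipos == ipos[causal_idx_hap]
    keep_site[clash] <- FALSE
    keep_site[causal_idx_hap] <- TRUE
    G_rg <- A[seq(1, 2 * n, 2), keep_site, drop = FALSE] +
      A[seq(2, 2 * n, 2), keep_site, drop = FALSE]
    rg_pos <- ipos[keep_site]
    causal_pos_geno <- ipos[causal_idx_hap]

    ## assemble genotype matrix
    m_bg <- ncol(G_bg)
    g <- genotype_matrix(cbind(G_bg, G_rg),
                         chrom = c(rep("chr1", m_bg), rep("chr10", length(rg_pos))),
                         pos = c(seq_len(m_bg) * 1000, rg_pos),
                         aa = c(rep(NA_character_, m_bg),
                                rep("A", length(rg_pos))))

    ## phenotype
    eff <- cf$causal_effect
    gmap <- c(0, eff * cf$dominance, eff)
    g_eff <- gmap[dos_causal + 1]
    var_c <- var(g_eff)
    if (cf$causal_pve >= 1)
      stopf("causal_pve must be < 1")
    if (cf$causal_pve > 0 && var_c == 0)
      stopf("requested PVE %.2f unattainable: causal genotype is monomorphic (feasible maximum 0)",
            cf$causal_pve)
    if (cf$causal_pve > 0) {
      # target the additive (least-squares dosage) variance share: that is the
      # quantity a GWAS effect estimate measures; the dominance deviation acts
      # as extra background variance on top of the solved remainder
      afit <- lm(g_eff ~ dos_causal)
      var_add <- var(afit$fitted.values)
      var_dom <- var_c - var_add
      var_rest <- var_add / cf$causal_pve - var_add - var_dom
      if (var_rest < 0)
        stopf("requested PVE %.2f unattainable with this dominance/frequency pattern (feasible maximum %.3f)",
              cf$causal_pve, var_add / var_c)
    } else {
      g_eff <- rep(0, n)
      var_rest <- (0.25 * abs(eff))^2  # baseline spread when no QTL is planted
    }
    nz <- min(200, m_bg)
    Z <- scale(G_bg[, seq_len(nz), drop = FALSE])
    Z[is.na(Z)] <- 0
    poly <- as.numeric(Z %*% rnorm(nz))
    poly <- poly / sd(poly) * sqrt(var_rest / 2)
    resid <- rnorm(n, 0, sqrt(var_rest / 2))
    y <- cf$grand_mean + g_eff + poly + resid

    meta <- data.frame(id = sprintf("ind%03d", seq_len(n)),
                       population = pop, latitude = lat,
                       env_pc1 = as.numeric(scale(lat)) + rnorm(n, 0, cf$env_noise_sd),
                       genetic_value = y)

    realized_pve <- summary(lm(y ~ factor(dos_causal)))$r.squared
    realized_pve_additive <- summary(lm(y ~ dos_causal))$r.squared
    truth <- list(config = cf,
                  causal_chrom = "chr10",
                  causal_pos = causal_pos_geno,
                  causal_index = m_bg + match(causal_pos_geno, rg_pos),
                  causal_hap_index = causal_idx_hap,
                  causal_dosage = dos_causal,
                  cline_freqs = f_cline,
                  realized_pop_freqs = tapply(dos_causal / 2, pop, mean),
                  realized_pve = realized_pve,
                  realized_pve_additive = realized_pve_additive,
                  region_model = model,
                  north_individuals = which(north))
    structure(list(genotypes = g, region_haplotypes = H_region,
                   metadata = meta, truth = truth),
              class = "study_cohort")
  })
}

#' @export
print.study_cohort <- function(x, ...) {
  cat(sprintf("<study_cohort> %d individuals, %d pops, %d SNPs (%d in sweep region)\n",
              nrow(x$genotypes$dosages), length(unique(x$metadata$population)),
              ncol(x$genotypes$dosages), sum(x$genotypes$chrom == "chr10")))
  cat(sprintf("  causal SNP at %s:%d, realized PVE %.3f\n",
              x$truth$causal_chrom, x$truth$causal_pos, x$truth$realized_pve))
  invisible(x)
}
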