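# project the derived-count spectrum of a sample of n_from haplotypes onto a
# smaller sample of n_to (hypergeometric downsampling), dropping the
# monomorphic classes
project_sfs <- function(counts, n_from, n_to) {
  q <- numeric(n_to)
  for (k in counts) {
    pj <- dhyper(seq_len(n_to), k, n_from - k, n_to)
    q <- q + pj
  }
  q
}

#' Pipeline configuration
#'
#' Declarative settings for [run_pipeline()]. Unknown keys are rejected.
#'
#' @param cohort a [cohort_config()] for the synthetic input.
#' @param seed RNG seed driving every stage.
#' @param fdr q-value significance level for the three scans (default 0.05).
#' @param consensus_min consensus rule: flagged by at least this many methods
#'   (default 2).
#' @param K latent factors for the environmental scan (default 2).
#' @param ld_r2,ld_window LD pruning settings before PCA (defaults 0.2 / 50).
#' @param pi_window,pi_step diversity/FST window and step in bp.
#' @param region_gap candidate-region merge gap in bp (default 50 kbp).
#' @param abc_n_sims ABC reference-table size for the dating stage.
#' @param abc_eps ABC acceptance quantile.
#' @param south_pops,mid_pops,north_pops population-group definitions.
#' @param out_dir optional output directory; when set, all artifacts are
#'   written there (TSV/BED/JSON, seed-stamped).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(), seed = 1, fdr = 0.05,
                            consensus_min = 2, K = 2, ld_r2 = 0.2,
                            ld_window = 50, pi_window = 10000, pi_step = 5000,
                            region_gap = 50000, abc_n_sims = 2000,
                            abc_eps = 0.01, south_pops = 1:6, mid_pops = 7:8,
                            north_pops = 9:12, out_dir = NULL) {
  stopifnot(fdr > 0, fdr < 1, consensus_min >= 1, K >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stage order: cohort simulation, MAF filtering, population structure
#' (LD-pruned PCA + Tracy-Widom, kinship, pairwise-population FST + Mantel
#' IBD), the tri-method adaptation scan with Storey q-values and consensus
#' candidate regions, selective-sweep statistics on the sweep region per
#' population group (South/Mid/North: windowed pi, H statistics, group FST,
#' CLR), and ABC dating of the northern sweep. Artifacts are returned (and
#' written to `config$out_dir` when set).
#'
#' @param config a [pipeline_config()].
#' @return List of class `"pipeline_result"` with elements `cohort`,
#'   `structure`, `scan`, `consensus`, `sweep_stats`, `abc`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    invisible(msg)
  }
  stage <- "simulate"
  res <- tryCatch({
    say("seed=%d", cf$seed)
    cohort <- simulate_study_cohort(cf$cohort, seed = cf$seed)
    meta <- cohort$metadata
    g <- cohort$genotypes
    say("simulate: %d individuals, %d SNPs", nrow(g$dosages), ncol(g$dosages))

    stage <- "qc"
    maf <- snp_maf(g)
    keep <- which(maf > 0.05)
    g <- genotype_matrix(g$dosages[, keep, drop = FALSE], g$chrom[keep],
                         g$pos[keep], g$ref[keep], g$alt[keep], g$aa[keep])
    causal_idx <- which(g$chrom == cohort$truth$causal_chrom &
                          g$pos == cohort$truth$causal_pos)
    say("qc: MAF>0.05 kept %d SNPs", length(keep))

    stage <- "structure"
    bg <- which(g$chrom == "chr1")
    pruned <- bg[ld_prune(g$dosages[, bg, drop = FALSE], cf$ld_r2, cf$ld_window)]
    pca <- genotype_pca(g$dosages[, pruned, drop = FALSE],
                        K = min(10, length(pruned), nrow(g$dosages) - 1))
    tw <- tracy_widom_pvalues(pca$eigenvalues, pca$n, pca$m)
    kin <- centered_kinship(g$dosages[, bg, drop = FALSE])
    fst_pw <- wc_fst(g$dosages[, bg, drop = FALSE], meta$population,
                     mode = "pairwise-pop")
    lat <- tapply(meta$latitude, meta$population, mean)
    km <- as.matrix(dist(lat)) * 111
    ibd <- mantel_ibd(fst_pw, km, n_perm = 999, seed = cf$seed + 1)
    say("structure: %d pruned SNPs, PC1 p=%.3g, mantel r=%.3f p=%.3f",
        length(pruned), tw$p[1], ibd$r, ibd$p)

    stage <- "scan"
    pca_full <- genotype_pca(g$dosages, K = 2)
    s_pca <- pca_outlier_scan(pca_full, g)
    s_env <- latent_factor_scan(g, meta$env_pc1, K = cf$K)
    s_gwas <- lmm_gwas(g, meta$genetic_value, kin)
    q_pca <- storey_qvalues(s_pca$p)
    q_env <- storey_qvalues(s_env$p)
    q_gwas <- storey_qvalues(s_gwas$p)
    flags <- cbind(pca = q_pca < cf$fdr, env = q_env < cf$fdr,
                   gwas = q_gwas < cf$fdr)
    scan <- data.frame(chrom = g$chrom, pos = g$pos,
                       beta = s_gwas$beta, se = s_gwas$se,
                       p_pca = s_pca$p, p_env = s_env$p, p_gwas = s_gwas$p,
                       q_pca = q_pca, q_env = q_env, q_gwas = q_gwas,
                       flags, pve = s_gwas$pve)
    cons <- consensus_candidates(flags, g$chrom, g$pos,
                                 min_methods = cf$consensus_min,
                                 gap = cf$region_gap)
    say("scan: %d consensus candidates in %d region(s)",
        length(cons$candidates), nrow(cons$regions))

    stage <- "sweepstats"
    H <- cohort$region_haplotypes
    groups <- list(South = cf$south_pops, Mid = cf$mid_pops,
                   North = cf$north_pops)
    hap_rows <- function(pops) {
      ind <- which(meta$population %in% pops)
      sort(c(2 * ind - 1, 2 * ind))
    }
    south_rows <- hap_rows(cf$south_pops)
    cnt_s <- colSums(H$alleles[south_rows, , drop = FALSE])
    sweep_stats <- lapply(groups, function(pp) {
      rows <- hap_rows(pp)
      Hg <- haplotype_matrix(H$alleles[rows, , drop = FALSE], H$positions,
                             H$region_length)
      qproj <- project_sfs(cnt_s[cnt_s >= 1 & cnt_s <= length(south_rows)],
                           length(south_rows), length(rows))
      qproj[length(rows)] <- 0
      bg_sfs <- structure(list(counts = qproj, n = length(rows)),
                          class = "background_sfs")
      list(pi = windowed_pi(Hg, cf$pi_window, cf$pi_step),
           h = h_statistics(Hg, window = cf$pi_window, step = cf$pi_step),
           clr = clr_scan(Hg, bg_sfs))
    })
    grp_label <- ifelse(meta$population %in% cf$north_pops, "North",
                        ifelse(meta$population %in% cf$mid_pops, "Mid", "South"))
    region_cols <- which(g$chrom == cohort$truth$causal_chrom)
    fst_groups <- wc_fst(g$dosages[, region_cols, drop = FALSE], grp_label,
                         mode = "windowed", window = cf$pi_window,
                         step = cf$pi_step, pos = g$pos[region_cols],
                         chrom = g$chrom[region_cols])
    say("sweepstats: groups %s", paste(names(groups), collapse = "/"))

    stage <- "abc"
    north_rows <- hap_rows(cf$north_pops)
    Hn <- haplotype_matrix(H$alleles[north_rows, , drop = FALSE], H$positions,
                           H$region_length)
    model <- cohort$truth$region_model
    model$n_hap <- length(north_rows)
    priors <- abc_priors(n_sims = cf$abc_n_sims)
    tab <- build_reference_table(priors, model, seed = cf$seed + 2)
    fit <- abc_reject(summarize_region(Hn), tab, eps = cf$abc_eps)
    say("abc: s median %.4g, T median %.4g", fit$median["s"], fit$median["T_fix"])

    out <- structure(list(cohort = cohort,
                          structure = list(pca = pca, tw = tw, kinship = kin,
                                           fst_pairwise = fst_pw, mantel = ibd),
                          scan = scan, consensus = cons,
                          sweep_stats = c(sweep_stats,
                                          list(fst_groups = fst_groups)),
                          abc = fit, log = log),
                     class = "pipeline_result")
    if (!is.null(cf$out_dir)) write_pipeline_outputs(out, cf)
    out
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  res
}

# serialize pipeline artifacts; every file carries the config hash + seed
write_pipeline_outputs <- function(res, cf) {
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- sprintf("%08x", sum(utf8ToInt(paste(deparse(cf[setdiff(names(cf), "out_dir")]),
                                              collapse = "")) *
                                seq_along(utf8ToInt(paste(deparse(cf[setdiff(names(cf), "out_dir")]),
                                                          collapse = "")))) %% 2^31)
  stamp <- sprintf("# config=%s seed=%d", hash, cf$seed)
  wtsv <- function(df, name) {
    p <- file.path(cf$out_dir, name)
    writeLines(stamp, p)
    suppressWarnings(write.table(df, p, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
  }
  wtsv(res$scan, "scan.tsv")
  wtsv(data.frame(res$structure$pca$scores), "eigenvec.tsv")
  wtsv(data.frame(eigenvalue = res$structure$pca$eigenvalues), "eigenval.tsv")
  wtsv(res$sweep_stats$fst_groups, "fst_windows.tsv")
  if (nrow(res$consensus$regions)) {
    bed <- res$consensus$regions
    bed$start <- bed$start - 1  # BED half-open 0-based
    wtsv(bed[, c("chrom", "start", "end", "n_candidates")], "candidates.bed")
  }
  jsonlite::write_json(
    list(config_hash = hash, seed = cf$seed,
         mantel = res$structure$mantel,
         abc = list(median = as.list(res$abc$median),
                    ci95 = as.data.frame(res$abc$ci95))),
    file.path(cf$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(stamp, res$log), file.path(cf$out_dir, "pipeline.log"))
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
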