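#' Read a VCF into genotype and/or haplotype matrices
#'
#' Biallelic SNP records are parsed with vcfR; multiallelic records are
#' skipped (counted). Coordinates stay 1-based; an `AA` INFO tag populates
#' the ancestral allele. With `haplotypes = TRUE` all genotypes must be
#' phased (`|` separator) and a polarized [haplotype_matrix()] is returned
#' (requires AA tags; sites with unknown ancestral state are dropped).
#'
#' @param path VCF file (plain or gzipped).
#' @param haplotypes return phased haplotypes instead of dosages.
#' @param region_length region span for the haplotype container (default:
#'   max position).
#' @return A [genotype_matrix()] or [haplotype_matrix()]; attribute
#'   `"n_multiallelic"` counts skipped records.
#' @export
read_vcf <- function(path, haplotypes = FALSE, region_length = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
    nchar(fix[, "ALT"]) != 1
  nmulti <- sum(multi)
  v <- v[!multi, ]
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, colnames(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  info <- vcfR::extract.info(v, element = "AA")
  aa <- if (is.null(info)) rep(NA_character_, nrow(fix)) else as.character(info)
  if (haplotypes) {
    unph <- which(!grepl("|", gt, fixed = TRUE) & !is.na(gt))
    if (length(unph)) {
      rec <- (unph[1] - 1) %% nrow(gt) + 1
      stopf("unphased genotype at record %s:%s; phased GT required for haplotypes",
            fix[rec, "CHROM"], fix[rec, "POS"])
    }
    a1 <- suppressWarnings(apply(gt, 2, function(col) as.integer(substr(col, 1, 1))))
    a2 <- suppressWarnings(apply(gt, 2, function(col) as.integer(substr(col, 3, 3))))
    # interleave: haplotypes 2i-1, 2i belong to sample i
    H <- matrix(NA_integer_, nrow = 2 * ncol(gt), ncol = nrow(gt))
    for (i in seq_len(ncol(gt))) {
      H[2 * i - 1, ] <- a1[, i]
      H[2 * i, ] <- a2[, i]
    }
    # polarize: allele == ancestral -> 0
    keep <- !is.na(aa) & (aa == fix[, "REF"] | aa == fix[, "ALT"])
    H <- H[, keep, drop = FALSE]
    flip <- aa[keep] == fix[keep, "ALT"]
    H[, flip] <- 1L - H[, flip]
    pos <- as.numeric(fix[keep, "POS"])
    out <- haplotype_matrix(H, pos, region_length %||% max(pos))
  } else {
    d <- t(suppressWarnings(apply(gt, 2, function(col) {
      a1 <- as.integer(substr(col, 1, 1))
      a2 <- as.integer(substr(col, 3, 3))
      a1 + a2
    })))
    out <- genotype_matrix(d, fix[, "CHROM"], as.numeric(fix[, "POS"]),
                           fix[, "REF"], fix[, "ALT"], aa)
  }
  attr(out, "n_multiallelic") <- nmulti
  out
}

#' Write a genotype or haplotype matrix as VCF 4.2
#'
#' Haplotype matrices are written with phased GT (pairs of rows = one
#' diploid; fractional simulator positions are rounded up and deduplicated)
#' and an `AA` INFO tag (row coding is already polarized, so AA = REF).
#' Genotype matrices are written unphased. Headers are stamped with the
#' generating seed when supplied.
#'
#' @param x a [genotype_matrix()] or [haplotype_matrix()].
#' @param path output file.
#' @param sample_names optional sample names.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, sample_names = NULL, seed = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=aspensweep%s",
                   if (is.null(seed)) "" else sprintf(";seed=%d", seed)),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (inherits(x, "hap_matrix")) {
    nh <- nrow(x$alleles)
    stopifnot(nh %% 2 == 0)
    ns <- nh / 2
    pos <- ceiling(x$positions)
    keep <- !duplicated(pos)
    A <- x$alleles[, keep, drop = FALSE]
    pos <- pos[keep]
    sn <- sample_names %||% sprintf("hap_ind%03d", seq_len(ns))
    gtrows <- vapply(seq_len(ncol(A)), function(j) {
      paste(paste(A[seq(1, nh, 2), j], A[seq(2, nh, 2), j], sep = "|"),
            collapse = "\t")
    }, character(1))
    body <- paste("region", pos, ".", "A", "T", ".", "PASS", "AA=A", "GT",
                  gtrows, sep = "\t")
  } else {
    ns <- nrow(x$dosages)
    sn <- sample_names %||% sprintf("ind%03d", seq_len(ns))
    code <- c("0/0", "0/1", "1/1")
    gtrows <- vapply(seq_len(ncol(x$dosages)), function(j) {
      g <- x$dosages[, j]
      s <- ifelse(is.na(g), "./.", code[g + 1])
      paste(s, collapse = "\t")
    }, character(1))
    info <- ifelse(is.na(x$aa), ".", paste0("AA=", x$aa))
    body <- paste(x$chrom, format(x$pos, scientific = FALSE, trim = TRUE),
                  ".", x$ref, x$alt, ".", "PASS", info, "GT", gtrows,
                  sep = "\t")
  }
  colline <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sn), collapse = "\t")
  writeLines(c(hdr, colline, body), path)
  invisible(path)
}

#' Write / read cohort metadata TSV
#'
#' @param meta data frame (id, population, latitude, env_pc1, genetic_value).
#' @param path file path.
#' @param seed optional seed recorded in a comment header.
#' @return `path` invisibly / the data frame.
#' @export
write_metadata <- function(meta, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  utils::write.table(meta, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write a cohort truth record as JSON
#'
#' @param truth the `truth` element of [simulate_study_cohort()].
#' @param path output file.
#' @param seed optional seed recorded in the record.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, seed = NULL) {
  truth$seed <- seed
  truth$config <- unclass(truth$config)
  truth$region_model <- unclass(truth$region_model)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Write / read an ABC reference table as TSV with header metadata
#'
#' The priors, model and seed are carried in `#`-prefixed header lines.
#'
#' @param table table from [build_reference_table()].
#' @param path file path.
#' @param priors,model,seed optional metadata recorded in the header.
#' @return `path` invisibly / the table (with a `"failures"` attribute when
#'   present in the header).
#' @export
write_reference_table <- function(table, path, priors = NULL, model = NULL,
                                  seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(priors))
    writeLines(sprintf("# priors: log10_T=[%g,%g] log10_s=[%g,%g] n_sims=%d",
                       priors$log10_T[1], priors$log10_T[2],
                       priors$log10_s[1], priors$log10_s[2], priors$n_sims), con)
  if (!is.null(model))
    writeLines(sprintf("# model: Ne=%g mu=%g r=%g L=%g n_hap=%d sweep_pos=%g",
                       model$Ne, model$mu, model$r, model$L, model$n_hap,
                       model$sweep_pos), con)
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  fa <- attr(table, "failures")
  if (!is.null(fa)) writeLines(sprintf("# failures=%g", fa), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  hdr <- grep("^#", readLines(path, n = 10), value = TRUE)
  fa <- sub(".*failures=", "", grep("failures=", hdr, value = TRUE))
  if (length(fa)) attr(out, "failures") <- as.numeric(fa)
  out
}

#' Write an ABC fit as JSON
#'
#' @param fit an [abc_reject()] result.
#' @param path output file.
#' @param generation_time,Ne optional conversion of T to years, reported
#'   alongside the coalescent-unit estimates.
#' @return `path`, invisibly.
#' @export
write_abc_result <- function(fit, path, generation_time = NULL, Ne = NULL) {
  out <- list(eps = fit$eps, n_accepted = fit$n_accepted,
              median = as.list(fit$median),
              ci95 = list(s = as.numeric(fit$ci95["s", ]),
                          T_fix = as.numeric(fit$ci95["T_fix", ])))
  if (!is.null(generation_time) && !is.null(Ne)) {
    out$generation_time <- generation_time
    out$T_years <- list(
      median = sweep_age_years(fit$median[["T_fix"]], Ne, generation_time),
      ci95 = sweep_age_years(as.numeric(fit$ci95["T_fix", ]), Ne, generation_time))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
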