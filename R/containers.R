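#' Phased haplotype matrix
#'
#' Container for phased, polarized haplotypes over a contiguous region:
#' a haplotypes-by-sites 0/1 matrix (0 = ancestral, 1 = derived), strictly
#' increasing physical positions (1-based; fractional coordinates are allowed
#' for infinite-sites simulation output and are rounded on VCF emission), and
#' the region length in bp.
#'
#' @param alleles integer/numeric matrix, haplotypes x sites, values 0/1
#'   (NA allowed for missing).
#' @param positions numeric vector of per-site coordinates in `[1, region_length]`,
#'   strictly increasing.
#' @param region_length region span in bp.
#' @return An object of class `"hap_matrix"`.
#' @export
haplotype_matrix <- function(alleles, positions, region_length) {
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != length(positions))
    stopf("alleles has %d sites but %d positions given", ncol(alleles), length(positions))
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stopf("positions must be strictly increasing")
  if (length(positions) && (min(positions) < 1 || max(positions) > region_length))
    stopf("positions must lie in [1, region_length]")
  bad <- !(alleles %in% c(0L, 1L) | is.na(alleles))
  if (any(bad)) stopf("alleles must be 0, 1 or NA")
  structure(list(alleles = alleles, positions = as.numeric(positions),
                 region_length = as.numeric(region_length)),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %d haplotypes x %d sites over %s bp\n",
              nrow(x$alleles), ncol(x$alleles), format(x$region_length, big.mark = ",")))
  invisible(x)
}

#' Diploid genotype matrix
#'
#' Dosage matrix (individuals x sites, values 0/1/2/NA counting the alternate
#' allele) together with per-site metadata: chromosome, 1-based position,
#' reference/alternate alleles and, when polarized, the ancestral allele.
#'
#' @param dosages numeric/integer matrix, individuals x sites.
#' @param chrom,pos per-site chromosome and 1-based position (positions must be
#'   unique within a chromosome).
#' @param ref,alt per-site alleles; default abstract "A"/"T".
#' @param aa per-site ancestral allele (`NA` = unknown).
#' @return An object of class `"geno_matrix"`. Minor allele frequencies are
#'   available through [snp_maf()].
#' @export
genotype_matrix <- function(dosages, chrom, pos, ref = NULL, alt = NULL, aa = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (length(chrom) == 1) chrom <- rep(chrom, m)
  stopifnot(length(chrom) == m, length(pos) == m)
  if (anyDuplicated(paste(chrom, pos))) stopf("duplicated chrom:pos")
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stopf("dosages must be 0, 1, 2 or NA")
  structure(list(dosages = dosages, chrom = as.character(chrom),
                 pos = as.numeric(pos),
                 ref = ref %||% rep("A", m), alt = alt %||% rep("T", m),
                 aa = aa %||% rep(NA_character_, m)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d SNPs (%d chromosome%s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$chrom)),
              if (length(unique(x$chrom)) == 1) "" else "s"))
  invisible(x)
}

#' Per-SNP minor allele frequency
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector in `[0, 0.5]` (NA for all-missing sites).
#' @export
snp_maf <- function(g) {
  f <- colMeans(g$dosages, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

# alternate-allele frequency
snp_freq <- function(g) colMeans(g$dosages, na.rm = TRUE) / 2
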