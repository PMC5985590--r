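Package: aspensweep
Title: Local Adaptation Scans, Selective Sweep Statistics and ABC Sweep
    Dating for Latitudinal Tree Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting local adaptation in weakly structured
    forest-tree cohorts sampled along an environmental gradient. Provides a
    seed-reproducible synthetic-cohort generator (Balding-Nichols background
    plus a trajectory-conditioned structured-coalescent selective sweep with
    a clinal major-effect phenology locus), post-VCF variant quality control,
    population-structure analyses (PCA with Tracy-Widom significance, IBS
    relatedness, Weir-Cockerham FST, Mantel isolation by distance, kinship,
    LD decay), a tri-method adaptation scan (PCA-loading outliers,
    latent-factor environmental association, kinship mixed-model GWAS) with
    Storey-Tibshirani q-values, consensus candidate regions, per-SNP variance
    explained and small-scale causal fine-mapping, haplotype- and SFS-based
    selection statistics (EHH, iHS, nSL, H1/H12/H2, windowed diversity,
    composite likelihood ratio sweep scans), and rejection ABC for jointly
    dating a sweep and estimating its selection coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
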