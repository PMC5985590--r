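---
title: "Methods behind aspensweep: simulation, scans and sweep dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind aspensweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

aspensweep re-creates, end to end, the analysis arc used to dissect a
major-effect local-adaptation locus in a weakly structured tree cohort
sampled along a latitudinal gradient: a genome scan for adaptation
candidates, selective-sweep statistics on the candidate region, and
approximate Bayesian dating of the sweep. Because the motivating study design
(94 diploids from 12 Swedish populations, near-zero background
differentiation, a single ~major phenology QTL swept in the northern
populations) relies on resequencing data that is not redistributable, the
package is built around a synthetic-cohort generator with known ground
truth, so that every stage can be verified quantitatively.

## The coalescent simulation engine

All haplotype data are produced by a single structured-coalescent engine
(compiled code) that tracks, for each ancestral lineage, a list of genomic
segments together with the set of sampled haplotypes descending from each
segment. Mutations are dropped on lineages as time passes (infinite-sites,
uniform positions) and resolve directly to sample rows, so no marginal trees
are stored. Recombination splits a lineage at a uniform point in its span;
coalescence merges segment lists and discards any segment whose descendant
set reaches the full sample (its mutations would be fixed and invisible as
polymorphism; see "CLR and substitutions" below).

A completed hard sweep is simulated in three phases, backward in time:

1. a neutral phase of duration `T_fix` (time since fixation, supplied in
   units of 4Ne generations);
2. a discrete-generation structured phase along a Wright-Fisher frequency
   trajectory of the beneficial allele, itself simulated forward under
   genotype fitnesses 1, 1 + s/2, 1 + s and conditioned on fixation by
   rejection. Within each generation lineages coalesce within allelic
   classes at rate 1/(2N x) per pair (x the class frequency), and a
   recombining lineage's unlinked side re-draws its class with probability x.
   Discrete generations (rather than a continuous-time approximation) are
   exact for the per-generation rates and simple to reason about;
3. the standard neutral ancestral process to completion.

**Rescaling.** Simulating Ne = 92,000 directly is wasteful; the engine
rescales to a smaller `N_sim` (cap 5,000 by default) while preserving 4Ns,
theta = 4 Ne mu L, rho = 4 Ne r L and all times in units of 4Ne generations.
Because a log-uniform prior on s can push the rescaled selection coefficient
above 1, `N_sim` is raised per draw so the rescaled s never exceeds 0.5. A
rescaling floor (4Ns >= 1) guards against rescaling a model whose selection
signal would not survive. A dedicated test checks that halving `N_sim` with
compensating rates leaves segregating-site counts and diversity unchanged
within sampling error.

**Printed scaled rates.** The published parameter set for the dating design
(Ne = 92,000, mu = 3.75e-8, r = 0.729e-8, L = 25,000) is not mutually
consistent with the published region totals (Theta = 86.27, rho = 19.76, which
would require a several-fold smaller Ne); the ratio rho/Theta = 0.229 matches
the genome-wide r/mu ratio, but the absolute values do not follow from the
stated per-bp rates. `sweep_model()` therefore accepts `theta` and `rho`
directly so either convention can be reproduced; the package defaults use
the per-bp rates, and the footprint experiment uses the per-bp diversity
0.0081 with rho/theta = 0.229, as stated for that analysis.

## The synthetic cohort

`simulate_study_cohort()` emulates the study design:

* **Background SNPs** (default 3,000) under the Balding-Nichols model:
  per-population allele frequencies Beta-distributed around a uniform
  ancestral frequency with FST = 0.0021. Twelve populations with 8/8/.../7/7
  individuals (94 total) on latitudes 56.3-65.8 degrees N. The mean
  Weir-Cockerham FST recovered from a cohort is ~0.002 with a Monte-Carlo
  spread of a few 1e-4 at this SNP count.
* **Sweep region** (default 50 kbp at theta = 0.0081/bp): northern
  populations (9-12) receive haplotypes from the sweep simulator
  (s = 0.016, T_fix ~ 19,000 years at a 15-year generation time), the
  southern/mid populations neutral haplotypes; the two groups' site sets are
  merged (sites private to one group are ancestral in the other). The two
  groups are therefore not drawn from one joint genealogy -- the region shows
  the intended diversity trough, haplotype structure and strong north-south
  differentiation, but cross-group LD is not modelled. This is adequate for
  the scans (which key on within-group haplotype structure and on
  between-group frequency differences) and is recorded as a known
  limitation.
* **Causal SNP** at the selected site, with derived-allele frequencies
  following a logistic cline in latitude (slope 1 per degree, midpoint
  between the Mid populations; the study figure showing the cline prints no
  frequencies, so the logistic shape is this package's choice, recorded in
  the truth record).
* **Phenotype**: genetic value = grand mean (bud-set day 240) + causal
  genotype effect + polygenic term + residual. Genotype means follow
  TT = 0, GT = -28 h, GG = -28 days with partial dominance h = 0.75 (the
  study states partial dominance without a coefficient). Variances are
  solved so that the *additive* (least-squares dosage) variance share of the
  causal SNP equals the configured 65%: that is the quantity a GWAS effect
  estimate plus the variance-share formula measures. With h = 0.75 the
  genotype-class R^2 then sits slightly above (~0.70). Half of the remaining
  variance is a polygenic term built from background SNPs (so the kinship
  matrix has something real to absorb), half is i.i.d. residual.
* **Environmental score**: standardized latitude plus N(0, 0.3) noise,
  standing in for a leading environmental principal component dominated by
  growing-season length.

What passing tests on this cohort do *not* show about real data: no
missingness or genotyping error in the default cohort, no LD between the
background SNPs, no shared genealogy between sweep-region groups, abstract
biallelic sites rather than sequence context, and an environmental score
that is latitude by construction.

## Variant QC

Post-VCF filters mirror standard resequencing practice: total-depth bounds
(< 400x, > 4500x, strict inequalities; boundary values kept), excess
mapping-quality-zero reads (> 200), repeat-masked sites, short scaffolds
(< 2 kbp), biallelic SNPs further than 5 bp from indels, genotypes masked at
GQ < 10, per-site call rate >= 70% (counted after GQ masking), a one-sided
exact test for heterozygote excess (Levene/Haldane conditional distribution,
upper tail; p < 1e-8 drops the site), and MAF > 5%. LD pruning removes one
SNP of each pair with r^2 > 0.2 in 50-SNP windows; ties are broken by
removing the lower-MAF SNP, then the higher index (the source pipeline's tool
does not document its tie-break). Ancestral states come from a two-outgroup
rule with precedence to the more distant outgroup.

## Population structure

PCA uses per-SNP mean imputation, centering and sqrt(p(1-p)) scaling; axis
signs are fixed by forcing the largest-|loading| SNP positive. Axis
significance follows the Tracy-Widom approach: for each axis the *remaining*
eigenvalues estimate an effective marker count (excluding the tested one, so
inflating an eigenvalue cannot deflate its own reference), the top remaining
eigenvalue is standardized with the Johnstone constants, and the TW(1) CDF
is evaluated through the Chiani (2014) shifted-gamma approximation
(accurate to ~1e-4 absolute over the whole support, including the far
tails). Weir-Cockerham FST uses the 1984 variance components; multi-locus
estimates (pairwise-population and 10-kbp/5-kbp windowed) are
ratio-of-sums, the convention recorded in output metadata since the source
study does not state which it used. The Mantel test permutes population
labels (the identity permutation is excluded as it is not a reshuffle) with
p = (1 + #(r_perm >= r_obs)) / (1 + n_perm). LD decay fits the Hill-Weir
drift expectation with its finite-sample correction by nonlinear least
squares.

## The tri-method adaptation scan

* **PCA-loading outliers**: squared SNP-PC1 correlations, rescaled by their
  genome-wide mean so the statistic matches the chi-square(1) expectation
  under no structure (the chi-square form is assumed by the method this
  emulates; the rescaling is the calibration this package fixes explicitly).
* **Latent-factor environmental association**: the ridge/SVD formulation --
  latent factors from the SVD of the genotype matrix residualized on the
  environmental score, per-SNP regression on score + factors, genomic-control
  median recalibration of the z-scores. The original method is MCMC-based;
  the SVD formulation targets the same estimand, runs deterministically and
  is the methodological substitution recorded here. K = 0 reduces exactly to
  simple regression.
* **Kinship LMM GWAS**: y = a + x b + u + e with u ~ N(0, sg^2 K), K the
  centered GRM. K is eigendecomposed once; each SNP's variance ratio is
  profiled by 1-D restricted-likelihood optimization on the rotated data
  (exact per-SNP optimization, not the null-model approximation, so the
  effect and standard error feeding the variance-share formula are
  consistent), Wald p-values. At K = I this reproduces OLS exactly.

Storey-Tibshirani q-values (lambda-spline pi0, fixed-lambda 0.5 fallback
below 100 p-values) give the FDR < 5% flags; the consensus rule keeps SNPs
flagged by >= 2 of the 3 methods and merges candidates within 50 kbp into
regions. Per-SNP variance explained is the standard summary-statistic
formula from effect, standard error, MAF and N. Fine-mapping enumerates
causal configurations (<= 2 causal SNPs, per-SNP prior 0.01, non-centrality
prior SD 5) under a multivariate-normal likelihood with the LD matrix
ridge-regularized by 1e-4, and reports the smallest set holding >= 99% of
the configuration mass. Priors follow common tool defaults since the source
specifies only the confidence level.

## Sweep statistics

EHH, iHS and nSL follow the standard definitions; iHS integrates EHH against
physical distance (no genetic map exists for synthetic data) by the
trapezoid rule, truncating where EHH < 0.05 and skipping SNPs whose curve
reaches the region edge first (the cited tool's default conventions). The
reported ratio is ln(iHH_ancestral / iHH_derived), so a long derived
haplotype gives a large negative value and the enrichment statistic uses
|score| > 2 in 700-kbp windows with < 100-SNP windows excluded.
Standardization subtracts the mean and divides by the SD within 100
equal-width derived-frequency bins. H1/H12/H2 use 200-SNP windows averaged
into 10-kbp/5-kbp sliding windows; windowed diversity uses the same physical
windows with a 10% callable-fraction floor. No gap penalty is applied
(synthetic regions have no assembly gaps); a coverage mask argument is
retained for real data.

**CLR.** The composite likelihood ratio contrasts the genome-wide background
SFS with its sweep distortion under independent lineage escape
(1 - exp(-alpha d) per lineage at distance d), maximized over a 64-point
log-spaced alpha grid per 2-kbp grid point. The spectrum transform depends
on alpha and d only through y = alpha d, so it is precomputed on a 160-point
log grid in y and interpolated (an exact mode exists and is what the tests'
brute-force oracle checks against; the interpolation error on CLR is well
below 0.1). The background spectrum gets half-count smoothing so a class
unobserved in a finite background cannot hand the sweep model an unbounded
gain. **Substitutions:** the source study included fixed-derived sites in
the background; a bare coalescent sample cannot define fixed-derived sites
without an outgroup divergence time, so simulation-driven CLR analyses here
use the polymorphic-only likelihood with a matched polymorphic-only
background (`clr_scan()` itself accepts a fixed-derived class when the
supplied background contains one).

## ABC dating

The summary vector (the reference this emulates defers its summaries to an
earlier paper without listing them; the fixed vector below is this package's
declared definition): per-bp pi, Watterson's theta and Tajima's D in 5 equal
subwindows; H1, H12, H2/H1 in the central subwindow; the number of distinct
haplotypes; and the largest |unstandardized iHS| among the 3 central SNPs
(edge-truncated integrals, so the summary is always defined). Empty-window
statistics are encoded 0 (uninformative) rather than dropped, keeping the
vector length fixed.

`build_reference_table()` draws (s, T) from independent log10-uniform priors
on [-4, -0.5] (T in units of 4Ne generations; conversion to years requires a
generation time, default 15 years, reported separately rather than asserted
into the estimate). `abc_reject()` standardizes summaries by the table SDs
and keeps the epsilon-quantile nearest draws by Euclidean distance --
rejection only, no regression adjustment (the simplest defensible choice;
adjustment is left as an extension). Posterior medians and equal-tailed 95%
intervals summarize the accepted draws. Leave-one-out coverage of the 95%
intervals is checked by test (>= 85/100), as is the Spearman association
between posterior medians and the generating s. At desk scale the posterior
median of s for data generated at s = 0.016 is recovered to within a factor
well inside the paper's own reported credible interval (0.006-0.192), with
a mild attraction toward the prior median that tighter tolerances do not
remove -- an expected property of rejection ABC with a 20-summary vector at
this table size.

The footprint experiment simulates completed sweeps plus matched neutral
replicates, pools the neutral CLR values, and calls grid points significant
above their 99th percentile (the source reports "significant peaks" without
defining significance; this rule is recorded in the output). The maximal
contiguous significant span per sweep replicate is summarized by its 95%
quantile.

## Problem sizes

The default analysis sizes are chosen for a single desktop core: ABC
reference tables of 10^4 rows (the source used 5x10^5), 50 pseudo-observed
datasets for the recovery experiment, 100 sweep + 60 neutral replicates of a
500-kbp region for the footprint experiment, 20 cohorts for the PVE
experiment, and cohorts of ~3,000 background SNPs + a 50-kbp sweep region.
The test suite runs reduced versions of the same experiments (smaller
tables, shorter regions, fewer replicates) chosen so each property remains a
sharp check at suite-friendly runtimes.

## Known limitations

* The sweep region's north/south groups come from separate genealogies
  (above); cross-group statistics at the region are driven by frequency
  differences, not shared ancestry.
* The neutral background SNPs are unlinked, so LD-based steps (pruning, LD
  decay) are exercised on the sweep region or on purpose-built fixtures.
* Rejection ABC point estimates inherit the usual tolerance bias; the
  credible intervals are calibrated by construction-level tests, the point
  estimates only to the tolerance documented above.
* `filter_sites()` consumes precomputed per-site depth/MQ0/repeat columns;
  the package never touches BAMs.
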