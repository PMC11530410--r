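---
title: "Genomic vulnerability: mutation load, inbreeding and climate offset"
author: "loadscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic vulnerability: mutation load, inbreeding and climate offset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Small, fragmented populations of long-lived plants face two compounding
genetic risks: the burden of deleterious variation they already carry
(mutation load, amplified by drift and inbreeding), and the mismatch between
the genotype-environment associations they evolved under and the climate
they will face (genomic offset). `loadscape` implements both halves of that
assessment from a multi-sample SNP matrix, together with the windowed
diversity and divergence statistics used to describe lineage structure, and
a synthetic cohort generator so the whole chain is testable without any
external download.

The package is organised as an analysis workflow: the numbered scripts under
`analysis/` narrate one full study on a generated cohort (simulate, filter,
windowed statistics, ROH and inbreeding, mutation load, genomic offset,
synthesis), while every computational step lives in the package's exported
functions, where the tests exercise it.

# Genotype model and site filtering

Genotypes are diploid derived/alternate-allele dosages in {0, 1, 2, NA} tied
to a site table with 1-based coordinates and exactly one REF and one ALT
allele (`genotype_matrix()`). VCF input goes through the vcfR parser;
multiallelic records and indels are dropped on read. `filter_sites()`
retains sites that are polymorphic among observed genotypes, missing in at
most 20% of samples (the default), and above an optional minor-allele
frequency floor; filtering is idempotent and order-preserving. Optional
depth/quality pass-through filters act on FORMAT/DP and QUAL when the file
carries them and are skipped with a message otherwise, because the original
caller context cannot be reconstructed from a bare matrix.

`ld_prune()` is a Plink-style `indep-pairwise` on dosage correlations:
windows of 50 sites advanced by 10, and within each window the worst pair
above r² = 0.2 loses its lower-MAF member (ties drop the later site). Those
defaults are configurable; the invariant the tests enforce is that no
retained pair inside any window exceeds the threshold.

# Windowed diversity and divergence

All window statistics use missing-data-aware denominators and are ratios of
window sums, never means of per-site ratios, following the pixy approach:

* Nucleotide diversity: pi = sum_j(c_ref,j c_alt,j) / sum_j C(n_j, 2), with
  c the called allele counts at site j and n_j their total. An entirely
  missing site changes nothing; a window with no usable site is `NA`,
  never 0. Because the denominator counts genotyped variant sites (not
  genomic base pairs), values are "per genotyped site".
* Absolute divergence: D_XY = sum_j(cA_ref cB_alt + cA_alt cB_ref) /
  sum_j(nA_j nB_j).
* Differentiation: Hudson's estimator F_ST = 1 - mean(Hw_A, Hw_B) / Hb as a
  ratio of window sums, with Hw the unbiased within-population
  heterozygosity c_ref c_alt / C(n, 2) and Hb the D_XY numerator per
  site pair count. Slightly negative estimates are reported as computed.
  Hudson's form was chosen because the windowed tools used in this
  literature do not pin a single estimator in print, and the ratio-of-sums
  Hudson form is the best-behaved under unequal sample sizes.
* Tajima's D uses the 1989 constants with n equal to the full haplotype
  count of the cohort slice; sites with any missing genotype are excluded
  first so a single n applies, and windows with fewer than three segregating
  sites are `NA`.

Windows are non-overlapping, anchored at position 1 of each chromosome
(100 kb by default), and trailing partial windows keep their true span.
`normal_cutoff(0.99)` returns 2.3263, the one-sided 99% standard-normal
quantile used as the significance cutoff for normalized selection-scan
statistics; `landscape_correlation()` gives Spearman correlations between
per-window statistics with mid-ranks and a two-sided t-approximation
p-value.

# Runs of homozygosity and inbreeding

`detect_roh()` scans each individual and chromosome for maximal runs of
non-heterozygous genotyped SNPs supported by sliding 50-SNP windows with
zero heterozygotes allowed (both configurable). Missing genotypes inside a
run are tolerated but not counted, mirroring common ROH callers; runs break
at inter-SNP gaps above 1 Mb. Segments need at least 50 SNPs and 10 kb, and
are classed short (10-100 kb), medium (100-200 kb) or long (>= 200 kb).
The gap, density and het-allowance settings beyond the window size and
10-kb minimum are this package's defaults, exposed as parameters. One
practical consequence worth knowing: at the default synthetic marker
density (50k SNPs over ~300 Mb, one SNP per ~6 kb) a 50-SNP segment spans
roughly 300 kb, so only long ROH are callable on the default cohort; the
short/medium classes are exercised in the tests on dense (8 SNPs/kb)
chromosomes, which is the regime of whole-genome data.

F_ROH divides an individual's cumulative ROH length by the total genome
length from the chromosome-sizes table (not the SNP-covered span). F_IS is
the method-of-moments coefficient (O_hom - E_hom) / (N - E_hom) with
E_hom = sum_j [1 - 2 p_j (1 - p_j) 2n_j/(2n_j - 1)] over the individual's
called sites, p_j the cohort frequency. Against cohort-wide frequencies
F_IS absorbs population structure (a Wahlund excess), so its level sits
above F_ROH; the two are expected to co-rank, which the tests check as a
positive Spearman correlation.

# Mutation load

Sites are polarized by a majority rule: the allele homozygous in more than
half of the genotyped individuals is ancestral (for a complete
154-individual cohort, more than 77). Sites with no such majority are
excluded, as are sites whose inferred ancestral allele is not the reference
allele - the latter guards against deleterious alleles fixed in the
reference assembly. The majority is computed over genotyped individuals, so
the rule degrades gracefully under missingness.

Missense changes are scored with Grantham's (1974) physicochemical
distance, D_ij = rho [alpha (c_i - c_j)^2 + beta (p_i - p_j)^2 +
gamma (v_i - v_j)^2]^(1/2) over side-chain composition, polarity and
volume, with the published alpha = 1.833, beta = 0.1018, gamma = 0.000399.
We derive rho from Grantham's own normalization condition (mean distance
100 over the 190 residue pairs; approximately 50.79, of which the printed
50.723 is a rounded form): this reproduces the landmark values of the
printed table exactly (Leu-Ile = 5 at the bottom, Cys-Trp = 215 at the
top). A small number of historically printed entries differ by one unit
from any consistent evaluation of the formula (for example Ile-Val printed
29 where the formula gives 30) - a known quirk of the 1974 typesetting -
so the package standardizes on the formula and ships its integer grid as a
versioned fixture; none of the discrepancies crosses a classification
threshold. Classification: synonymous variants are benign (SYN); missense
with score 5-150 is tolerated (TOL) and above 150 deleterious (DEL); stop
gains and splice acceptor/donor variants are loss-of-function (LOF)
regardless of residues. The score floor of 5 is vacuous for distinct
residues (the table minimum is 5), so identical-residue "missense" records
are treated as annotation errors.

Per individual and class, with n_het and n_hom the derived heterozygous and
homozygous locus counts:

* homozygosity load = 2 n_hom / (2 n_hom + n_het) - the fraction of derived
  allele copies that are expressed in homozygotes (two copies per
  homozygous locus, one per heterozygous locus);
* masked load = (n_het(DEL) + n_het(LOF)) / SYN;
* realized load = 2 (n_hom(DEL) + n_hom(LOF)) / SYN.

Whether SYN should count derived synonymous allele copies
(2 n_hom + n_het) or loci is genuinely open in the verbal definition of
"proportion relative to all synonymous"; both are implemented
(`count_mode = "alleles"` or `"loci"`) and allele counting is the default
because it weights homozygous and heterozygous loci consistently with the
numerators. Population values are means over members (not medians).
Converting one deleterious heterozygote into a homozygote must decrease the
masked and increase the realized load; that directionality is a standing
test.

# Turnover model and genomic offset

The genotype-environment model follows the gradient-forest idea: per locus,
a bagged ensemble of regression trees (500 per locus by default) predicts
population allele frequencies from climate; each split's impurity reduction
is credited to its variable at the split threshold; per-locus importances
are normalized, weighted by the locus's out-of-bag R² (negatives truncated
to zero), accumulated into 101 equal-width bins over each variable's
training range, and averaged over loci. The running sum along a variable's
axis is its allelic-turnover function: monotone non-decreasing, zero at the
range minimum, with total height the variable's overall importance.
Averaging over loci keeps turnover heights - and therefore offsets -
comparable between SNP sets of different sizes. The reference
gradient-forest implementation computes a conditional-permutation
importance; this package deliberately uses impurity-reduction importance
with R² weighting, which preserves the two properties the offset
construction actually relies on (split-position resolution along each
variable and R²-weighted aggregation) with far simpler machinery. The tree
engine is compiled (Rcpp) because a forest is fitted per locus; it draws
all randomness from R's RNG, so a single seed fixes the model.

Before fitting, redundant climate variables are removed greedily: among any
pair with |Spearman R| > 0.7 the lower-importance variable is dropped
(importances from a preliminary fit on all variables), until no pair
exceeds the threshold.

Adaptive loci are detected by redundancy analysis: the centred frequency
matrix is regressed on the standardized retained variables, the fitted
matrix is decomposed by SVD, and each locus is scored by its squared
singular-value-weighted loading norm on the first three constrained axes.
The phrase "first three axes" is ambiguous between climate principal
components used as predictors and RDA axes used for scoring; the latter is
implemented - scoring on three constrained axes - because it keeps the
predictors interpretable as named climate variables. Significance comes
from 999 row permutations of the climate table
(p = (1 + exceedances)/(n_perm + 1), loci with p <= 0.05 reported);
permutations are drawn in a canonical name-sorted population order so that
relabeling both tables jointly cannot change the result. The outlier rule
(permutation p rather than a loading-SD cutoff) is this package's choice
and is calibrated by construction: on pure-noise frequencies the flagged
fraction matches the nominal level within binomial error, which is a
standing acceptance check. Neutral comparison loci are drawn uniformly
without replacement from intergenic annotations, by default matching the
adaptive set's size.

Offsets: both the current and each future climate grid are mapped through
the turnover functions (values outside the training range are clamped to
the range ends), and the per-cell offset is the Euclidean distance between
the transformed vectors. Per-scenario offsets are computed first and then
averaged over the four scenarios - the order matters, and averaging offsets
(not climates) is the convention adopted. Transformed space makes the
offset a true metric, which the tests verify on random triples. Population
offsets average the per-cell mean offset over cells within 20 km
(haversine) of the population coordinate.

# The synthetic cohort generator

The generator reproduces the statistical structure the analyses assume, not
the biology that produced it:

* Frequencies follow a hierarchical Balding-Nichols model: ancestral
  frequency, a lineage draw with divergence parameter `fst_target = 0.35`
  (two lineages, East and West), then a population draw with drift 0.05 in
  core and 0.15 in edge populations. The variance identity
  Var = F p(1 - p) is checked against closed form, and a two-population
  draw at F = 0.35 must return a Hudson F_ST estimate within 0.02.
* The East lineage passes through a bottleneck filter (25% of polymorphic
  sites fixed lineage-wide), giving it lower diversity than the West and,
  through occasional fixation of deleterious alleles, a drift-load
  signature.
* The 13 populations (154 individuals) mirror a two-lineage design with
  five small range-edge demes; edge populations also carry a heavier
  autozygous-tract burden (about 4 tracts of 0.3-2 Mb per individual
  versus 1 of 0.2-0.8 Mb), implemented as direct tract overwrite - one
  IBD allele is drawn per site and doubled - rather than pedigree
  simulation, which is sufficient to exercise ROH detection and F_ROH
  recovery.
* Site classes are mixed as intergenic 50%, SYN 25%, TOL 15%, DEL 6%,
  LOF 4%, with derived-frequency Beta priors of mean 0.10 (SYN), 0.05
  (TOL) and 0.02 (DEL/LOF) emulating purifying selection without forward
  simulation; missense amino-acid pairs are drawn from the appropriate
  Grantham band so annotation and class agree.
* Climate: 19 bioclimatic variables are built from three latent spatial
  fields (temperature, precipitation, seasonality) plus variable-specific
  spatial wiggles, sampled on a regular lat/lon grid (1/24 degree cells,
  about 4.6 km, the resolution of 2.5-minute climate rasters). Future
  scenarios shift the latent fields additively with multipliers 0.5/1/1.5/2
  across four scenarios, and the displacement grows toward the range
  margins, so edge populations face larger shifts by construction.
  Adaptive loci follow a logistic function of standardized annual mean
  temperature (slope 4, Gaussian noise 0.05).

A fixed configuration reproduces the cohort bit-identically; the writer
emits a plain-text VCFv4.2 (contig headers matching the chromosome-sizes
table) plus TSV tables, and the VCF round-trips through the vcfR-based
reader to the identical matrix.

What the generator does not emulate - and therefore what passing tests do
not establish about real data: linkage and recombination (sites are drawn
independently, so LD pruning only sees structure-induced correlation),
phased haplotypes, selection acting during the simulated history (class
frequency differences are imposed, not evolved), sequencing error, and real
raster formats. Conclusions about the method's behaviour under those forces
need real data or a forward/coalescent simulator, which are out of scope.

# Numerical choices, determinism and problem sizes

Undefined statistics are `NA` with an explicit reason, never silent zeros.
Degenerate Balding-Nichols parameters (F of 0 or 1) are rejected rather
than special-cased. All stochastic steps (generator, forests, permutations,
neutral sampling) take explicit integer seeds, and every pipeline run
writes a JSON manifest of resolved parameters, seeds and input checksums;
rerunning a manifest's configuration reproduces the outputs exactly. Tie
breaks are deterministic everywhere (LD pruning drops the lower-MAF then
later site; variable selection keeps the earlier column on equal
importance).

The test and acceptance workloads are sized for a single CPU: brute-force
oracle comparisons use cohorts of up to 10 diploids by 200 sites (100
replicates), ROH oracles 200 dense 200-kb chromosomes, the Tajima
calibration 10,000 neutral windows, RDA calibration 1,050 loci with 999
permutations, and the end-to-end run the full default cohort (154
individuals, 50,000 sites, ~120,000 grid cells), which completes in about
a minute.

# Known limitations

* Windowed diversity is per genotyped variant site; without monomorphic
  sites in the input it is not comparable to per-base-pair diversity from
  all-sites callers.
* F_IS against pooled cohort frequencies includes the Wahlund component;
  interpret its level, as opposed to its ranking, with care in structured
  cohorts.
* The turnover engine is a faithful re-derivation of the gradient-forest
  construction but not a line-for-line port; absolute importance values
  differ from the reference implementation even where rankings and offsets
  agree qualitatively.
* RDA power depends on how linear the genotype-environment relationship
  is; hard-threshold clines are better found by the forest than by RDA.
* With 13 populations, population-level Spearman correlations have wide
  sampling intervals; the package reports them with t-approximation
  p-values rather than exact permutation p-values.
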