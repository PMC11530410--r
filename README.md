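# loadscape

Genomic-vulnerability analysis for structured plant populations from
multi-sample SNP data. The package serves conservation and landscape
genomicists who want, from one genotype matrix plus annotation, population
map and climate tables:

- **Mutation load**, decomposed per individual. Sites are polarized to
  ancestral/derived by a majority-homozygote rule, missense changes are
  scored with Grantham's physicochemical distance and classified
  SYN / TOL (5 ≤ GS ≤ 150) / DEL (GS > 150) / LOF (stop gain, splice
  acceptor/donor), and three statistics are reported:
  homozygosity load = 2·n_hom / (2·n_hom + n_het) per class,
  masked load = (n_het(DEL) + n_het(LOF)) / SYN, and
  realized load = 2·(n_hom(DEL) + n_hom(LOF)) / SYN.
- **Inbreeding**: runs of homozygosity from 50-SNP sliding windows
  (short/medium/long classes at 10/100/200 kb), F_ROH = cumulative ROH
  length / genome length, and the method-of-moments F_IS.
- **Windowed diversity and divergence** with missing-data-aware
  denominators as ratios of window sums: π, D_XY, Hudson's F_ST
  (F_ST = 1 − mean(Hw)/Hb), Tajima's D, the ±2.3263 (99% one-sided normal)
  selection-scan cutoff, and Spearman landscape correlations.
- **Genomic offset**: a gradient-forest-style turnover model (bagged
  regression trees per locus, split importances R²-weighted and
  accumulated into monotone cumulative-importance functions), redundancy
  filtering of climate variables at |Spearman R| > 0.7, RDA-based adaptive
  SNP detection (scores on the first three constrained axes, 999
  permutations), intergenic neutral SNP sets, per-grid-cell Euclidean
  offsets between transformed current and future climates averaged over
  four scenarios, and 20-km-radius population means.

A synthetic cohort generator (`sim_config()` / `simulate_cohort()`)
emulates the two-lineage, 13-population, 154-individual design the
defaults target — lineage divergence F_ST ≈ 0.35, smaller drift-prone edge
populations, autozygous tracts, deleteriousness-coupled site frequencies,
climate-driven adaptive loci and gridded current/future climates — so the
entire pipeline runs and is tested end-to-end with no downloads.

## Worked example

```r
library(loadscape)

cfg <- sim_config(n_sites = 5000, seed = 1,
                  chrom_lengths = data.frame(chrom = c("chr1", "chr2"),
                                             length = c(2e6, 1.5e6)),
                  grid = list(lon_range = c(104, 120), lat_range = c(18, 31),
                              cell_deg = 0.25, edge_gain = 1.2))
cohort <- simulate_cohort(cfg)
print(cohort$geno)
#> genotype_matrix: 154 samples x 5000 sites on 2 chromosome(s), 0.00% missing

geno <- filter_sites(cohort$geno, max_missing_rate = 0.2)
n_sites(geno)   # polymorphic sites surviving the missingness filter
#> [1] 2708

paths <- write_cohort(cohort, tempfile())    # VCF + TSV file set
ann <- classify_sites(parse_annotations(paths["annotations"], geno,
                                        allow_extra = TRUE))
load_rep <- compute_load(geno, polarize(geno), ann, popmap = cohort$popmap)
print(load_rep)
#> load_report: 154 individuals, 659 polarized classified sites (alleles mode)
#>   mean masked load 0.06302, mean realized load 0.08703

head(load_rep$per_population[order(-load_rep$per_population$realized_load), ], 5)
#>    population masked_load realized_load homozygosity_load_dellof
#> 2          ES  0.02516337     0.1609199                0.8661967
#> 13        ZJJ  0.01792078     0.1532785                0.8972545
#> 12        WZS  0.01795885     0.1504237                0.8973693
#> 11         TB  0.01167639     0.1073747                0.9147436
#> 9          PB  0.01455508     0.1061775                0.8533613
```

The five populations with the highest realized load are exactly the five
small range-edge demes of the simulated design (ES, ZJJ, WZS, TB, PB):
drift and autozygosity expose deleterious alleles in homozygous state,
while the larger core populations keep more of their load masked in
heterozygotes. The per-class table in `load_rep$per_class` carries the
underlying n_het/n_hom counts.

The full study — windowed statistics, ROH/F_ROH/F_IS, the turnover model
and per-population offsets, and the population-level correlation panel —
is narrated by the numbered scripts in `analysis/` (run them in order from
the repository root), or in one call:

```r
res <- run_pipeline(pipeline_config(sim = sim_config(seed = 42),
                                    out_dir = "results/run", seed = 42))
res$summary$populations   # pi, F_ROH, F_IS, loads, offsets per population
res$summary$correlations  # pairwise Spearman panel
```

Every run writes per-stage TSVs and a `manifest.json` with all resolved
parameters, seeds and input checksums; the same configuration reproduces
identical outputs.

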