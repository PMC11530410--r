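# Genomic offset: gradient-forest turnover model on the no-missing LD-pruned
# frequency table (500 trees per locus), redundancy filtering of the 19
# climate variables at |Spearman R| > 0.7, RDA adaptive SNPs (3 axes, 999
# permutations), an equal-sized intergenic neutral set, per-cell offsets
# under four future scenarios (averaged), and 20-km population means.
source("analysis/00_settings.R")

co <- read_cohort(COHORT_DIR)
nomiss <- filter_sites(co$geno, 0, 0)
nomiss <- nomiss[, ld_prune(nomiss)]
freqs <- population_allele_freqs(nomiss, co$popmap)
env <- as.matrix(co$env_pops)[rownames(freqs), ]

sub <- round(seq(1, ncol(freqs), length.out = min(400, ncol(freqs))))
pre <- fit_gradient_forest(freqs[, sub], env, n_trees = 500, seed = SEED)
cat("variable importance (all 19):\n")
print(round(sort(pre$importance, decreasing = TRUE), 5))
vars <- select_climate_variables(env, pre$importance, r_threshold = 0.7)
cat("representative variables:", paste(vars, collapse = ", "), "\n")

rda <- rda_adaptive_snps(freqs, env[, vars], n_axes = 3, n_perm = 999,
                         alpha = 0.05, seed = SEED)
cat(length(rda$adaptive), "adaptive SNPs at p <= 0.05\n")
ann <- parse_annotations(file.path(COHORT_DIR, "annotations.tsv"), nomiss,
                         allow_extra = TRUE)
neutral <- sample_neutral_snps(ann, n = min(length(rda$adaptive),
                                            sum(ann$class == "intergenic")),
                               seed = SEED)

gf_adp <- fit_gradient_forest(freqs[, rda$adaptive], env[, vars],
                              n_trees = 500, seed = SEED)
gf_neu <- fit_gradient_forest(freqs[, neutral], env[, vars],
                              n_trees = 500, seed = SEED)
om_adp <- genomic_offset(gf_adp, co$climate_current, co$climate_future)
om_neu <- genomic_offset(gf_neu, co$climate_current, co$climate_future)
cat(sprintf("mean per-cell offset: adaptive %.4f, neutral %.4f\n",
            mean(om_adp$offset_mean), mean(om_neu$offset_mean)))

pops <- unique(co$popmap[, c("population", "lat", "lon")])
po_adp <- population_offset(om_adp, pops, radius_km = 20)
po_neu <- population_offset(om_neu, pops, radius_km = 20)
out <- merge(po_adp, po_neu, by = "population", suffixes = c("_adaptive", "_neutral"))
out$edge <- out$population %in% EDGE_POPS
print(out[order(-out$offset_adaptive), ], digits = 3)
data.table::fwrite(om_adp, "results/offset_cells_adaptive.tsv", sep = "\t")
data.table::fwrite(om_neu, "results/offset_cells_neutral.tsv", sep = "\t")
data.table::fwrite(out, "results/offset_populations.tsv", sep = "\t")
writeLines(rda$adaptive, "results/adaptive_loci.txt")
writeLines(neutral, "results/neutral_loci.txt")
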