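# Windowed diversity and divergence in 100-kb windows: per-population pi,
# and between-lineage FST/DXY plus per-lineage Tajima's D on equal 40-
# individual lineage subsamples. Also the landscape correlations among the
# window statistics and the +/-2.3263 selection-scan cutoff.
source("analysis/00_settings.R")

co <- read_cohort(COHORT_DIR)
geno <- filter_sites(co$geno, 0.2, 0)
pops <- sim_config()$pops
lineages <- setNames(pops$lineage, pops$population)

w <- windowed_stats(geno, co$popmap, chrom_sizes = co$chrom_sizes,
                    window_size = 1e5, lineages = lineages,
                    lineage_sample_n = 40)
data.table::fwrite(w, "results/windowed_stats.tsv", sep = "\t")

pi_pop <- tapply(w$value[w$stat == "pi" & w$unit %in% pops$population],
                 w$unit[w$stat == "pi" & w$unit %in% pops$population],
                 mean, na.rm = TRUE)
cat("per-population mean pi (per genotyped site):\n")
print(round(pi_pop, 4))
for (l in c("East", "West")) {
  cat(sprintf("lineage %s: pi = %.4f, Tajima's D = %.3f\n", l,
              mean(w$value[w$stat == "pi" & w$unit == l], na.rm = TRUE),
              mean(w$value[w$stat == "tajima_d" & w$unit == l], na.rm = TRUE)))
}
cat(sprintf("between lineages: FST = %.3f, DXY = %.3f\n",
            mean(w$value[w$stat == "fst"], na.rm = TRUE),
            mean(w$value[w$stat == "dxy"], na.rm = TRUE)))

fst <- w$value[w$stat == "fst"]
dxy <- w$value[w$stat == "dxy"]
pi_lin <- (w$value[w$stat == "pi" & w$unit == "East"] +
             w$value[w$stat == "pi" & w$unit == "West"]) / 2
r1 <- landscape_correlation(fst, dxy)
r2 <- landscape_correlation(fst, pi_lin)
r3 <- landscape_correlation(dxy, pi_lin)
cat(sprintf("windowed Spearman: FST~DXY R=%.2f (p=%.2g); FST~pi R=%.2f; DXY~pi R=%.2f\n",
            r1$estimate, r1$p.value, r2$estimate, r3$estimate))
cat(sprintf("selection-scan cutoff at 99%% confidence: +/-%.4f\n",
            normal_cutoff(0.99)))
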