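# Runs of homozygosity (50-SNP windows, >= 10 kb, short/medium/long classes)
# and the FROH / FIS inbreeding coefficients.
source("analysis/00_settings.R")

co <- read_cohort(COHORT_DIR)
geno <- filter_sites(co$geno, 0.2, 0)
genome_length <- sum(as.numeric(co$chrom_sizes$length))

segs <- detect_roh(geno)
cat("segments by class:\n")
print(table(segs$class))

froh <- froh_by_sample(segs, genome_length, geno$samples)
fis <- f_is(geno)
rep <- merge(froh, fis[, c("sample", "f_is")], by = "sample", sort = FALSE)
rep$population <- co$popmap$population[match(rep$sample, co$popmap$sample)]
data.table::fwrite(segs, "results/roh_segments.tsv", sep = "\t")
data.table::fwrite(rep, "results/inbreeding.tsv", sep = "\t")

by_pop <- aggregate(rep[, c("f_roh", "f_is")], list(population = rep$population),
                    mean)
print(by_pop[order(-by_pop$f_roh), ], digits = 3)
r <- landscape_correlation(rep$f_roh, rep$f_is)
cat(sprintf("FROH ~ FIS Spearman R = %.2f (p = %.2g) over %d individuals\n",
            r$estimate, r$p.value, r$n))
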