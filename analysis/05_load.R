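# Mutation load: polarize sites to ancestral/derived via the >50% homozygous
# majority rule (ancestral must match the reference), classify SYN/TOL/DEL/
# LOF with Grantham scores, and compute per-individual homozygosity, masked
# and realized loads.
source("analysis/00_settings.R")

co <- read_cohort(COHORT_DIR)
geno <- filter_sites(co$geno, 0.2, 0)

ann <- parse_annotations(file.path(COHORT_DIR, "annotations.tsv"), geno,
                         allow_extra = TRUE)
pol <- polarize(geno)
cat("polarization:\n")
print(table(pol$status))

cls <- classify_sites(ann)
print(table(cls$mutation_class, useNA = "ifany"))

load_rep <- compute_load(geno, pol, cls, count_mode = "alleles",
                         popmap = co$popmap)
print(load_rep)
data.table::fwrite(load_rep$per_class, "results/load_per_class.tsv", sep = "\t")
data.table::fwrite(load_rep$per_sample, "results/load_per_sample.tsv", sep = "\t")
data.table::fwrite(load_rep$per_population, "results/load_per_population.tsv",
                   sep = "\t")

pp <- load_rep$per_population
pp$edge <- pp$population %in% EDGE_POPS
print(pp[order(-pp$realized_load), ], digits = 3)
cat(sprintf("edge vs core mean realized load: %.4f vs %.4f\n",
            mean(pp$realized_load[pp$edge]), mean(pp$realized_load[!pp$edge])))
cat(sprintf("edge vs core mean masked load:   %.4f vs %.4f\n",
            mean(pp$masked_load[pp$edge]), mean(pp$masked_load[!pp$edge])))
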