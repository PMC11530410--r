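# Site-level filtering: missingness <= 20%, biallelic/polymorphic, and the
# LD-pruned no-missing set used later for genotype-environment work.
source("analysis/00_settings.R")

co <- read_cohort(COHORT_DIR)
cat("raw sites:", n_sites(co$geno), "\n")

filtered <- filter_sites(co$geno, max_missing_rate = 0.2, min_maf = 0)
cat("after missingness/biallelic filter:", n_sites(filtered), "\n")

nomiss <- filter_sites(co$geno, max_missing_rate = 0, min_maf = 0)
kept <- ld_prune(nomiss, ld_window = 50, ld_step = 10, ld_r2 = 0.2)
cat("no-missing, LD-pruned set:", length(kept), "sites\n")

data.table::fwrite(nomiss$sites[kept, c("chrom", "pos")],
                   "results/ld_pruned_sites.tsv", sep = "\t")
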