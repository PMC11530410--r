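test_that("Balding-Nichols draws honour the stated moments", {
  set.seed(101)
  f <- simulate_allele_freqs(rep(0.5, 10000), 0.35, 1)
  expect_equal(mean(f), 0.5, tolerance = 0.01)
  expect_equal(stats::var(as.numeric(f)), 0.35 * 0.25, tolerance = 0.01)
  # near-zero divergence collapses to the ancestral frequency
  set.seed(102)
  f0 <- simulate_allele_freqs(rep(0.3, 2000), 1e-5, 1)
  expect_equal(mean(abs(f0 - 0.3)), 0, tolerance = 0.01)
})

test_that("degenerate divergence and frequencies are rejected", {
  expect_error(simulate_allele_freqs(0.5, 0, 2), "degenerate")
  expect_error(simulate_allele_freqs(0.5, 1, 2), "degenerate")
  expect_error(simulate_allele_freqs(0, 0.2, 2), "strictly")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(fst_target = 1.2), "fst_target")
  expect_error(sim_config(class_mix = c(intergenic = 0.5, SYN = 0.2, TOL = 0.1,
                                        DEL = 0.1, LOF = 0.05)), "sum to 1")
  expect_error(sim_config(n_sites = 0), "positive")
  expect_error(tiny_sim_config(adaptive_spec = list(n_loci = 1e6, slope = 4,
                                                    noise_sd = 0.05,
                                                    variable = "BIO1")),
               "adaptive loci exceed")
})

test_that("an explicit autozygous tract is homozygous at every covered site", {
  cfg <- tiny_sim_config(n_sites = 1500, seed = 23,
                         roh_tracts = data.frame(sample = 1, chrom = "chr1",
                                                 start = 100000, length = 150000))
  co <- simulate_cohort(cfg)
  j <- co$geno$sites$chrom == "chr1" & co$geno$sites$pos >= 1e5 &
    co$geno$sites$pos <= 1e5 + 150000 - 1
  expect_gt(sum(j), 10)
  expect_false(any(co$geno$genotypes[1, j] == 1L, na.rm = TRUE))
  expect_equal(co$truth$roh_tracts$end, 100000 + 150000 - 1)
})

test_that("a tract longer than its chromosome is rejected", {
  expect_error(simulate_cohort(tiny_sim_config(
    roh_tracts = data.frame(sample = 1, chrom = "chr2", start = 1,
                            length = 5e6))), "exceeds its chromosome")
})

test_that("the same configuration reproduces the cohort exactly", {
  co1 <- simulate_cohort(tiny_sim_config(n_sites = 800, seed = 5))
  co2 <- simulate_cohort(tiny_sim_config(n_sites = 800, seed = 5))
  expect_identical(co1$geno$genotypes, co2$geno$genotypes)
  expect_identical(co1$annotations, co2$annotations)
  expect_identical(co1$truth$pop_freqs, co2$truth$pop_freqs)
  co3 <- simulate_cohort(tiny_sim_config(n_sites = 800, seed = 6))
  expect_false(identical(co1$geno$genotypes, co3$geno$genotypes))
})

test_that("deleterious classes have lower derived frequencies than synonymous", {
  co <- simulate_cohort(tiny_sim_config(n_sites = 6000, seed = 29))
  af <- allele_counts(co$geno)$af
  cls <- co$truth$class
  neutral_af <- af[cls == "SYN" & !co$truth$adaptive]
  expect_lt(mean(af[cls == "DEL"]), mean(neutral_af))
  expect_lt(mean(af[cls == "LOF"]), mean(neutral_af))
})

test_that("adaptive loci track the driving climate variable more than neutral loci", {
  co <- simulate_cohort(tiny_sim_config(n_sites = 4000, seed = 31))
  z <- co$truth$env_pops[, co$truth$driving_variable]
  p <- co$truth$pop_freqs
  adaptive <- which(co$truth$adaptive)
  neutral <- sample(which(!co$truth$adaptive), 500)
  cor_of <- function(j) {
    suppressWarnings(abs(stats::cor(p[, j], z, method = "spearman")))
  }
  ca <- vapply(adaptive, cor_of, numeric(1))
  cn <- vapply(neutral, cor_of, numeric(1))
  expect_gte(mean(mean(ca, na.rm = TRUE) > cn, na.rm = TRUE), 0.95)
})

test_that("the East lineage carries less diversity than the West", {
  co <- simulate_cohort(tiny_sim_config(n_sites = 5000, seed = 37))
  lin <- stats::setNames(co$pops$lineage, co$pops$population)
  idx <- split(co$popmap$sample, lin[co$popmap$population])
  pi_w <- nuc_diversity(co$geno[idx$West, ]$genotypes)
  pi_e <- nuc_diversity(co$geno[idx$East, ]$genotypes)
  expect_lt(pi_e, pi_w)
})

test_that("a written cohort round-trips through the VCF reader identically", {
  co <- simulate_cohort(tiny_sim_config(n_sites = 600, seed = 41,
                                        missing_rate = 0.05))
  dir <- tempfile("cohort")
  paths <- write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(unname(back$geno$genotypes), unname(co$geno$genotypes))
  expect_identical(back$geno$samples, co$geno$samples)
  expect_identical(back$geno$sites$pos, co$geno$sites$pos)
  expect_identical(back$geno$sites$ref, co$geno$sites$ref)
  # contig headers declare the chromosome-sizes table
  hdr <- readLines(file.path(dir, "cohort.vcf"), n = 20)
  contigs <- grep("^##contig", hdr, value = TRUE)
  expect_length(contigs, nrow(co$chrom_sizes))
  expect_true(all(mapply(grepl, sprintf("ID=%s,length=%d", co$chrom_sizes$chrom,
                                        co$chrom_sizes$length), contigs)))
})

test_that("an empty cohort refuses to write files", {
  co <- simulate_cohort(tiny_sim_config(n_sites = 600, seed = 43))
  co$geno <- co$geno[, integer(0)]
  expect_error(write_cohort(co, tempfile()), "empty cohort")
})

test_that("neutral windows average Tajima's D near zero", {
  wins <- simulate_neutral_windows(400, n_dip = 10, mean_s = 12, seed = 47)
  d <- vapply(wins, tajimas_d, numeric(1))
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.15)
})
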