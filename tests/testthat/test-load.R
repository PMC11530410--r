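gm_from <- function(g, ref = "A", alt = "T") {
  genotype_matrix(g, data.frame(chrom = "chr1", pos = seq_len(ncol(g)) * 10,
                                ref = ref, alt = alt))
}

test_that("majority-homozygous allele becomes the ancestral state", {
  # 154 individuals: ref/ref homozygous in 100 (> 77) -> polarized
  g1 <- c(rep(0L, 100), rep(1L, 54))
  # alt/alt homozygous in 90 of 154 -> ancestral is alt, not reference
  g2 <- c(rep(2L, 90), rep(1L, 64))
  # 60 ref-hom, 60 alt-hom, 34 het -> no majority
  g3 <- c(rep(0L, 60), rep(2L, 60), rep(1L, 34))
  pol <- polarize(gm_from(cbind(g1, g2, g3)))
  expect_identical(pol$status, c("polarized", "excluded_ref_mismatch",
                                 "excluded_no_majority"))
  expect_identical(pol$ancestral, c("A", "T", "A"))
})

test_that("the majority is taken over genotyped individuals only", {
  # 10 individuals, 4 missing: 4 of 6 genotyped are ref-hom (> 50%)
  g <- c(rep(0L, 4), 1L, 1L, rep(NA_integer_, 4))
  pol <- polarize(gm_from(matrix(g, ncol = 1)))
  expect_identical(pol$status, "polarized")
})

test_that("polarization equals a brute-force re-scan on random matrices", {
  gm <- random_gm(30, 150, miss = 0.2, seed = 21)
  pol <- polarize(gm)
  brute <- apply(gm$genotypes, 2, function(g) {
    g <- g[!is.na(g)]
    if (sum(g == 0) > length(g) / 2) "polarized"
    else if (sum(g == 2) > length(g) / 2) "excluded_ref_mismatch"
    else "excluded_no_majority"
  })
  expect_identical(pol$status, unname(brute))
})

test_that("mutation classes follow the Grantham thresholds and LOF rule", {
  ann <- data.frame(
    chrom = "chr1", pos = 1:5,
    class = c("missense", "missense", "stop_gained", "synonymous", "missense"),
    aa_ref = c("H", "C", NA, NA, "L"),
    aa_alt = c("P", "W", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  expect_message(out <- classify_sites(ann), "lack an amino-acid pair")
  # His-Pro = 77 (TOL range), Cys-Trp = 215 (> 150, DEL)
  expect_identical(as.character(out$mutation_class),
                   c("TOL", "DEL", "LOF", "SYN", NA))
  expect_true(out$grantham[1] >= 5 && out$grantham[1] <= 150)
  expect_gt(out$grantham[2], 150)
})

test_that("splice variants are loss-of-function regardless of residues", {
  ann <- data.frame(chrom = "c", pos = 1:2,
                    class = c("splice_acceptor", "splice_donor"),
                    aa_ref = NA, aa_alt = NA)
  expect_identical(as.character(classify_sites(ann)$mutation_class),
                   c("LOF", "LOF"))
})

test_that("homozygosity load identity holds on an exhaustive count grid", {
  # one individual per (hom, het) combination; DEL sites only plus one fixed
  # SYN site so masked/realized are defined
  grid <- expand.grid(hom = 0:20, het = 0:20)
  n_del <- 40
  g <- t(apply(grid, 1, function(r) {
    c(rep(2L, r["hom"]), rep(1L, r["het"]), rep(0L, n_del - r["hom"] - r["het"]),
      2L)  # trailing SYN hom
  }))
  gm <- gm_from(g)
  pol <- data.frame(status = rep("polarized", ncol(g)))
  cls <- data.frame(mutation_class = factor(c(rep("DEL", n_del), "SYN"),
                                            levels = c("SYN", "TOL", "DEL", "LOF")))
  rep_ <- compute_load(gm, pol, cls)
  del <- rep_$per_class[rep_$per_class$class == "DEL", ]
  expect_equal(del$n_hom, grid$hom)
  expect_equal(del$n_het, grid$het)
  expected <- ifelse(grid$hom + grid$het == 0, NA_real_,
                     2 * grid$hom / (2 * grid$hom + grid$het))
  expect_equal(del$homozygosity_load, expected)
  # masked and realized against the stated formulas (SYN alleles = 2)
  expect_equal(rep_$per_sample$masked_load, grid$het / 2)
  expect_equal(rep_$per_sample$realized_load, 2 * grid$hom / 2)
})

test_that("worked example: 3 derived homozygotes and 4 heterozygotes give 0.6", {
  g <- matrix(c(rep(2L, 3), rep(1L, 4), 2L), nrow = 1)
  pol <- data.frame(status = rep("polarized", 8))
  cls <- data.frame(mutation_class = factor(c(rep("DEL", 7), "SYN"),
                                            levels = c("SYN", "TOL", "DEL", "LOF")))
  rep_ <- compute_load(gm_from(g), pol, cls)
  expect_equal(rep_$per_class$homozygosity_load[rep_$per_class$class == "DEL"], 0.6)
})

test_that("a fully homozygous-derived individual has load 1 and masked load 0", {
  g <- matrix(rep(2L, 12), nrow = 1)
  pol <- data.frame(status = rep("polarized", 12))
  cls <- data.frame(mutation_class = factor(rep(c("SYN", "TOL", "DEL", "LOF"), 3),
                                            levels = c("SYN", "TOL", "DEL", "LOF")))
  rep_ <- compute_load(gm_from(g), pol, cls)
  expect_true(all(rep_$per_class$homozygosity_load == 1))
  expect_equal(rep_$per_sample$masked_load, 0)
})

test_that("converting a DEL heterozygote to homozygote moves masked and realized oppositely", {
  base <- c(rep(1L, 5), rep(2L, 2), rep(0L, 3), rep(2L, 4), rep(1L, 2))  # 10 DEL + 6 SYN
  flip <- base
  flip[1] <- 2L
  cls <- data.frame(mutation_class = factor(c(rep("DEL", 10), rep("SYN", 6)),
                                            levels = c("SYN", "TOL", "DEL", "LOF")))
  pol <- data.frame(status = rep("polarized", 16))
  r0 <- compute_load(gm_from(matrix(base, 1)), pol, cls)$per_sample
  r1 <- compute_load(gm_from(matrix(flip, 1)), pol, cls)$per_sample
  expect_lt(r1$masked_load, r0$masked_load)
  expect_gt(r1$realized_load, r0$realized_load)
})

test_that("homozygosity load ignores SYN sites; masked/realized scale with SYN alleles", {
  g <- matrix(c(rep(1L, 4), rep(2L, 3), rep(2L, 2), rep(1L, 2)), nrow = 1)
  cls1 <- data.frame(mutation_class = factor(c(rep("DEL", 7), rep("SYN", 4)),
                                             levels = c("SYN", "TOL", "DEL", "LOF")))
  pol <- data.frame(status = rep("polarized", 11))
  r1 <- compute_load(gm_from(g), pol, cls1)
  # duplicate the SYN sites: homozygosity load unchanged, masked/realized halve
  g2 <- matrix(c(g[1, 1:7], rep(g[1, 8:11], 2)), nrow = 1)
  cls2 <- data.frame(mutation_class = factor(c(rep("DEL", 7), rep("SYN", 8)),
                                             levels = c("SYN", "TOL", "DEL", "LOF")))
  pol2 <- data.frame(status = rep("polarized", 15))
  r2 <- compute_load(gm_from(g2), pol2, cls2)
  del1 <- r1$per_class$homozygosity_load[r1$per_class$class == "DEL"]
  del2 <- r2$per_class$homozygosity_load[r2$per_class$class == "DEL"]
  expect_equal(del1, del2)
  expect_equal(r2$per_sample$masked_load, r1$per_sample$masked_load / 2)
  expect_equal(r2$per_sample$realized_load, r1$per_sample$realized_load / 2)
})

test_that("locus counting mode divides loci by loci", {
  g <- matrix(c(1L, 1L, 2L, 2L, 1L, 2L), nrow = 1)  # 4 DEL + 2 SYN
  cls <- data.frame(mutation_class = factor(c(rep("DEL", 4), rep("SYN", 2)),
                                            levels = c("SYN", "TOL", "DEL", "LOF")))
  pol <- data.frame(status = rep("polarized", 6))
  r <- compute_load(gm_from(g), pol, cls, count_mode = "loci")$per_sample
  expect_equal(r$masked_load, 2 / 2)
  expect_equal(r$realized_load, 2 / 2)
})
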