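env13 <- function(seed = 1, n_var = 5, n_pop = 13) {
  set.seed(seed)
  m <- matrix(rnorm(n_pop * n_var), n_pop,
              dimnames = list(sprintf("P%02d", 1:n_pop),
                              paste0("V", seq_len(n_var))))
  m
}

test_that("population frequencies equal brute-force allele counting", {
  co <- simulate_cohort(tiny_sim_config(n_sites = 500, seed = 51))
  fr <- population_allele_freqs(co$geno, co$popmap)
  for (p in c("LP", "TB")) {
    rows <- co$popmap$sample[co$popmap$population == p]
    j <- c(3, 77, 410)
    manual <- vapply(j, function(jj) {
      sum(co$geno$genotypes[rows, jj]) / (2 * length(rows))
    }, numeric(1))
    expect_equal(unname(fr[p, j]), manual)
  }
  expect_true(all(fr >= 0 & fr <= 1))
  # a single diploid trio worked example: dosages 0, 1, 2 -> 0.5
  gm <- genotype_matrix(matrix(c(0L, 1L, 2L), 3),
                        data.frame(chrom = "c", pos = 1, ref = "A", alt = "T"),
                        samples = c("a", "b", "c"))
  pm <- data.frame(sample = c("a", "b", "c"), population = "X")
  expect_equal(unname(population_allele_freqs(gm, pm)[1, 1]), 0.5)
})

test_that("missing genotypes in the frequency table are an error", {
  gm <- genotype_matrix(matrix(c(0L, NA), 2),
                        data.frame(chrom = "c", pos = 1, ref = "A", alt = "T"),
                        samples = c("a", "b"))
  expect_error(population_allele_freqs(gm, data.frame(sample = c("a", "b"),
                                                      population = "X")),
               "no-missing")
})

test_that("redundant variables are removed greedily by importance", {
  env <- env13(seed = 2, n_var = 3)
  env <- cbind(env, V1copy = env[, "V1"])
  imp <- c(V1 = 3, V2 = 2, V3 = 1, V1copy = 0.5)
  kept <- select_climate_variables(env, imp, 0.7)
  expect_true("V1" %in% kept && !("V1copy" %in% kept))
  # mutually independent variables all survive
  env2 <- env13(seed = 3, n_var = 4, n_pop = 200)
  expect_identical(select_climate_variables(env2, c(V1 = 1, V2 = 2, V3 = 3, V4 = 4),
                                            0.7), colnames(env2))
  expect_warning(select_climate_variables(cbind(env2, K = 1),
                                          c(V1 = 1, V2 = 2, V3 = 3, V4 = 4, K = 9)),
                 "constant")
})

test_that("a known correlation block is resolved exactly as exhaustive checking says", {
  set.seed(4)
  base <- rnorm(40)
  env <- cbind(A = base, B = base + rnorm(40, 0, 0.1), C = rnorm(40),
               D = -base + rnorm(40, 0, 0.1), E = rnorm(40))
  imp <- c(A = 5, B = 1, C = 3, D = 2, E = 4)
  kept <- select_climate_variables(env, imp, 0.7)
  r <- abs(cor(env[, kept], method = "spearman"))
  diag(r) <- 0
  expect_lte(max(r), 0.7)
  expect_true("A" %in% kept)  # highest-importance member of the block
})

test_that("constant loci produce zero importance and flat turnover functions", {
  env <- env13(seed = 5)
  freqs <- matrix(0.4, nrow = 13, ncol = 6,
                  dimnames = list(rownames(env), paste0("L", 1:6)))
  gf <- fit_gradient_forest(freqs, env, n_trees = 30, seed = 1)
  expect_true(all(gf$importance == 0))
  expect_true(all(vapply(gf$cumulative, function(f) all(f == 0), logical(1))))
})

test_that("a step-function driver ranks first and rises at its threshold", {
  env <- env13(seed = 6, n_var = 5)
  thr <- stats::median(env[, "V3"])
  set.seed(7)
  freqs <- vapply(1:60, function(i) {
    0.15 + 0.6 * (env[, "V3"] > thr) + rnorm(13, 0, 0.03)
  }, numeric(13))
  rownames(freqs) <- rownames(env)
  gf <- fit_gradient_forest(freqs, env, n_trees = 200, seed = 8)
  expect_identical(names(which.max(gf$importance)), "V3")
  # the steepest rise of the V3 turnover function falls inside the interval
  # between the data values flanking the step (any split there is equivalent)
  v_sorted <- sort(env[, "V3"])
  lo <- max(v_sorted[v_sorted <= thr])
  hi <- min(v_sorted[v_sorted > thr])
  imp_bins <- gf$bin_importance$V3
  e <- gf$edges$V3
  best_bin <- which.max(imp_bins)
  expect_true(e[best_bin + 1] > lo && e[best_bin] < hi)
  # determinism
  gf2 <- fit_gradient_forest(freqs, env, n_trees = 200, seed = 8)
  expect_identical(gf$cumulative, gf2$cumulative)
  expect_identical(gf$r2, gf2$r2)
})

test_that("turnover functions are monotone and anchored at zero", {
  co <- simulate_cohort(tiny_sim_config(n_sites = 1200, seed = 53))
  fr <- population_allele_freqs(filter_sites(co$geno, 0, 0), co$popmap)
  env <- as.matrix(co$env_pops)[rownames(fr), 1:6]
  gf <- fit_gradient_forest(fr[, 1:80], env, n_trees = 100, seed = 2)
  for (v in gf$variables) {
    f <- gf$cumulative[[v]]
    expect_true(all(diff(f) >= 0))
  }
  at_min <- transform_climate(gf, as.data.frame(t(gf$ranges[1, ])))
  expect_true(all(at_min == 0))
  beyond <- as.data.frame(t(gf$ranges[2, ] + 100))
  at_max <- transform_climate(gf, as.data.frame(t(gf$ranges[2, ])))
  expect_equal(transform_climate(gf, beyond), at_max)
})

test_that("transformation equals manual step-function lookup on a toy model", {
  m <- toy_turnover_model()
  x <- data.frame(T = c(0, 0.5, 1, 1.5, 2.7, 3, 99), P = c(0, 1, 1.2, 2, 2.5, -5, 3))
  got <- transform_climate(m, x)
  # bins [0,1), [1,2), [2,3]; F steps at upper edges
  expect_equal(got[, "T"], c(0, 0, 0.1, 0.1, 0.3, 0.6, 0.6))
  expect_equal(got[, "P"], c(0, 0.4, 0.4, 0.4, 0.4, 0, 0.5))
  expect_error(transform_climate(m, data.frame(T = 1)), "missing variable")
})

test_that("offsets vanish when the future equals the present", {
  m <- toy_turnover_model()
  grid <- data.frame(cell = 1:4, lat = c(24, 25, 26, 27), lon = 110:113,
                     T = c(0.5, 1.5, 2.5, 3), P = c(0.2, 1.1, 2.9, 0.4))
  om <- genomic_offset(m, grid, list(s1 = grid, s2 = grid))
  expect_true(all(om$offset_mean == 0))
})

test_that("offsets equal hand-computed norms and reduce to |dF| in one dimension", {
  m <- toy_turnover_model()
  cur <- data.frame(cell = 1:2, lat = c(24, 25), lon = c(110, 111),
                    T = c(0.5, 1.5), P = c(0.5, 0.5))
  fut <- cur
  fut$T <- c(2.5, 2.5)
  fut$P <- c(1.5, 2.5)
  om <- genomic_offset(m, cur, list(s = fut))
  # step lookups by hand: F_T(0.5)=0, F_T(1.5)=0.1, F_T(2.5)=0.3;
  #                       F_P(0.5)=0, F_P(1.5)=F_P(2.5)=0.4
  hand <- c(sqrt((0.3 - 0)^2 + (0.4 - 0)^2),
            sqrt((0.3 - 0.1)^2 + (0.4 - 0)^2))
  expect_equal(om$offset_s, hand, tolerance = 1e-12)
  # single-variable model: offset is |F(future) - F(current)|
  m1 <- m
  m1$variables <- "T"
  om1 <- genomic_offset(m1, cur, list(s = fut))
  expect_equal(om1$offset_s, c(0.3 - 0, 0.3 - 0.1))
  # mismatched cells error
  bad <- fut
  bad$cell <- c(9, 10)
  expect_error(genomic_offset(m, cur, list(s = bad)), "cell mismatch")
})

test_that("offsets obey the metric axioms on random climate triples", {
  co <- simulate_cohort(tiny_sim_config(n_sites = 1000, seed = 59))
  fr <- population_allele_freqs(filter_sites(co$geno, 0, 0), co$popmap)
  env <- as.matrix(co$env_pops)[rownames(fr), 1:5]
  gf <- fit_gradient_forest(fr[, 1:60], env, n_trees = 80, seed = 3)
  set.seed(60)
  dist_of <- function(a, b) {
    sqrt(sum((transform_climate(gf, a) - transform_climate(gf, b))^2))
  }
  for (k in 1:20) {
    pts <- lapply(1:3, function(i) {
      as.data.frame(t(gf$ranges[1, ] + runif(5) * (gf$ranges[2, ] - gf$ranges[1, ])))
    })
    dab <- dist_of(pts[[1]], pts[[2]])
    dba <- dist_of(pts[[2]], pts[[1]])
    dac <- dist_of(pts[[1]], pts[[3]])
    dcb <- dist_of(pts[[3]], pts[[2]])
    expect_gte(dab, 0)
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
    same <- dist_of(pts[[1]], pts[[1]])
    expect_equal(same, 0)
  }
})

test_that("population offsets equal brute-force radius filtering", {
  m <- toy_turnover_model()
  set.seed(61)
  grid <- expand.grid(lon = seq(109.5, 110.5, by = 0.05),
                      lat = seq(24.5, 25.5, by = 0.05))
  grid <- data.frame(cell = seq_len(nrow(grid)), lat = grid$lat, lon = grid$lon,
                     T = runif(nrow(grid), 0, 3), P = runif(nrow(grid), 0, 3))
  fut <- grid
  fut$T <- pmin(grid$T + 0.7, 3)
  om <- genomic_offset(m, grid, list(s = fut))
  pops <- data.frame(population = c("A", "B"), lat = c(25, 25.2),
                     lon = c(110, 110.4))
  po <- population_offset(om, pops, radius_km = 20)
  for (i in 1:2) {
    d <- geosphere::distHaversine(cbind(om$lon, om$lat),
                                  c(pops$lon[i], pops$lat[i]))
    expect_equal(po$offset[i], mean(om$offset_mean[d <= 20000]))
  }
  # uniform offset field gives back the uniform value
  om2 <- om
  om2$offset_mean <- 0.123
  expect_equal(unique(population_offset(om2, pops, 20)$offset), 0.123)
  expect_warning(population_offset(om, data.frame(population = "far", lat = 0,
                                                  lon = 0), 20), "no grid cell")
})

test_that("rda flags climate-driven loci and respects joint relabeling", {
  env <- env13(seed = 62, n_var = 4)
  set.seed(63)
  n_causal <- 40
  n_null <- 160
  causal <- vapply(seq_len(n_causal), function(i) {
    stats::plogis(2 * scale(env[, "V2"])[, 1] + rnorm(13, 0, 0.3))
  }, numeric(13))
  nulls <- matrix(runif(13 * n_null, 0.1, 0.9), 13)
  freqs <- cbind(causal, nulls)
  colnames(freqs) <- c(sprintf("causal%02d", seq_len(n_causal)),
                       sprintf("null%03d", seq_len(n_null)))
  rownames(freqs) <- rownames(env)
  res <- rda_adaptive_snps(freqs, env, n_axes = 3, n_perm = 499, seed = 64)
  power <- mean(sprintf("causal%02d", seq_len(n_causal)) %in% res$adaptive)
  expect_gte(power, 0.8)
  # jointly permuting population labels of both tables leaves the set unchanged
  perm <- sample(13)
  res2 <- rda_adaptive_snps(freqs[perm, ], env[perm, ], n_axes = 3,
                            n_perm = 499, seed = 64)
  expect_identical(sort(res$adaptive), sort(res2$adaptive))
})

test_that("rda rejects rank-deficient climate and too few populations", {
  env <- env13(seed = 65, n_var = 3)
  freqs <- matrix(runif(13 * 10), 13, dimnames = list(rownames(env), NULL))
  expect_error(rda_adaptive_snps(freqs, cbind(env, dup = env[, 1] * 2)),
               "collinear")
  expect_error(rda_adaptive_snps(freqs[1:4, ], env[1:4, ]), "at least")
})

test_that("rda agrees with an independent constrained-ordination implementation", {
  skip_if_not_installed("vegan")
  env <- env13(seed = 66, n_var = 3)
  set.seed(67)
  freqs <- matrix(runif(13 * 50, 0.05, 0.95), 13,
                  dimnames = list(rownames(env), paste0("L", 1:50)))
  x <- scale(env)
  q <- qr.Q(qr(x))
  yfit_mine <- q %*% crossprod(q, scale(freqs, center = TRUE, scale = FALSE))
  yfit_mine <- sweep(yfit_mine, 2, colMeans(freqs), "+")  # back to response scale
  mod <- vegan::rda(freqs ~ x)
  yfit_vegan <- stats::fitted(mod)
  attributes(yfit_vegan)[c("METHOD")] <- NULL
  expect_equal(unname(yfit_mine), unname(unclass(yfit_vegan)), tolerance = 1e-8)
})

test_that("neutral sampling is intergenic-only and seed-deterministic", {
  ann <- data.frame(chrom = "chr1", pos = 1:100,
                    class = rep(c("intergenic", "synonymous"), 50),
                    stringsAsFactors = FALSE)
  s1 <- sample_neutral_snps(ann, 20, seed = 3)
  s2 <- sample_neutral_snps(ann, 20, seed = 3)
  expect_identical(s1, s2)
  pos <- as.integer(sub("chr1:", "", s1))
  expect_true(all(ann$class[match(pos, ann$pos)] == "intergenic"))
  all50 <- sample_neutral_snps(ann, seed = 1)
  expect_length(all50, 50)
  expect_error(sample_neutral_snps(ann, 51), "intergenic loci available")
})
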