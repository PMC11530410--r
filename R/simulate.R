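# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analyses assume: two
# diverged lineages with unequal diversity, thirteen populations (five of
# them small range-edge demes with stronger drift), per-individual autozygous
# tracts, an annotated site spectrum whose derived-allele frequencies fall
# with deleteriousness, environmental clines driving designated adaptive
# loci, and matching current/future climate grids. Everything is driven by
# one seed; a fixed configuration reproduces the cohort bit-identically.

.default_pops <- function() {
  data.frame(
    population = c("LP", "LQ", "ML", "DH", "NP", "SX", "HY", "LY",
                   "ZJJ", "ES", "WZS", "TB", "PB"),
    lineage = c("West", "West", "West", "West", "East", "East", "East", "East",
                "West", "West", "West", "East", "East"),
    edge = c(rep(FALSE, 8), rep(TRUE, 5)),
    lat = c(25.5, 24.8, 26.3, 25.9, 26.5, 25.6, 24.9, 27.4,
            29.2, 30.3, 18.9, 27.3, 23.5),
    lon = c(107.5, 109.0, 108.2, 110.0, 113.8, 114.8, 112.9, 113.9,
            110.5, 109.4, 109.7, 118.1, 116.5),
    size = c(15, 15, 15, 14, 14, 14, 14, 13, 8, 8, 8, 8, 8),
    stringsAsFactors = FALSE
  )
}

.default_chroms <- function() {
  data.frame(chrom = paste0("chr", 1:8),
             length = c(45e6, 42e6, 40e6, 38e6, 36e6, 34e6, 33e6, 32e6))
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort. The
#' defaults reproduce the study design the package targets: 154 individuals
#' in 13 populations split into an East and a West lineage (five small edge
#' populations), a between-lineage divergence parameter of 0.35, lower
#' within-lineage diversity in the East (a bottleneck survival fraction),
#' stronger drift and a heavier autozygous-tract burden in edge populations,
#' a SYN/TOL/DEL/LOF/intergenic site mixture with derived-allele frequency
#' falling with deleteriousness, adaptive loci tied to an annual
#' mean-temperature cline, and a ~4.6-km climate grid with four future
#' scenarios of increasing displacement, larger toward the range margins.
#'
#' @param pops Data frame `population`, `lineage`, `edge`, `lat`, `lon`,
#'   `size`.
#' @param chrom_lengths Data frame `chrom`, `length` (bp).
#' @param n_sites Total SNP count.
#' @param fst_target Between-lineage divergence parameter in (0, 1).
#' @param fst_within_core,fst_within_edge Within-lineage drift parameter for
#'   core and edge populations.
#' @param lineage_bottleneck Named vector: per-lineage probability that an
#'   ancestrally polymorphic site was fixed lineage-wide (lowers that
#'   lineage's diversity).
#' @param class_mix Named proportions over
#'   `intergenic`/`SYN`/`TOL`/`DEL`/`LOF`; must sum to 1.
#' @param class_freq_means Mean derived-allele frequency priors per class.
#' @param roh_spec List: `rate_core`/`rate_edge` (mean tracts per
#'   individual) and `len_range_core`/`len_range_edge` (bp).
#' @param roh_tracts Optional explicit tracts (`sample` index or name,
#'   `chrom`, `start`, `length`) overriding `roh_spec`.
#' @param adaptive_spec List: `n_loci`, `slope`, `noise_sd`, `variable`.
#' @param grid List: `lon_range`, `lat_range`, `cell_deg` (default 1/24
#'   degree, about 4.6 km), `edge_gain` (extra future displacement toward
#'   range margins).
#' @param scenarios Named vector of future-scenario displacement multipliers.
#' @param missing_rate Per-genotype missingness probability (default 0).
#' @param seed Integer seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(pops = .default_pops(),
                       chrom_lengths = .default_chroms(),
                       n_sites = 50000,
                       fst_target = 0.35,
                       fst_within_core = 0.05,
                       fst_within_edge = 0.15,
                       lineage_bottleneck = c(West = 0, East = 0.25),
                       class_mix = c(intergenic = 0.50, SYN = 0.25, TOL = 0.15,
                                     DEL = 0.06, LOF = 0.04),
                       class_freq_means = c(intergenic = 0.25, SYN = 0.10,
                                            TOL = 0.05, DEL = 0.02, LOF = 0.02),
                       roh_spec = list(rate_core = 1, rate_edge = 4,
                                       len_range_core = c(2e5, 8e5),
                                       len_range_edge = c(3e5, 2e6)),
                       roh_tracts = NULL,
                       adaptive_spec = list(n_loci = 250, slope = 4,
                                            noise_sd = 0.05, variable = "BIO1"),
                       grid = list(lon_range = c(104, 120),
                                   lat_range = c(18, 31),
                                   cell_deg = 1 / 24, edge_gain = 1.2),
                       scenarios = c(ssp126 = 0.5, ssp245 = 1, ssp370 = 1.5,
                                     ssp585 = 2),
                       missing_rate = 0,
                       seed = 1L) {
  if (fst_target <= 0 || fst_target >= 1) stop("fst_target must lie in (0, 1)")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix proportions must sum to 1")
  if (n_sites < 1 || any(pops$size < 1) || any(chrom_lengths$length < 1)) {
    stop("all counts must be positive")
  }
  if (!all(pops$lineage %in% names(lineage_bottleneck))) {
    stop("lineage_bottleneck must name every lineage")
  }
  if (adaptive_spec$n_loci > n_sites) stop("adaptive loci exceed n_sites")
  structure(
    list(pops = pops, chrom_lengths = chrom_lengths, n_sites = n_sites,
         fst_target = fst_target, fst_within_core = fst_within_core,
         fst_within_edge = fst_within_edge,
         lineage_bottleneck = lineage_bottleneck, class_mix = class_mix,
         class_freq_means = class_freq_means, roh_spec = roh_spec,
         roh_tracts = roh_tracts, adaptive_spec = adaptive_spec, grid = grid,
         scenarios = scenarios, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Balding-Nichols population allele frequencies
#'
#' Draws per-population frequencies from a Beta distribution with mean
#' `p_anc` and variance `fst * p_anc * (1 - p_anc)` (shape parameters
#' `p (1-F)/F` and `(1-p)(1-F)/F`) - the standard model for allele
#' frequencies in populations that diverged from a common ancestor with
#' differentiation `F`.
#'
#' @param p_anc Ancestral frequency (vector over loci), strictly in (0, 1).
#' @param fst Divergence parameter, strictly in (0, 1).
#' @param n_pops Number of populations.
#' @return Matrix `n_pops` x `length(p_anc)` of frequencies.
#' @export
simulate_allele_freqs <- function(p_anc, fst, n_pops) {
  if (any(p_anc <= 0) || any(p_anc >= 1)) stop("p_anc must lie strictly in (0, 1)")
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly in (0, 1); degenerate values rejected")
  k <- (1 - fst) / fst
  n_loci <- length(p_anc)
  m <- matrix(stats::rbeta(n_pops * n_loci, rep(p_anc * k, each = n_pops),
                           rep((1 - p_anc) * k, each = n_pops)),
              nrow = n_pops)
  m
}

.latent_fields <- function(lon, lat) {
  list(
    T = 22 - 0.60 * (lat - 24) - 0.15 * (lon - 112) + 0.8 * sin(0.5 * lon),
    P = 1500 + 40 * (lon - 112) - 25 * (lat - 24) + 120 * sin(0.7 * lat),
    S = 60 + 8 * sin(0.9 * lon + 0.6 * lat) + 0.5 * (lat - 24)
  )
}

# loading table: variable -> (latent, intercept, scale, wiggle amp, phase)
.bioclim_spec <- function() {
  data.frame(
    variable = paste0("BIO", 1:19),
    latent = c("T", "T", "S", "S", "T", "T", "T", "T", "T", "T",
               "T", "P", "P", "P", "S", "P", "P", "P", "P"),
    intercept = c(0, -8, 30, 600, 8, -10, 18, 2, -3, 6,
                  -5, 0, 150, -900, 0, 300, -800, 100, -600),
    scale = c(1, 0.25, 0.4, 9, 1.1, 0.9, 0.35, 0.95, 1.05, 1.0,
              0.85, 1, 0.22, 0.65, 1, 0.55, 0.6, 0.3, 0.45),
    wiggle = c(0.3, 1.4, 2.2, 28, 0.6, 1.1, 1.6, 0.8, 0.9, 0.4,
               1.2, 35, 24, 38, 5.5, 40, 42, 65, 48),
    phase = seq(0.3, 5.7, length.out = 19),
    freq_lon = c(0.8, 1.7, 2.6, 1.2, 0.5, 2.1, 1.4, 0.9, 3.0, 0.6,
                 1.9, 0.7, 2.4, 1.1, 2.8, 1.6, 0.4, 2.2, 1.3),
    freq_lat = c(1.1, 0.6, 1.8, 2.3, 1.5, 0.8, 2.7, 1.9, 0.5, 2.5,
                 1.2, 1.7, 0.9, 2.9, 1.4, 0.7, 2.1, 1.0, 2.6),
    stringsAsFactors = FALSE
  )
}

.climate_values <- function(lon, lat, shift_scale = 0, edge_gain = 0,
                            lon_range = NULL, lat_range = NULL) {
  lf <- .latent_fields(lon, lat)
  if (shift_scale > 0) {
    ctr <- c(mean(lon_range), mean(lat_range))
    d <- pmax(abs(lon - ctr[1]) / (diff(lon_range) / 2),
              abs(lat - ctr[2]) / (diff(lat_range) / 2))
    gain <- shift_scale * (1 + edge_gain * d)
    lf$T <- lf$T + 1.6 * gain
    lf$P <- lf$P - 120 * gain
    lf$S <- lf$S + 3 * gain
  }
  sp <- .bioclim_spec()
  out <- matrix(0, nrow = length(lon), ncol = nrow(sp),
                dimnames = list(NULL, sp$variable))
  for (i in seq_len(nrow(sp))) {
    out[, i] <- sp$intercept[i] + sp$scale[i] * lf[[sp$latent[i]]] +
      sp$wiggle[i] * sin(sp$phase[i] + sp$freq_lon[i] * lon + sp$freq_lat[i] * lat)
  }
  out
}

.climate_grid <- function(grid, shift_scale = 0) {
  lon <- seq(grid$lon_range[1] + grid$cell_deg / 2, grid$lon_range[2],
             by = grid$cell_deg)
  lat <- seq(grid$lat_range[1] + grid$cell_deg / 2, grid$lat_range[2],
             by = grid$cell_deg)
  cells <- expand.grid(lon = lon, lat = lat)
  vals <- .climate_values(cells$lon, cells$lat, shift_scale,
                          grid$edge_gain, grid$lon_range, grid$lat_range)
  cbind(data.frame(cell = seq_len(nrow(cells)), lon = cells$lon,
                   lat = cells$lat), as.data.frame(vals))
}

.beta_from_mean <- function(n, mean, conc = 2) {
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Simulate a full cohort
#'
#' Draws genotypes under a hierarchical Balding-Nichols model (ancestral
#' frequency, lineage draw at `fst_target` with optional lineage-wide
#' bottleneck fixation, population draw at the core/edge drift parameter),
#' assigns effect classes with deleteriousness-coupled frequency priors,
#' overwrites designated autozygous tracts as homozygous runs, ties adaptive
#' loci to a logistic function of the driving climate variable, and attaches
#' the matching climate tables and a complete ground-truth record.
#' Deterministic for a fixed configuration.
#'
#' @param config A [sim_config()].
#' @return List of class `cohort`: `geno` (a `genotype_matrix`),
#'   `annotations`, `popmap`, `pops`, `chrom_sizes`, `env_pops`,
#'   `climate_current`, `climate_future` (named list), `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- config$pops
  n_pop <- nrow(pops)
  n_ind <- sum(pops$size)
  n_sites <- config$n_sites

  # --- sites ---------------------------------------------------------------
  chroms <- config$chrom_lengths
  n_per <- floor(n_sites * chroms$length / sum(chroms$length))
  n_per[1] <- n_per[1] + n_sites - sum(n_per)
  site_chrom <- rep(chroms$chrom, n_per)
  site_pos <- unlist(lapply(seq_len(nrow(chroms)), function(i) {
    sort(sample.int(chroms$length[i], n_per[i]))
  }))
  classes <- sample(names(config$class_mix), n_sites, replace = TRUE,
                    prob = config$class_mix)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))

  # --- hierarchical frequencies --------------------------------------------
  p_anc <- numeric(n_sites)
  for (cl in names(config$class_freq_means)) {
    sel <- classes == cl
    p_anc[sel] <- .beta_from_mean(sum(sel), config$class_freq_means[[cl]])
  }
  p_anc <- pmin(pmax(p_anc, 0.01), 0.99)
  lineages <- unique(pops$lineage)
  p_lin <- matrix(0, nrow = length(lineages), ncol = n_sites,
                  dimnames = list(lineages, NULL))
  for (l in lineages) {
    p <- simulate_allele_freqs(p_anc, config$fst_target, 1)[1, ]
    fix <- stats::runif(n_sites) < config$lineage_bottleneck[[l]]
    if (any(fix)) p[fix] <- stats::rbinom(sum(fix), 1, p[fix])
    p_lin[l, ] <- p
  }
  fst_pop <- ifelse(pops$edge, config$fst_within_edge, config$fst_within_core)
  p_pop <- matrix(0, nrow = n_pop, ncol = n_sites,
                  dimnames = list(pops$population, NULL))
  for (i in seq_len(n_pop)) {
    pl <- pmin(pmax(p_lin[pops$lineage[i], ], 1e-6), 1 - 1e-6)
    p_pop[i, ] <- simulate_allele_freqs(pl, fst_pop[i], 1)[1, ]
  }

  # --- climate + adaptive clines -------------------------------------------
  env_pops <- .climate_values(pops$lon, pops$lat)
  rownames(env_pops) <- pops$population
  adp <- config$adaptive_spec
  pool <- which(classes %in% c("intergenic", "SYN"))
  if (adp$n_loci > length(pool)) stop("adaptive loci exceed available neutral sites")
  adaptive_idx <- sort(sample(pool, adp$n_loci))
  z <- as.numeric(scale(env_pops[, adp$variable]))
  p_adp <- stats::plogis(adp$slope * z)          # per population
  cline <- matrix(rep(p_adp, length(adaptive_idx)), nrow = n_pop) +
    stats::rnorm(n_pop * length(adaptive_idx), 0, adp$noise_sd)
  p_pop[, adaptive_idx] <- pmin(pmax(cline, 0.01), 0.99)

  # --- genotypes ------------------------------------------------------------
  sample_pop <- rep(pops$population, pops$size)
  samples <- unlist(lapply(seq_len(n_pop), function(i) {
    sprintf("%s_%02d", pops$population[i], seq_len(pops$size[i]))
  }))
  g <- matrix(0L, nrow = n_ind, ncol = n_sites, dimnames = list(samples, NULL))
  for (i in seq_len(n_pop)) {
    rows <- which(sample_pop == pops$population[i])
    g[rows, ] <- matrix(stats::rbinom(length(rows) * n_sites, 2,
                                      rep(p_pop[i, ], each = length(rows))),
                        nrow = length(rows))
  }

  # --- autozygous tracts ----------------------------------------------------
  tracts <- config$roh_tracts
  if (is.null(tracts)) {
    rate <- ifelse(pops$edge[match(sample_pop, pops$population)],
                   config$roh_spec$rate_edge, config$roh_spec$rate_core)
    n_tr <- stats::rpois(n_ind, rate)
    tracts <- do.call(rbind, lapply(which(n_tr > 0), function(i) {
      rng <- if (pops$edge[match(sample_pop[i], pops$population)]) {
        config$roh_spec$len_range_edge
      } else config$roh_spec$len_range_core
      len <- round(stats::runif(n_tr[i], rng[1], rng[2]))
      ci <- sample.int(nrow(chroms), n_tr[i], prob = chroms$length, replace = TRUE)
      len <- pmin(len, chroms$length[ci])
      start <- vapply(seq_len(n_tr[i]), function(k) {
        sample.int(as.integer(chroms$length[ci[k]] - len[k] + 1), 1)
      }, integer(1))
      data.frame(sample = samples[i], chrom = chroms$chrom[ci], start = start,
                 length = len, stringsAsFactors = FALSE)
    }))
    if (is.null(tracts)) {
      tracts <- data.frame(sample = character(), chrom = character(),
                           start = integer(), length = integer())
    }
  } else {
    if (is.numeric(tracts$sample)) tracts$sample <- samples[tracts$sample]
    clen <- chroms$length[match(tracts$chrom, chroms$chrom)]
    if (any(is.na(clen)) || any(tracts$start + tracts$length - 1 > clen)) {
      stop("autozygous tract exceeds its chromosome")
    }
  }
  if (nrow(tracts)) {
    for (k in seq_len(nrow(tracts))) {
      j <- which(site_chrom == tracts$chrom[k] & site_pos >= tracts$start[k] &
                   site_pos <= tracts$start[k] + tracts$length[k] - 1)
      if (!length(j)) next
      pi_row <- match(sample_pop[match(tracts$sample[k], samples)], pops$population)
      g[tracts$sample[k], j] <- 2L * stats::rbinom(length(j), 1, p_pop[pi_row, j])
    }
    tracts$end <- tracts$start + tracts$length - 1L
  }

  # --- missingness ----------------------------------------------------------
  if (config$missing_rate > 0) {
    g[stats::runif(length(g)) < config$missing_rate] <- NA_integer_
  }

  # --- annotations ----------------------------------------------------------
  gm_mat <- grantham_matrix()
  pairs <- which(upper.tri(gm_mat), arr.ind = TRUE)
  gs <- gm_mat[pairs]
  tol_pool <- pairs[gs >= 5 & gs <= 150, , drop = FALSE]
  del_pool <- pairs[gs > 150, , drop = FALSE]
  effect <- character(n_sites)
  aa_ref <- aa_alt <- rep(NA_character_, n_sites)
  effect[classes == "intergenic"] <- "intergenic_region"
  effect[classes == "SYN"] <- "synonymous_variant"
  lof_terms <- c("stop_gained", "splice_acceptor_variant", "splice_donor_variant")
  effect[classes == "LOF"] <- sample(lof_terms, sum(classes == "LOF"),
                                     replace = TRUE)
  for (cl in c("TOL", "DEL")) {
    sel <- which(classes == cl)
    if (!length(sel)) next
    pool_cl <- if (cl == "TOL") tol_pool else del_pool
    pick <- pool_cl[sample.int(nrow(pool_cl), length(sel), replace = TRUE), ,
                    drop = FALSE]
    effect[sel] <- "missense_variant"
    aa_ref[sel] <- rownames(gm_mat)[pick[, 1]]
    aa_alt[sel] <- colnames(gm_mat)[pick[, 2]]
  }

  annotations <- data.frame(chrom = site_chrom, pos = site_pos, effect = effect,
                            aa_ref = aa_ref, aa_alt = aa_alt,
                            stringsAsFactors = FALSE)
  geno <- genotype_matrix(g, data.frame(chrom = site_chrom, pos = site_pos,
                                        ref = ref, alt = alt,
                                        stringsAsFactors = FALSE),
                          samples = samples)
  popmap <- data.frame(sample = samples, population = sample_pop,
                       lat = pops$lat[match(sample_pop, pops$population)],
                       lon = pops$lon[match(sample_pop, pops$population)],
                       stringsAsFactors = FALSE)
  climate_future <- lapply(config$scenarios, function(s) {
    .climate_grid(config$grid, shift_scale = s)
  })
  truth <- list(
    ancestral = ref, class = classes,
    adaptive = seq_len(n_sites) %in% adaptive_idx,
    roh_tracts = tracts, pop_freqs = p_pop, lineage_freqs = p_lin,
    driving_variable = adp$variable, env_pops = env_pops
  )
  structure(
    list(geno = geno, annotations = annotations, popmap = popmap, pops = pops,
         chrom_sizes = chroms, env_pops = as.data.frame(env_pops),
         climate_current = .climate_grid(config$grid),
         climate_future = climate_future, truth = truth, config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d individuals / %d populations, %d sites, %d scenario(s)\n",
              n_samples(x$geno), nrow(x$pops), n_sites(x$geno),
              length(x$climate_future)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits the standard file set: a multi-sample VCF (contig headers matching
#' the chromosome-sizes table), annotation TSV, population map TSV,
#' chromosome sizes TSV, per-population climate TSV, and one gridded climate
#' TSV for the current period plus one per future scenario. The VCF
#' round-trips through [read_vcf_genotypes()] to an identical genotype
#' matrix.
#'
#' @param cohort A `cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (n_sites(cohort$geno) == 0L || n_samples(cohort$geno) == 0L) {
    stop("refusing to write an empty cohort")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    annotations = file.path(out_dir, "annotations.tsv"),
    popmap = file.path(out_dir, "popmap.tsv"),
    chrom_sizes = file.path(out_dir, "chrom_sizes.tsv"),
    env_pops = file.path(out_dir, "climate_populations.tsv"),
    climate_current = file.path(out_dir, "climate_current.tsv")
  )
  write_vcf(cohort$geno, paths["vcf"], chrom_sizes = cohort$chrom_sizes)
  data.table::fwrite(cohort$annotations, paths["annotations"], sep = "\t")
  data.table::fwrite(cohort$popmap, paths["popmap"], sep = "\t")
  data.table::fwrite(cohort$chrom_sizes, paths["chrom_sizes"], sep = "\t")
  env <- cbind(population = rownames(cohort$env_pops), cohort$env_pops)
  data.table::fwrite(env, paths["env_pops"], sep = "\t")
  data.table::fwrite(cohort$climate_current, paths["climate_current"], sep = "\t")
  for (s in names(cohort$climate_future)) {
    p <- file.path(out_dir, sprintf("climate_future_%s.tsv", s))
    data.table::fwrite(cohort$climate_future[[s]], p, sep = "\t")
    paths[paste0("climate_", s)] <- p
  }
  invisible(paths)
}

#' Read a cohort file set
#'
#' @param dir Directory previously populated by [write_cohort()].
#' @return A list with `geno`, `annotations`, `popmap`, `chrom_sizes`,
#'   `env_pops`, `climate_current`, `climate_future`.
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("cohort.vcf", "annotations.tsv", "popmap.tsv",
                           "chrom_sizes.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing cohort file(s): ", paste(miss, collapse = ", "))
  fut_files <- list.files(dir, pattern = "^climate_future_.*\\.tsv$",
                          full.names = TRUE)
  fut <- lapply(fut_files, data.table::fread, data.table = FALSE)
  names(fut) <- sub("^climate_future_(.*)\\.tsv$", "\\1", basename(fut_files))
  env_path <- file.path(dir, "climate_populations.tsv")
  cur_path <- file.path(dir, "climate_current.tsv")
  list(
    geno = read_vcf_genotypes(file.path(dir, "cohort.vcf")),
    annotations = data.table::fread(file.path(dir, "annotations.tsv"),
                                    data.table = FALSE),
    popmap = data.table::fread(file.path(dir, "popmap.tsv"), data.table = FALSE),
    chrom_sizes = data.table::fread(file.path(dir, "chrom_sizes.tsv"),
                                    data.table = FALSE),
    env_pops = if (file.exists(env_path)) {
      e <- data.table::fread(env_path, data.table = FALSE)
      rownames(e) <- e$population
      e[, -1, drop = FALSE]
    },
    climate_current = if (file.exists(cur_path)) {
      data.table::fread(cur_path, data.table = FALSE)
    },
    climate_future = fut
  )
}

#' Neutral single-population windows for sampling-theory checks
#'
#' Generates windows of segregating sites whose derived-allele counts follow
#' the neutral equilibrium frequency spectrum (probability proportional to
#' 1/k for k derived copies among the 2N haplotypes), with the derived
#' copies assigned to haplotypes uniformly at random and haplotypes paired
#' into diploids. Under this spectrum the expected difference between
#' pairwise diversity and Watterson's estimator is zero, so windowed
#' Tajima's D should average zero.
#'
#' @param n_windows Number of windows.
#' @param n_dip Diploid individuals per window.
#' @param mean_s Mean segregating sites per window (Poisson, floored at 3).
#' @param seed Integer seed.
#' @return List of genotype matrices (`n_dip` rows).
#' @export
simulate_neutral_windows <- function(n_windows, n_dip = 10, mean_s = 12,
                                     seed = 1) {
  set.seed(seed)
  n_hap <- 2L * n_dip
  kprob <- 1 / seq_len(n_hap - 1)
  odd <- seq(1L, n_hap, by = 2L)
  lapply(seq_len(n_windows), function(w) {
    s <- max(3L, stats::rpois(1, mean_s))
    k <- sample.int(n_hap - 1L, s, replace = TRUE, prob = kprob)
    haps <- matrix(0L, nrow = n_hap, ncol = s)
    for (j in seq_len(s)) haps[sample.int(n_hap, k[j]), j] <- 1L
    haps[odd, , drop = FALSE] + haps[odd + 1L, , drop = FALSE]
  })
}
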