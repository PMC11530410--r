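# Small simulation configurations used across tests: two short chromosomes
# and a coarse climate grid keep cohort generation around a tenth of a
# second while preserving the full two-lineage, 13-population structure.

tiny_sim_config <- function(n_sites = 2000, seed = 11, ...) {
  args <- utils::modifyList(list(
    n_sites = n_sites,
    chrom_lengths = data.frame(chrom = c("chr1", "chr2"),
                               length = c(2e6, 1.5e6)),
    grid = list(lon_range = c(104, 120), lat_range = c(18, 31),
                cell_deg = 0.5, edge_gain = 1.2),
    adaptive_spec = list(n_loci = 60, slope = 4, noise_sd = 0.05,
                         variable = "BIO1"),
    seed = seed
  ), list(...))
  do.call(sim_config, args)
}

# one dense individual chromosome with optional injected homozygous tracts
dense_gm <- function(n_sites = 1600, chrom_len = 2e5, p_het = 0.45, seed = 1,
                     tracts = NULL, chrom = "chr1") {
  set.seed(seed)
  pos <- sort(sample.int(chrom_len, n_sites))
  g <- ifelse(runif(n_sites) < p_het, 1L,
              ifelse(runif(n_sites) < 0.5, 0L, 2L))
  if (!is.null(tracts)) {
    for (k in seq_len(nrow(tracts))) {
      j <- pos >= tracts$start[k] & pos <= tracts$end[k]
      g[j] <- ifelse(runif(sum(j)) < 0.5, 0L, 2L)
    }
  }
  genotype_matrix(matrix(g, nrow = 1),
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T"),
                  samples = "ind1")
}

# hand-built two-variable turnover model with known step functions
toy_turnover_model <- function() {
  structure(list(
    variables = c("T", "P"),
    ranges = matrix(c(0, 3, 0, 3), nrow = 2, dimnames = list(NULL, c("T", "P"))),
    edges = list(T = c(0, 1, 2, 3), P = c(0, 1, 2, 3)),
    bin_importance = list(T = c(0.1, 0.2, 0.3), P = c(0.4, 0, 0.1)),
    cumulative = list(T = cumsum(c(0.1, 0.2, 0.3)), P = cumsum(c(0.4, 0, 0.1))),
    importance = c(T = 0.6, P = 0.5),
    r2 = numeric(0), n_trees = 0L, n_bins = 3L, mtry = 1L,
    min_split = 5L, seed = 0L
  ), class = "turnover_model")
}
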