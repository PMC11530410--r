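# Windowed diversity/divergence statistics with missing-data-aware
# denominators, in the pixy style: every statistic is a ratio of window sums
# of per-site numerators and denominators over the alleles actually called,
# never a mean of per-site ratios.

#' Nucleotide diversity over a set of sites
#'
#' pi = sum_sites(c_ref * c_alt) / sum_sites C(n_site, 2), with c the
#' non-missing allele counts at each site and n_site their total. Sites with
#' fewer than two called alleles contribute to neither sum; an entirely
#' missing site therefore changes nothing.
#'
#' @param g A `genotype_matrix` or dosage matrix (samples x sites) already
#'   restricted to the window and population of interest.
#' @return Diversity per genotyped site, or `NA` when no site is usable.
#' @export
nuc_diversity <- function(g) {
  ac <- allele_counts(g)
  use <- ac$n_called >= 2L
  if (!any(use)) return(NA_real_)
  num <- sum(as.numeric(ac$n_ref[use]) * ac$n_alt[use])
  den <- sum(choose(as.numeric(ac$n_called[use]), 2))
  num / den
}

#' Absolute divergence DXY between two populations
#'
#' DXY = sum_sites(cA_ref * cB_alt + cA_alt * cB_ref) /
#' sum_sites(nA_site * nB_site) over sites called in both populations.
#'
#' @param ga,gb Genotype matrices (or dosage matrices) for the two
#'   populations over the same sites.
#' @return Divergence per genotyped site, or `NA` when undefined.
#' @export
nuc_divergence <- function(ga, gb) {
  a <- allele_counts(ga)
  b <- allele_counts(gb)
  use <- a$n_called >= 1L & b$n_called >= 1L
  if (!any(use)) return(NA_real_)
  num <- sum(as.numeric(a$n_ref[use]) * b$n_alt[use] +
             as.numeric(a$n_alt[use]) * b$n_ref[use])
  den <- sum(as.numeric(a$n_called[use]) * b$n_called[use])
  num / den
}

#' Hudson's FST between two populations (ratio of sums)
#'
#' FST = 1 - mean(within-population heterozygosity sums) / between-population
#' sum, where the within terms are the unbiased per-site heterozygosities
#' c_ref*c_alt / C(n,2) and the between term is the per-site DXY numerator
#' over nA*nB. Computed as a ratio of window sums, so single-site noise does
#' not dominate; the estimate may be slightly negative and is reported as
#' computed.
#'
#' @inheritParams nuc_divergence
#' @return FST, or `NA` when the between-population denominator is zero.
#' @export
hudson_fst <- function(ga, gb) {
  a <- allele_counts(ga)
  b <- allele_counts(gb)
  use <- a$n_called >= 2L & b$n_called >= 2L
  if (!any(use)) return(NA_real_)
  hw_a <- sum(as.numeric(a$n_ref[use]) * a$n_alt[use] /
                choose(as.numeric(a$n_called[use]), 2))
  hw_b <- sum(as.numeric(b$n_ref[use]) * b$n_alt[use] /
                choose(as.numeric(b$n_called[use]), 2))
  hb <- sum((as.numeric(a$n_ref[use]) * b$n_alt[use] +
             as.numeric(a$n_alt[use]) * b$n_ref[use]) /
              (as.numeric(a$n_called[use]) * b$n_called[use]))
  if (hb == 0) return(NA_real_)
  1 - mean(c(hw_a, hw_b)) / hb
}

#' Tajima's D over a window
#'
#' Standard Tajima (1989) D = (pi_hat - S/a1) / sqrt(e1 S + e2 S (S-1)), with
#' the constants computed from the haplotype count n = 2 x diploids. Sites
#' with any missing genotype are excluded before counting segregating sites
#' (so that a single n applies to the whole window); fewer than three
#' segregating sites yields an explicit undefined marker.
#'
#' @param g Genotype matrix (samples x sites) for one population/window.
#' @return Tajima's D, or `NA` when `S < 3`.
#' @export
tajimas_d <- function(g) {
  if (inherits(g, "genotype_matrix")) g <- g$genotypes
  complete <- colSums(is.na(g)) == 0L
  g <- g[, complete, drop = FALSE]
  n <- 2L * nrow(g)
  if (n < 4L || ncol(g) == 0L) return(NA_real_)
  n_alt <- colSums(g)
  seg <- n_alt > 0L & n_alt < n
  s <- sum(seg)
  if (s < 3L) return(NA_real_)
  k <- as.numeric(n_alt[seg])
  pi_hat <- sum(k * (n - k)) / choose(n, 2)
  tj <- tajima_constants(n)
  theta_w <- s / tj$a1
  (pi_hat - theta_w) / sqrt(tj$e1 * s + tj$e2 * s * (s - 1))
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' One-sided standard normal significance cutoff
#'
#' The selection-scan threshold: the standard normal inverse CDF at the given
#' one-sided confidence level, rounded to four decimals for reporting (0.99
#' gives 2.3263, the cutoff applied to the normalized composite-likelihood
#' statistic in the scan this package accompanies).
#'
#' @param confidence One-sided probability in (0, 1).
#' @return The quantile, rounded to 4 decimals.
#' @export
normal_cutoff <- function(confidence) {
  if (!is.numeric(confidence) || any(confidence <= 0) || any(confidence >= 1)) {
    stop("confidence must lie strictly between 0 and 1")
  }
  round(stats::qnorm(confidence), 4)
}

#' Spearman correlation between two per-window statistics
#'
#' Mid-ranks for ties, Pearson correlation of the ranks, and a two-sided
#' p-value from the t approximation with n - 2 degrees of freedom. Windows
#' where either statistic is undefined are dropped pairwise.
#'
#' @param stat_a,stat_b Numeric vectors of per-window values.
#' @return A list with `estimate`, `p.value` and `n` (pairs used).
#' @export
landscape_correlation <- function(stat_a, stat_b) {
  ok <- is.finite(stat_a) & is.finite(stat_b)
  x <- stat_a[ok]
  y <- stat_b[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired windows")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined")
    return(list(estimate = NA_real_, p.value = NA_real_, n = n))
  }
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(estimate = r, p.value = p, n = n)
}

window_grid <- function(chrom_sizes, window_size) {
  out <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    len <- chrom_sizes$length[i]
    start <- seq(1, len, by = window_size)
    data.frame(chrom = chrom_sizes$chrom[i], start = start,
               end = pmin(start + window_size - 1, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Windowed diversity and divergence statistics
#'
#' Cuts each chromosome into non-overlapping windows anchored at position 1
#' (trailing partial windows keep their true span) and computes per-window
#' nucleotide diversity for each population and, when `lineages` maps
#' populations to two groups, DXY, Hudson's FST and per-lineage Tajima's D
#' between/within the pooled lineages. Undefined statistics are reported as
#' `NA`, never silently as zero.
#'
#' @param gm A `genotype_matrix`.
#' @param popmap Data frame with columns `sample`, `population`.
#' @param chrom_sizes Data frame with columns `chrom`, `length`; defaults to
#'   the span of the observed sites.
#' @param window_size Window length in bp (default 100 kb).
#' @param lineages Optional named character vector population -> lineage
#'   label (exactly two labels) enabling between-lineage statistics.
#' @param lineage_sample_n Optional equal per-lineage subsample size used for
#'   lineage-level diversity (a sample-size correction; individuals are taken
#'   deterministically in popmap order).
#' @return Data frame: `chrom`, `start`, `end`, `stat`, `unit`, `value`,
#'   `n_sites_used`.
#' @export
windowed_stats <- function(gm, popmap, chrom_sizes = NULL, window_size = 1e5,
                           lineages = NULL, lineage_sample_n = NULL) {
  if (is.null(chrom_sizes)) {
    chrom_sizes <- do.call(rbind, lapply(split(gm$sites, gm$sites$chrom), function(s) {
      data.frame(chrom = s$chrom[1], length = max(s$pos))
    }))
  }
  wins <- window_grid(chrom_sizes, window_size)
  pops <- split(match(popmap$sample, gm$samples), popmap$population)
  lin_rows <- NULL
  if (!is.null(lineages)) {
    labs <- unique(lineages)
    if (length(labs) != 2L) stop("lineages must define exactly two groups")
    lin_rows <- lapply(labs, function(l) {
      members <- popmap$sample[popmap$population %in% names(lineages)[lineages == l]]
      idx <- match(members, gm$samples)
      if (!is.null(lineage_sample_n)) idx <- idx[seq_len(min(lineage_sample_n, length(idx)))]
      idx
    })
    names(lin_rows) <- labs
  }
  g <- gm$genotypes
  site_chrom <- gm$sites$chrom
  site_pos <- gm$sites$pos
  res <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    j <- which(site_chrom == wins$chrom[w] & site_pos >= wins$start[w] &
                 site_pos <= wins$end[w])
    rows <- list()
    for (p in names(pops)) {
      gp <- g[pops[[p]], j, drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        stat = "pi", unit = p, value = nuc_diversity(gp),
        n_sites_used = length(j))
    }
    if (!is.null(lin_rows)) {
      ga <- g[lin_rows[[1]], j, drop = FALSE]
      gb <- g[lin_rows[[2]], j, drop = FALSE]
      pair <- paste(names(lin_rows), collapse = "-")
      rows[[length(rows) + 1L]] <- data.frame(
        stat = c("pi", "pi", "dxy", "fst", "tajima_d", "tajima_d"),
        unit = c(names(lin_rows), pair, pair, names(lin_rows)),
        value = c(nuc_diversity(ga), nuc_diversity(gb),
                  nuc_divergence(ga, gb), hudson_fst(ga, gb),
                  tajimas_d(ga), tajimas_d(gb)),
        n_sites_used = length(j))
    }
    out <- do.call(rbind, rows)
    out$chrom <- wins$chrom[w]
    out$start <- wins$start[w]
    out$end <- wins$end[w]
    res[[w]] <- out
  }
  out <- do.call(rbind, res)
  out[, c("chrom", "start", "end", "stat", "unit", "value", "n_sites_used")]
}
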