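# Runs of homozygosity and individual inbreeding coefficients.

.roh_class <- function(length_bp) {
  cut(length_bp, breaks = c(1e4, 1e5, 2e5, Inf), right = FALSE,
      labels = c("short", "medium", "long"))
}

#' Detect runs of homozygosity
#'
#' Scans each individual and chromosome for maximal runs of consecutive
#' non-heterozygous genotyped SNPs supported by sliding windows of
#' `window_snps` genotyped sites containing at most `max_het` heterozygotes
#' (default zero, the "50-SNP window excluding heterozygous loci" rule).
#' Missing genotypes are tolerated inside a run - they neither break it nor
#' count toward its SNP support - and runs are broken where consecutive
#' genotyped SNPs are further apart than `max_gap_bp`. Segments shorter than
#' `min_length_bp` (default 10 kb) or supported by fewer than `min_snps`
#' SNPs are discarded; survivors are classed as short (10-100 kb), medium
#' (100-200 kb) or long (>= 200 kb).
#'
#' @param gm A `genotype_matrix` (sites position-sorted; enforced by the
#'   container).
#' @param samples Samples to scan (default all).
#' @param window_snps Sliding window size in genotyped SNPs (default 50).
#' @param max_het Heterozygous calls allowed per window (default 0).
#' @param min_length_bp Minimum segment length in bp (default 1e4).
#' @param min_snps Minimum genotyped SNPs per segment (default 50).
#' @param max_gap_bp Maximum gap between consecutive genotyped SNPs within a
#'   run (default 1e6).
#' @return Data frame: `sample`, `chrom`, `start`, `end` (bp, 1-based
#'   inclusive), `n_snps`, `length`, `class`.
#' @export
detect_roh <- function(gm, samples = gm$samples, window_snps = 50, max_het = 0,
                       min_length_bp = 1e4, min_snps = 50, max_gap_bp = 1e6) {
  by_chrom <- split(seq_len(n_sites(gm)), gm$sites$chrom)
  segs <- list()
  for (chrom_idx in by_chrom) {
    pos_all <- gm$sites$pos[chrom_idx]
    if (is.unsorted(pos_all, strictly = TRUE)) stop("sites are not position-sorted")
    chrom <- gm$sites$chrom[chrom_idx[1]]
    for (s in samples) {
      g <- gm$genotypes[s, chrom_idx]
      called <- !is.na(g)
      if (!any(called)) next
      gg <- g[called]
      pos <- pos_all[called]
      segs[[length(segs) + 1L]] <-
        .roh_scan_one(gg, pos, s, chrom, window_snps, max_het,
                      min_length_bp, min_snps, max_gap_bp)
    }
  }
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), n_snps = integer(),
                      length = integer(), class = factor(character(),
                      levels = c("short", "medium", "long")))
  }
  rownames(out) <- NULL
  out
}

# One individual, one chromosome; gg/pos contain genotyped sites only.
.roh_scan_one <- function(gg, pos, sample, chrom, window_snps, max_het,
                          min_length_bp, min_snps, max_gap_bp) {
  n <- length(gg)
  if (n == 0L) return(NULL)
  het <- gg == 1L
  # window support: a genotyped site is supported if some window of
  # window_snps consecutive genotyped sites covering it has <= max_het hets
  if (n >= window_snps) {
    wsum <- as.numeric(stats::filter(het, rep(1, window_snps), sides = 1))
    wsum <- wsum[window_snps:n]              # window ending at i covers i-w+1..i
    ok_win <- wsum <= max_het                # one flag per window start
    supported <- logical(n)
    # site i supported iff min over windows covering i; take running
    # min via cummax trick on ok flags: mark all sites covered by an ok window
    ok_starts <- which(ok_win)
    for (st in ok_starts) supported[st:(st + window_snps - 1L)] <- TRUE
  } else {
    supported <- logical(n)
  }
  eligible <- supported & !het
  if (!any(eligible)) return(NULL)
  # break runs at large gaps between consecutive genotyped sites
  gap_break <- c(FALSE, diff(pos) > max_gap_bp)
  run_id <- cumsum(!eligible | gap_break)
  runs <- split(which(eligible), run_id[eligible])
  out <- lapply(runs, function(ii) {
    if (length(ii) < min_snps) return(NULL)
    start <- pos[ii[1]]
    end <- pos[ii[length(ii)]]
    len <- end - start + 1L
    if (len < min_length_bp) return(NULL)
    data.frame(sample = sample, chrom = chrom, start = start, end = end,
               n_snps = length(ii), length = len,
               class = .roh_class(len), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genomic inbreeding coefficient from ROH
#'
#' F_ROH: the cumulative length of an individual's ROH segments divided by
#' the total genome length (sum of the chromosome-sizes entries, not the
#' SNP-covered span).
#'
#' @param segments ROH data frame as returned by [detect_roh()] (one
#'   individual's rows, or any subset to be summed).
#' @param genome_length Total genome length in bp.
#' @return The genome fraction in ROH.
#' @export
f_roh <- function(segments, genome_length) {
  if (genome_length <= 0) stop("genome length must be positive")
  if (is.null(segments) || nrow(segments) == 0L) return(0)
  sum(as.numeric(segments$length)) / genome_length
}

#' Per-sample F_ROH table
#'
#' @param segments ROH data frame for a cohort.
#' @param genome_length Total genome length in bp.
#' @param samples Sample identifiers (so that individuals without segments
#'   report 0).
#' @return Data frame `sample`, `f_roh`, plus total ROH length per class.
#' @export
froh_by_sample <- function(segments, genome_length, samples) {
  out <- data.frame(sample = samples, f_roh = 0,
                    kb_short = 0, kb_medium = 0, kb_long = 0,
                    stringsAsFactors = FALSE)
  if (nrow(segments)) {
    for (i in seq_along(samples)) {
      seg <- segments[segments$sample == samples[i], , drop = FALSE]
      out$f_roh[i] <- f_roh(seg, genome_length)
      bycl <- tapply(seg$length, seg$class, sum)
      out$kb_short[i] <- ifelse(is.na(bycl["short"]), 0, bycl["short"]) / 1e3
      out$kb_medium[i] <- ifelse(is.na(bycl["medium"]), 0, bycl["medium"]) / 1e3
      out$kb_long[i] <- ifelse(is.na(bycl["long"]), 0, bycl["long"]) / 1e3
    }
  }
  out
}

#' Method-of-moments inbreeding coefficient F_IS
#'
#' Plink-het-style estimate per individual:
#' `F = (O_hom - E_hom) / (N_used - E_hom)`, with
#' `E_hom = sum_sites [1 - 2 p (1-p) * 2n/(2n-1)]` over the individual's
#' non-missing sites, `p` the cohort alternate-allele frequency and `n` the
#' number of genotyped diploids at the site. Undefined (all sites
#' monomorphic) yields `NA`.
#'
#' @param gm A `genotype_matrix` for the whole cohort.
#' @return Data frame `sample`, `f_is`, `o_hom`, `e_hom`, `n_used`.
#' @export
f_is <- function(gm) {
  g <- gm$genotypes
  ac <- allele_counts(gm)
  n_dip <- ac$n_called / 2
  p <- ac$af
  e_site <- 1 - 2 * p * (1 - p) * (2 * n_dip / pmax(2 * n_dip - 1, 1))
  obs <- g != 1L
  called <- !is.na(g)
  o_hom <- rowSums(obs, na.rm = TRUE)
  e_hom <- as.vector(called %*% ifelse(is.na(e_site), 0, e_site))
  n_used <- rowSums(called & !is.na(rep(1, nrow(g)) %o% p))
  denom <- n_used - e_hom
  f <- ifelse(abs(denom) < 1e-12, NA_real_, (o_hom - e_hom) / denom)
  data.frame(sample = gm$samples, f_is = f, o_hom = o_hom, e_hom = e_hom,
             n_used = n_used, stringsAsFactors = FALSE)
}
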