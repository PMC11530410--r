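# Independent brute-force oracles. These enumerate allele pairs / scan runs
# directly and are deliberately written without reference to the package's
# internals.

# expand a genotype column into its called allele vector (0/1 per haplotype)
.alleles_of <- function(g) {
  g <- unname(g[!is.na(g)])
  if (!length(g)) return(integer(0))
  unlist(lapply(g, function(x) c(rep(1L, x), rep(0L, 2L - x))))
}

brute_pi <- function(g) {
  num <- 0
  den <- 0
  for (j in seq_len(ncol(g))) {
    a <- .alleles_of(g[, j])
    n <- length(a)
    if (n < 2) next
    d <- 0
    for (x in seq_len(n - 1)) for (y in (x + 1):n) d <- d + (a[x] != a[y])
    num <- num + d
    den <- den + n * (n - 1) / 2
  }
  if (den == 0) NA_real_ else num / den
}

brute_dxy <- function(ga, gb) {
  num <- 0
  den <- 0
  for (j in seq_len(ncol(ga))) {
    a <- .alleles_of(ga[, j])
    b <- .alleles_of(gb[, j])
    if (!length(a) || !length(b)) next
    num <- num + sum(outer(a, b, "!="))
    den <- den + length(a) * length(b)
  }
  if (den == 0) NA_real_ else num / den
}

# textbook Hudson estimator: ratio of window sums of unbiased within-pop
# heterozygosity over between-pop heterozygosity
brute_hudson <- function(ga, gb) {
  hw_a <- hw_b <- hb <- 0
  any_site <- FALSE
  for (j in seq_len(ncol(ga))) {
    a <- .alleles_of(ga[, j])
    b <- .alleles_of(gb[, j])
    if (length(a) < 2 || length(b) < 2) next
    any_site <- TRUE
    hw_a <- hw_a + sum(outer(a, a, "!=")) / (length(a) * (length(a) - 1))
    hw_b <- hw_b + sum(outer(b, b, "!=")) / (length(b) * (length(b) - 1))
    hb <- hb + mean(outer(a, b, "!="))
  }
  if (!any_site || hb == 0) return(NA_real_)
  1 - (hw_a + hw_b) / 2 / hb
}

brute_tajima <- function(g) {
  complete <- colSums(is.na(g)) == 0
  g <- g[, complete, drop = FALSE]
  n <- 2 * nrow(g)
  if (n < 4 || ncol(g) == 0) return(NA_real_)
  k <- colSums(g)
  seg <- k > 0 & k < n
  s <- sum(seg)
  if (s < 3) return(NA_real_)
  pi_hat <- 0
  for (j in which(seg)) {
    a <- .alleles_of(g[, j])
    pi_hat <- pi_hat + sum(outer(a, a, "!=")) / 2 / choose(n, 2)
  }
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

brute_fis_one <- function(g_ind, g_all) {
  o_hom <- 0
  e_hom <- 0
  n_used <- 0
  for (j in seq_len(ncol(g_all))) {
    if (is.na(g_ind[j])) next
    called <- g_all[, j][!is.na(g_all[, j])]
    n <- length(called)
    p <- sum(called) / (2 * n)
    o_hom <- o_hom + (g_ind[j] != 1)
    e_hom <- e_hom + (1 - 2 * p * (1 - p) * (2 * n / (2 * n - 1)))
    n_used <- n_used + 1
  }
  if (abs(n_used - e_hom) < 1e-12) return(NA_real_)
  (o_hom - e_hom) / (n_used - e_hom)
}

# maximal-run ROH scan over one individual's genotypes on one chromosome
brute_roh <- function(g, pos, window_snps = 50, min_snps = 50,
                      min_length_bp = 1e4, max_gap_bp = 1e6) {
  keep <- !is.na(g)
  g <- g[keep]
  pos <- pos[keep]
  segs <- list()
  run <- integer(0)
  flush <- function(run) {
    if (length(run) >= max(min_snps, window_snps)) {
      len <- pos[run[length(run)]] - pos[run[1]] + 1
      if (len >= min_length_bp) {
        return(data.frame(start = pos[run[1]], end = pos[run[length(run)]],
                          n_snps = length(run), length = len))
      }
    }
    NULL
  }
  for (i in seq_along(g)) {
    gap <- length(run) > 0 && (pos[i] - pos[run[length(run)]]) > max_gap_bp
    if (g[i] == 1 || gap) {
      segs[[length(segs) + 1]] <- flush(run)
      run <- if (g[i] == 1) integer(0) else i
    } else {
      run <- c(run, i)
    }
  }
  segs[[length(segs) + 1]] <- flush(run)
  out <- do.call(rbind, segs)
  if (is.null(out)) data.frame(start = integer(), end = integer(),
                               n_snps = integer(), length = integer())
  else out
}

brute_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(estimate = r, p.value = 2 * stats::pt(-abs(tval), df = n - 2))
}

random_gm <- function(n_ind, n_site, miss = 0.1, seed = 1, chrom = "chr1") {
  set.seed(seed)
  g <- matrix(rbinom(n_ind * n_site, 2, runif(n_site, 0.05, 0.95)[
    rep(seq_len(n_site), each = n_ind)]), nrow = n_ind)
  if (miss > 0) g[runif(length(g)) < miss] <- NA_integer_
  genotype_matrix(
    g,
    data.frame(chrom = chrom, pos = sort(sample.int(n_site * 50, n_site)),
               ref = "A", alt = "T", stringsAsFactors = FALSE),
    samples = sprintf("I%02d", seq_len(n_ind))
  )
}
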