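# Site-level filtering and SNP-set construction.

#' Filter sites on missingness, biallelism and minor allele frequency
#'
#' Retains sites that are polymorphic among observed genotypes (both alleles
#' seen), have a missing-genotype proportion at or below `max_missing_rate`,
#' and have a minor allele frequency of at least `min_maf` computed on
#' non-missing alleles. Site order is preserved and filtering is idempotent.
#'
#' @param gm A `genotype_matrix`.
#' @param max_missing_rate Maximum tolerated missing-genotype proportion per
#'   site (default 0.2, i.e. remove sites missing in more than 20% of
#'   samples).
#' @param min_maf Minimum minor allele frequency (default 0).
#' @return A filtered `genotype_matrix`; the retained site indices are
#'   attached as attribute `"kept"`.
#' @export
filter_sites <- function(gm, max_missing_rate = 0.2, min_maf = 0) {
  if (n_sites(gm) == 0L) stop("empty genotype matrix")
  miss <- colMeans(is.na(gm$genotypes))
  ac <- allele_counts(gm)
  maf <- pmin(ac$af, 1 - ac$af)
  poly <- !is.na(ac$af) & ac$af > 0 & ac$af < 1
  keep <- poly & miss <= max_missing_rate & !is.na(maf) & maf >= min_maf
  if (!any(keep)) {
    warning("all sites removed by filters; returning an empty matrix")
  }
  out <- gm[, keep]
  attr(out, "kept") <- which(keep)
  out
}

#' LD pruning of sites (Plink-style indep-pairwise on dosages)
#'
#' Slides a window of `ld_window` sites advanced by `ld_step` along each
#' chromosome. Within a window, while any pair of retained sites has a
#' squared dosage correlation above `ld_r2`, the worst pair (largest r^2) is
#' located and its lower-MAF member dropped (ties broken by dropping the
#' later site) - a deterministic rule. The output never contains a
#' within-window retained pair above the threshold.
#'
#' @param gm A `genotype_matrix` with sites sorted by position.
#' @param ld_window Window size in sites (default 50).
#' @param ld_step Step between window starts in sites (default 10).
#' @param ld_r2 Squared-correlation threshold (default 0.2).
#' @return Integer vector of retained site indices, in original order.
#' @export
ld_prune <- function(gm, ld_window = 50, ld_step = 10, ld_r2 = 0.2) {
  if (ld_window < 2) stop("ld_window must be at least 2")
  if (ld_step < 1) stop("ld_step must be positive")
  g <- gm$genotypes
  ac <- allele_counts(gm)
  maf <- pmin(ac$af, 1 - ac$af)
  keep <- rep(TRUE, n_sites(gm))
  for (idx in split(seq_len(n_sites(gm)), gm$sites$chrom)) {
    n <- length(idx)
    starts <- seq(1L, max(1L, n), by = ld_step)
    for (s in starts) {
      win <- idx[s:min(s + ld_window - 1L, n)]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2L) break
        r2 <- suppressWarnings(stats::cor(g[, act, drop = FALSE],
                                          use = "pairwise.complete.obs"))^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        worst <- max(r2)
        if (worst <= ld_r2) break
        hit <- which(r2 == worst, arr.ind = TRUE)[1L, ]
        pair <- sort(act[hit])
        drop <- if (isTRUE(maf[pair[1]] < maf[pair[2]])) pair[1]
                else if (isTRUE(maf[pair[2]] < maf[pair[1]])) pair[2]
                else pair[2]
        keep[drop] <- FALSE
      }
      if (s + ld_window - 1L >= n) break
    }
  }
  which(keep)
}

.effect_class_map <- c(
  synonymous_variant = "synonymous",
  missense_variant = "missense",
  stop_gained = "stop_gained",
  splice_acceptor_variant = "splice_acceptor",
  splice_donor_variant = "splice_donor",
  intergenic_region = "intergenic",
  intergenic_variant = "intergenic"
)

.aa3to1 <- function(x) {
  m <- stats::setNames(.aa1, .aa3)
  out <- m[paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))]
  unname(out)
}

#' Parse a variant-effect annotation table
#'
#' Reads either a plain TSV (columns `chrom`, `pos`, `effect`, `aa_ref`,
#' `aa_alt`) or a VCF whose INFO field carries SnpEff-style `ANN=` entries
#' (effect from the annotation field, amino acids from the `p.` HGVS
#' notation). Effect strings are mapped to the classes `synonymous`,
#' `missense`, `stop_gained`, `splice_acceptor`, `splice_donor`,
#' `intergenic`; unknown strings become `other` (with a message giving the
#' count), and matrix sites without any annotation record are returned as
#' `other` so downstream load analysis excludes them. Annotated coordinates
#' absent from the matrix are an error unless `allow_extra` is set (useful
#' when the matrix has already been site-filtered).
#'
#' @param path Annotation TSV or VCF path.
#' @param gm The `genotype_matrix` the annotations describe.
#' @param allow_extra Silently drop annotation records at coordinates not in
#'   the matrix (default `FALSE`: they are an error).
#' @return Data frame with one row per matrix site: `chrom`, `pos`, `class`,
#'   `aa_ref`, `aa_alt` (one-letter, `NA` unless missense).
#' @export
parse_annotations <- function(path, gm, allow_extra = FALSE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    ann <- .parse_ann_vcf(path)
  } else {
    ann <- data.table::fread(path, sep = "\t", data.table = FALSE)
    need <- c("chrom", "pos", "effect")
    if (!all(need %in% names(ann))) {
      stop("annotation TSV must have columns chrom, pos, effect")
    }
    if (is.null(ann$aa_ref)) ann$aa_ref <- NA_character_
    if (is.null(ann$aa_alt)) ann$aa_alt <- NA_character_
  }
  key_m <- site_key(gm$sites)
  key_a <- paste(ann$chrom, ann$pos, sep = ":")
  missing_sites <- !(key_a %in% key_m)
  if (any(missing_sites)) {
    if (!allow_extra) {
      stop("annotation coordinates not present in the genotype matrix, e.g. ",
           key_a[which(missing_sites)[1]])
    }
    ann <- ann[!missing_sites, , drop = FALSE]
    key_a <- key_a[!missing_sites]
  }
  cls <- .effect_class_map[ann$effect]
  n_unknown <- sum(is.na(cls))
  if (n_unknown > 0) {
    message(n_unknown, " annotation record(s) with unknown effect mapped to class 'other'")
    cls[is.na(cls)] <- "other"
  }
  out <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    class = "other", aa_ref = NA_character_,
                    aa_alt = NA_character_, stringsAsFactors = FALSE)
  idx <- match(key_a, key_m)
  out$class[idx] <- unname(cls)
  out$aa_ref[idx] <- ann$aa_ref
  out$aa_alt[idx] <- ann$aa_alt
  out$aa_ref[out$class != "missense"] <- NA_character_
  out$aa_alt[out$class != "missense"] <- NA_character_
  out
}

.parse_ann_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  ann_str <- sub(".*ANN=([^;]*).*", "\\1", fix$INFO)
  ann_str[!grepl("ANN=", fix$INFO)] <- NA
  first_ann <- vapply(strsplit(ann_str, ",", fixed = TRUE),
                      function(x) x[1], character(1))
  fields <- strsplit(first_ann, "|", fixed = TRUE)
  effect <- vapply(fields, function(f) if (length(f) >= 2) f[2] else NA_character_,
                   character(1))
  hgvs_p <- vapply(fields, function(f) if (length(f) >= 11) f[11] else "",
                   character(1))
  aa <- regmatches(hgvs_p, regexec("p\\.([A-Za-z]{3})[0-9]+([A-Za-z]{3})", hgvs_p))
  aa_ref <- vapply(aa, function(m) if (length(m) == 3) .aa3to1(m[2]) else NA_character_,
                   character(1))
  aa_alt <- vapply(aa, function(m) if (length(m) == 3) .aa3to1(m[3]) else NA_character_,
                   character(1))
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), effect = effect,
             aa_ref = aa_ref, aa_alt = aa_alt, stringsAsFactors = FALSE)
}
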