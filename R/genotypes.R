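#' Genotype matrix container
#'
#' Couples a samples x sites matrix of derived/alternate allele dosages
#' (0, 1, 2, or `NA` for a missing call) with its site table. Sites carry
#' 1-based VCF-style coordinates and exactly one reference and one alternate
#' allele; positions must be strictly increasing within each chromosome.
#'
#' @param genotypes Integer matrix, samples in rows, sites in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param samples Character vector of sample identifiers; defaults to the
#'   row names of `genotypes`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, sites, samples = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(genotypes)))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("`sites` must have columns chrom, pos, ref, alt")
  }
  if (nrow(sites) != ncol(genotypes)) {
    stop("number of sites (", nrow(sites), ") does not match genotype columns (",
         ncol(genotypes), ")")
  }
  if (length(samples) != nrow(genotypes)) {
    stop("sample names do not match genotype rows")
  }
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    stop("sites must be sorted by position within chromosome")
  }
  dup <- unlist(lapply(split(sites$pos, sites$chrom), function(p) any(diff(p) == 0)))
  if (any(dup)) stop("positions must be strictly increasing within chromosome")
  rownames(genotypes) <- samples
  structure(
    list(genotypes = genotypes, sites = sites, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$genotypes))
  cat(sprintf(
    "genotype_matrix: %d samples x %d sites on %d chromosome(s), %.2f%% missing\n",
    n_samples(x), n_sites(x), length(unique(x$sites$chrom)), 100 * miss
  ))
  invisible(x)
}

#' Numbers of samples and sites
#' @param x A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname n_samples
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param i Sample index (integer, logical, or sample names).
#' @param j Site index (integer or logical).
#' @param ... Unused.
#' @return A `genotype_matrix` restricted to the requested samples/sites.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_sites(x))
  if (is.character(i)) i <- match(i, x$samples)
  genotype_matrix(
    x$genotypes[i, j, drop = FALSE],
    x$sites[j, , drop = FALSE],
    samples = x$samples[i]
  )
}

site_key <- function(sites) paste(sites$chrom, sites$pos, sep = ":")

#' Per-site allele counts among non-missing genotypes
#'
#' @param x A `genotype_matrix` or a bare dosage matrix.
#' @return A list with per-site vectors: `n_alt` (derived/alt allele count),
#'   `n_called` (non-missing allele count, i.e. twice the genotyped diploids),
#'   `n_ref`, and `af` (alt allele frequency, `NaN` where no call).
#' @export
allele_counts <- function(x) {
  g <- if (inherits(x, "genotype_matrix")) x$genotypes else x
  called <- colSums(!is.na(g))
  n_alt <- colSums(g, na.rm = TRUE)
  n_called <- 2L * called
  list(n_alt = n_alt, n_called = n_called,
       n_ref = n_called - n_alt, af = n_alt / n_called)
}

genotype_to_gt <- function(g) {
  gt <- rep("./.", length(g))
  gt[!is.na(g) & g == 0L] <- "0/0"
  gt[!is.na(g) & g == 1L] <- "0/1"
  gt[!is.na(g) & g == 2L] <- "1/1"
  gt
}

#' Write genotypes to a VCFv4.2 file
#'
#' Emits a minimal standards-compliant multi-sample VCF (GT field only),
#' with `##contig` headers taken from `chrom_sizes` when supplied.
#'
#' @param x A `genotype_matrix`.
#' @param path Output file path (plain text).
#' @param chrom_sizes Optional data frame with columns `chrom`, `length`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, chrom_sizes = NULL) {
  if (n_sites(x) == 0L || n_samples(x) == 0L) {
    stop("refusing to write an empty cohort to ", path)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=loadscape",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(chrom_sizes)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          chrom_sizes$chrom, as.integer(chrom_sizes$length)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", x$samples), collapse = "\t"))
  gt <- apply(x$genotypes, 2L, genotype_to_gt)
  # apply() returns samples in rows of the result only when >1 site; normalise
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_samples(x))
  body <- data.table::data.table(
    chrom = x$sites$chrom, pos = x$sites$pos, id = ".",
    ref = x$sites$ref, alt = x$sites$alt,
    qual = ".", filter = "PASS", info = ".", format = "GT"
  )
  body <- cbind(body, data.table::as.data.table(t(gt)))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Uses the vcfR parser and converts GT calls to 0/1/2 dosages. Multiallelic
#' records and indels are dropped with a message so that the resulting matrix
#' honours the one-alt-allele invariant. Optional depth/quality pass-through
#' filters operate on FORMAT/DP and QUAL when those fields are present in the
#' file, and are skipped with a message otherwise (the upstream caller context
#' cannot be reconstructed from a bare matrix).
#'
#' @param path VCF file path.
#' @param min_qual Optional minimum QUAL; sites below are dropped.
#' @param depth_range Optional length-2 numeric; genotypes with FORMAT/DP
#'   outside `[depth_range[1], depth_range[2]]` are set to missing.
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path, min_qual = NULL, depth_range = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  if (!is.null(min_qual)) {
    qual <- suppressWarnings(as.numeric(fix$QUAL))
    if (all(is.na(qual))) {
      message("QUAL absent; quality filter skipped")
    } else {
      keep <- keep & !is.na(qual) & qual >= min_qual
    }
  }
  if (any(!keep)) {
    message("dropped ", sum(!keep), " multiallelic/indel/low-quality record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  g <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
              dimnames = list(colnames(gt), NULL))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  g[] <- t(ifelse(clean == "0/0", 0L,
           ifelse(clean %in% c("0/1", "1/0"), 1L,
           ifelse(clean == "1/1", 2L, NA_integer_))))
  if (!is.null(depth_range)) {
    dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                   error = function(e) NULL)
    if (is.null(dp)) {
      message("FORMAT/DP absent; depth filter skipped")
    } else {
      dp <- t(dp[keep, , drop = FALSE])
      g[!is.na(dp) & (dp < depth_range[1] | dp > depth_range[2])] <- NA_integer_
    }
  }
  genotype_matrix(
    g,
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    samples = colnames(gt)
  )
}
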