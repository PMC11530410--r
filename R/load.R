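# Polarization to ancestral/derived state and mutation-load decomposition.

#' Polarize sites to ancestral/derived state
#'
#' For each site, the allele that is homozygous in more than half of the
#' genotyped individuals is taken as the ancestral state (for a complete
#' 154-individual cohort this is the "more than 77 individuals" rule). Sites
#' where no allele reaches that majority are excluded
#' (`excluded_no_majority`); sites whose inferred ancestral allele is not the
#' reference allele are excluded (`excluded_ref_mismatch`) to avoid bias from
#' deleterious alleles fixed in the reference assembly. Only `polarized`
#' sites, for which derived-allele dosage equals the stored alt dosage, enter
#' the load computation.
#'
#' @param gm A filtered, biallelic `genotype_matrix`.
#' @return Data frame: `chrom`, `pos`, `ancestral`, `derived`, `status`.
#' @export
polarize <- function(gm) {
  g <- gm$genotypes
  n_geno <- colSums(!is.na(g))
  hom_ref <- colSums(g == 0L, na.rm = TRUE)
  hom_alt <- colSums(g == 2L, na.rm = TRUE)
  status <- rep("excluded_no_majority", n_sites(gm))
  status[hom_ref > n_geno / 2] <- "polarized"
  status[hom_alt > n_geno / 2] <- "excluded_ref_mismatch"
  data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos,
    ancestral = ifelse(status == "excluded_ref_mismatch",
                       gm$sites$alt, gm$sites$ref),
    derived = ifelse(status == "excluded_ref_mismatch",
                     gm$sites$ref, gm$sites$alt),
    status = status, stringsAsFactors = FALSE
  )
}

#' Classify sites into mutation classes
#'
#' Synonymous variants are benign (`SYN`). Missense variants are scored with
#' the Grantham distance between the two residues: scores from 5 to 150 are
#' slightly deleterious tolerated (`TOL`), scores above 150 deleterious
#' (`DEL`). Stop-gain and splice acceptor/donor variants are severely
#' deleterious loss-of-function (`LOF`) regardless of amino-acid change.
#' Intergenic and `other` sites, and missense records without an amino-acid
#' pair (annotation errors, counted in a message), get `NA` and are excluded
#' from load analysis.
#'
#' @param annotations Data frame as returned by [parse_annotations()].
#' @return The input with added columns `grantham` (integer score, missense
#'   only) and `mutation_class` (factor `SYN`/`TOL`/`DEL`/`LOF` or `NA`).
#' @export
classify_sites <- function(annotations) {
  cls <- rep(NA_character_, nrow(annotations))
  gs <- rep(NA_integer_, nrow(annotations))
  cls[annotations$class == "synonymous"] <- "SYN"
  cls[annotations$class %in% c("stop_gained", "splice_acceptor", "splice_donor")] <- "LOF"
  mis <- which(annotations$class == "missense")
  has_aa <- mis[!is.na(annotations$aa_ref[mis]) & !is.na(annotations$aa_alt[mis])]
  if (length(has_aa) < length(mis)) {
    message(length(mis) - length(has_aa),
            " missense site(s) lack an amino-acid pair; excluded")
  }
  if (length(has_aa)) {
    gs[has_aa] <- grantham_score(annotations$aa_ref[has_aa],
                                 annotations$aa_alt[has_aa])
    ident <- has_aa[gs[has_aa] == 0L]
    if (length(ident)) {
      message(length(ident),
              " missense site(s) with identical residues treated as annotation errors")
    }
    scored <- setdiff(has_aa, ident)
    cls[scored] <- ifelse(gs[scored] > 150L, "DEL", "TOL")
  }
  annotations$grantham <- gs
  annotations$mutation_class <- factor(cls, levels = c("SYN", "TOL", "DEL", "LOF"))
  annotations
}

#' Per-individual mutation load
#'
#' Counts derived heterozygous and homozygous loci per mutation class over
#' the polarized sites and computes three statistics per individual:
#' the per-class homozygosity load `2*n_hom / (2*n_hom + n_het)` (the ratio
#' of derived homozygous allele copies to all derived copies: two per
#' homozygous locus, one per heterozygous locus); the masked load
#' `(n_het(DEL) + n_het(LOF)) / SYN` (deleterious copies hidden in
#' heterozygotes, relative to benign variation); and the realized load
#' `2*(n_hom(DEL) + n_hom(LOF)) / SYN` (deleterious copies expressed in
#' homozygotes). In the default `"alleles"` mode `SYN` counts derived
#' synonymous allele copies (`2*n_hom + n_het`); in `"loci"` mode both
#' numerators and denominators count loci instead. Missing genotypes
#' contribute to neither numerator nor denominator; an individual with no
#' derived allele in a class has that class's homozygosity load reported as
#' `NA`, and one with no derived synonymous allele has undefined
#' masked/realized load.
#'
#' @param gm A `genotype_matrix` (dosage = alt = derived for polarized
#'   sites).
#' @param polarized Output of [polarize()] for the same sites.
#' @param classes Output of [classify_sites()] for the same sites.
#' @param count_mode `"alleles"` (default) or `"loci"`.
#' @param popmap Optional data frame (`sample`, `population`) for population
#'   means.
#' @return A list of class `load_report`: `per_class` (sample, class, n_het,
#'   n_hom, homozygosity_load), `per_sample` (masked/realized load and the
#'   combined DEL+LOF homozygosity load), and `per_population` means when a
#'   popmap is given.
#' @export
compute_load <- function(gm, polarized, classes, count_mode = c("alleles", "loci"),
                         popmap = NULL) {
  count_mode <- match.arg(count_mode)
  stopifnot(nrow(polarized) == n_sites(gm), nrow(classes) == n_sites(gm))
  use <- polarized$status == "polarized" & !is.na(classes$mutation_class)
  g <- gm$genotypes[, use, drop = FALSE]
  cls <- droplevels(factor(classes$mutation_class[use],
                           levels = c("SYN", "TOL", "DEL", "LOF")))
  lev <- c("SYN", "TOL", "DEL", "LOF")
  het <- hom <- matrix(0, nrow = n_samples(gm), ncol = length(lev),
                       dimnames = list(gm$samples, lev))
  for (cl in levels(cls)) {
    sub <- g[, cls == cl, drop = FALSE]
    het[, cl] <- rowSums(sub == 1L, na.rm = TRUE)
    hom[, cl] <- rowSums(sub == 2L, na.rm = TRUE)
  }
  homload <- 2 * hom / (2 * hom + het)
  homload[!is.finite(homload)] <- NA_real_
  per_class <- data.frame(
    sample = rep(gm$samples, times = length(lev)),
    class = rep(lev, each = n_samples(gm)),
    n_het = as.vector(het), n_hom = as.vector(hom),
    homozygosity_load = as.vector(homload),
    stringsAsFactors = FALSE
  )
  if (count_mode == "alleles") {
    syn <- 2 * hom[, "SYN"] + het[, "SYN"]
    masked <- (het[, "DEL"] + het[, "LOF"]) / syn
    realized <- 2 * (hom[, "DEL"] + hom[, "LOF"]) / syn
  } else {
    syn <- hom[, "SYN"] + het[, "SYN"]
    masked <- (het[, "DEL"] + het[, "LOF"]) / syn
    realized <- (hom[, "DEL"] + hom[, "LOF"]) / syn
  }
  masked[!is.finite(masked)] <- NA_real_
  realized[!is.finite(realized)] <- NA_real_
  dellof_hom <- hom[, "DEL"] + hom[, "LOF"]
  dellof_het <- het[, "DEL"] + het[, "LOF"]
  load_dellof <- 2 * dellof_hom / (2 * dellof_hom + dellof_het)
  load_dellof[!is.finite(load_dellof)] <- NA_real_
  per_sample <- data.frame(
    sample = gm$samples,
    syn_alleles = unname(syn),
    masked_load = unname(masked),
    realized_load = unname(realized),
    homozygosity_load_dellof = unname(load_dellof),
    stringsAsFactors = FALSE
  )
  out <- list(per_class = per_class, per_sample = per_sample,
              count_mode = count_mode, n_sites_used = sum(use))
  if (!is.null(popmap)) {
    per_sample$population <- popmap$population[match(per_sample$sample, popmap$sample)]
    agg <- stats::aggregate(
      per_sample[, c("masked_load", "realized_load", "homozygosity_load_dellof")],
      by = list(population = per_sample$population),
      FUN = function(v) mean(v, na.rm = TRUE)
    )
    out$per_population <- agg
  }
  class(out) <- "load_report"
  out
}

#' @export
print.load_report <- function(x, ...) {
  cat(sprintf("load_report: %d individuals, %d polarized classified sites (%s mode)\n",
              nrow(x$per_sample), x$n_sites_used, x$count_mode))
  cat(sprintf("  mean masked load %.4g, mean realized load %.4g\n",
              mean(x$per_sample$masked_load, na.rm = TRUE),
              mean(x$per_sample$realized_load, na.rm = TRUE)))
  invisible(x)
}
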