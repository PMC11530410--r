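# Grantham (1974) amino-acid difference formula:
#   D_ij = rho * [alpha (c_i - c_j)^2 + beta (p_i - p_j)^2 + gamma (v_i - v_j)^2]^(1/2)
# with composition c, polarity p and molecular volume v from Grantham's
# property table, alpha = 1.833, beta = 0.1018, gamma = 0.000399, and rho the
# normalization constant that sets the mean over the 190 residue pairs to 100
# (printed as 50.723 in the original; we carry it unrounded, which is what
# reproduces the table's anchor values such as Cys-Trp = 215 after rounding).

.aa1 <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
          "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")
.aa3 <- c("Ser", "Arg", "Leu", "Pro", "Thr", "Ala", "Val", "Gly", "Ile", "Phe",
          "Tyr", "Cys", "His", "Gln", "Asn", "Lys", "Asp", "Glu", "Met", "Trp")

.grantham_properties <- data.frame(
  aa = .aa1,
  composition = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
                  0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
  polarity    = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
                  6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  volume      = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
                  136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
  stringsAsFactors = FALSE
)

.grantham_const <- list(alpha = 1.833, beta = 0.1018, gamma = 0.000399)

.loadscape_cache <- new.env(parent = emptyenv())

.grantham_unscaled <- function() {
  pr <- .grantham_properties
  k <- .grantham_const
  dc <- outer(pr$composition, pr$composition, "-")
  dp <- outer(pr$polarity, pr$polarity, "-")
  dv <- outer(pr$volume, pr$volume, "-")
  d <- sqrt(k$alpha * dc^2 + k$beta * dp^2 + k$gamma * dv^2)
  dimnames(d) <- list(pr$aa, pr$aa)
  d
}

.grantham_rho <- function() {
  if (is.null(.loadscape_cache$rho)) {
    d <- .grantham_unscaled()
    .loadscape_cache$rho <- 100 / mean(d[upper.tri(d)])
  }
  .loadscape_cache$rho
}

#' Grantham physicochemical distance between amino acids
#'
#' `grantham_formula()` evaluates Grantham's (1974) difference formula
#' (composition, polarity and molecular volume, with the published
#' alpha/beta/gamma weights and mean-100 normalization) and returns the
#' unrounded distance. `grantham_score()` rounds to the integer grid of the
#' published 190-pair table; identical residues score 0. Both accept one- or
#' three-letter codes and are vectorized over pairs.
#'
#' @param aa_i,aa_j Amino-acid codes ("L" or "Leu"); recycled to a common
#'   length.
#' @return Numeric (formula) or integer (score) vector of distances.
#' @references Grantham, R. (1974) Amino acid difference formula to help
#'   explain protein evolution. Science 185:862-864.
#' @export
grantham_score <- function(aa_i, aa_j) {
  as.integer(round(grantham_formula(aa_i, aa_j)))
}

#' @rdname grantham_score
#' @export
grantham_formula <- function(aa_i, aa_j) {
  i <- aa_index(aa_i)
  j <- aa_index(aa_j)
  d <- .grantham_unscaled() * .grantham_rho()
  d[cbind(i, j)]
}

aa_index <- function(aa) {
  aa <- as.character(aa)
  i <- ifelse(nchar(aa) == 1L, match(toupper(aa), .aa1),
              match(paste0(toupper(substr(aa, 1, 1)), tolower(substring(aa, 2))), .aa3))
  if (anyNA(i)) {
    stop("non-standard amino acid code(s): ",
         paste(unique(aa[is.na(i)]), collapse = ", "))
  }
  i
}

#' Full Grantham distance matrix
#'
#' @return A symmetric 20 x 20 integer matrix over the standard amino acids
#'   (one-letter row/column names), zero on the diagonal.
#' @export
grantham_matrix <- function() {
  m <- round(.grantham_unscaled() * .grantham_rho())
  storage.mode(m) <- "integer"
  m
}

#' Grantham property table
#'
#' The composition, polarity and molecular volume values underlying the
#' distance formula, as shipped (and versioned) with the package under
#' `inst/extdata/grantham_properties.tsv`.
#'
#' @return Data frame with columns `aa`, `composition`, `polarity`, `volume`.
#' @export
grantham_properties <- function() .grantham_properties
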