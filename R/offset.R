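# Gradient-forest turnover model, genotype-environment association and
# genomic offset under future climate.

#' Population allele-frequency table
#'
#' Derived/alternate allele frequency per population over a no-missing SNP
#' set: allele count divided by twice the number of members.
#'
#' @param gm A `genotype_matrix` without missing genotypes.
#' @param popmap Data frame (`sample`, `population`).
#' @return Matrix populations x loci; column names are `chrom:pos` keys.
#' @export
population_allele_freqs <- function(gm, popmap) {
  if (anyNA(gm$genotypes)) {
    stop("missing genotypes present; build the table from a no-missing SNP set ",
         "(filter_sites with max_missing_rate = 0)")
  }
  pops <- split(match(popmap$sample, gm$samples), popmap$population)
  out <- t(vapply(pops, function(idx) {
    colSums(gm$genotypes[idx, , drop = FALSE]) / (2 * length(idx))
  }, numeric(n_sites(gm))))
  colnames(out) <- site_key(gm$sites)
  out
}

#' Drop redundant climate variables
#'
#' Greedy removal: among any pair of variables with absolute Spearman
#' correlation above `r_threshold`, the one with lower importance is dropped;
#' repeated until no pair exceeds the threshold. Constant variables are
#' dropped first with a warning. Deterministic given the importance ranking
#' (ties broken by keeping the earlier column).
#'
#' @param env Data frame or matrix, populations x climate variables.
#' @param importance Named numeric vector of preliminary importances.
#' @param r_threshold Absolute Spearman correlation threshold (default 0.7).
#' @return Character vector of retained variable names.
#' @export
select_climate_variables <- function(env, importance, r_threshold = 0.7) {
  env <- as.matrix(env)
  if (ncol(env) < 2L) stop("need at least two variables")
  keep <- colnames(env)
  const <- apply(env, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("dropping constant variable(s): ", paste(keep[const], collapse = ", "))
    keep <- keep[!const]
  }
  imp <- importance[keep]
  imp[is.na(imp)] <- 0
  repeat {
    if (length(keep) < 2L) break
    r <- abs(stats::cor(env[, keep, drop = FALSE], method = "spearman"))
    diag(r) <- 0
    if (max(r) <= r_threshold) break
    hit <- which(r == max(r), arr.ind = TRUE)[1L, ]
    pair <- keep[hit]
    drop <- if (imp[pair[1]] < imp[pair[2]]) pair[1]
            else if (imp[pair[2]] < imp[pair[1]]) pair[2]
            else pair[2]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Fit a gradient-forest turnover model
#'
#' For every locus, a bagged ensemble of `n_trees` regression trees predicts
#' its population allele frequencies from the climate variables. Per-locus
#' fit quality is the out-of-bag R^2 (negative values truncated to zero);
#' each split's impurity reduction is accrued to its variable at the split
#' threshold. Split importances are normalized within locus, weighted by the
#' locus R^2, and accumulated into `n_bins` equal-width bins over each
#' variable's observed range, then averaged over loci (so turnover height
#' does not scale with the size of the SNP set); the cumulative sum along
#' the axis is the
#' species-level turnover function (monotone non-decreasing, zero at the
#' range minimum) and each variable's total accrual is its overall
#' importance.
#'
#' @param freqs Populations x loci frequency matrix
#'   (see [population_allele_freqs()]).
#' @param env Populations x variables data frame/matrix, rows aligned with
#'   `freqs`.
#' @param n_trees Trees per locus (default 500).
#' @param mtry Variables tried per split (default `max(1, floor(V/3))`).
#' @param min_split Minimum node size eligible for splitting (default 5).
#' @param n_bins Bins per variable for the turnover functions (default 101).
#' @param seed Integer seed making the fit reproducible.
#' @return An object of class `turnover_model`.
#' @export
fit_gradient_forest <- function(freqs, env, n_trees = 500, mtry = NULL,
                                min_split = 5, n_bins = 101, seed = 1) {
  freqs <- as.matrix(freqs)
  env <- as.matrix(env)
  if (nrow(freqs) < 4L) stop("need at least 4 populations to fit")
  if (nrow(env) != nrow(freqs)) stop("env rows must match freqs rows")
  if (is.null(colnames(env))) colnames(env) <- paste0("V", seq_len(ncol(env)))
  vars <- colnames(env)
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(env) / 3))
  set.seed(seed)
  ranges <- apply(env, 2, range)
  edges <- lapply(vars, function(v) seq(ranges[1, v], ranges[2, v],
                                        length.out = n_bins + 1L))
  names(edges) <- vars
  bin_imp <- lapply(vars, function(v) numeric(n_bins))
  names(bin_imp) <- vars
  r2 <- numeric(ncol(freqs))
  for (l in seq_len(ncol(freqs))) {
    y <- freqs[, l]
    if (stats::var(y) == 0) next
    fit <- .bagged_forest(env, y, n_trees, mtry, min_split)
    r2[l] <- fit$r2
    tot <- sum(fit$imp)
    if (fit$r2 <= 0 || tot <= 0) next
    w <- fit$imp / tot * fit$r2
    for (v in seq_along(vars)) {
      sel <- fit$var == v
      if (!any(sel)) next
      e <- edges[[v]]
      bin <- pmin(pmax(findInterval(fit$thr[sel], e, rightmost.closed = TRUE), 1L),
                  n_bins)
      bin_imp[[vars[v]]] <- bin_imp[[vars[v]]] +
        as.numeric(tapply(w[sel], factor(bin, levels = seq_len(n_bins)), sum,
                          default = 0))
    }
  }
  # average over loci so turnover height does not scale with locus count
  # (offsets from differently sized SNP sets stay comparable)
  bin_imp <- lapply(bin_imp, function(b) b / ncol(freqs))
  importance <- vapply(bin_imp, sum, numeric(1))
  structure(
    list(variables = vars, ranges = ranges, edges = edges,
         bin_importance = bin_imp,
         cumulative = lapply(bin_imp, cumsum),
         importance = importance, r2 = r2,
         n_trees = n_trees, n_bins = n_bins, mtry = mtry,
         min_split = min_split, seed = seed),
    class = "turnover_model"
  )
}

#' @export
print.turnover_model <- function(x, ...) {
  cat(sprintf("turnover_model: %d variables, %d loci, %d trees/locus (seed %d)\n",
              length(x$variables), length(x$r2), x$n_trees, x$seed))
  imp <- sort(x$importance, decreasing = TRUE)
  cat("  importance:", paste(sprintf("%s=%.4g", names(imp), imp), collapse = ", "),
      "\n")
  invisible(x)
}

#' Map climate into turnover (cumulative-importance) space
#'
#' Evaluates each variable's turnover step function at the supplied values.
#' The function is zero at the variable's training-range minimum and steps up
#' at bin boundaries; values outside the training range are clamped to the
#' range ends.
#'
#' @param model A `turnover_model`.
#' @param climate Data frame or matrix containing the model's variables.
#' @return Matrix rows x variables of transformed values.
#' @export
transform_climate <- function(model, climate) {
  climate <- as.data.frame(climate)
  miss <- setdiff(model$variables, colnames(climate))
  if (length(miss)) stop("unknown/missing variable(s): ", paste(miss, collapse = ", "))
  climate <- as.matrix(climate[, model$variables, drop = FALSE])
  out <- matrix(0, nrow = nrow(climate), ncol = length(model$variables),
                dimnames = list(rownames(climate), model$variables))
  for (v in model$variables) {
    e <- model$edges[[v]]
    x <- pmin(pmax(climate[, v], e[1]), e[length(e)])
    cum <- c(0, model$cumulative[[v]])
    k <- findInterval(x, e[-1], rightmost.closed = FALSE)
    out[, v] <- cum[k + 1L]
  }
  out
}

#' Genomic offset between current and future climate
#'
#' Per grid cell and scenario, the offset is the Euclidean distance between
#' the turnover-transformed current and future climate vectors; the mean
#' offset averages the per-scenario offsets (offsets are computed per
#' scenario first, then averaged).
#'
#' @param model A `turnover_model`.
#' @param current Data frame with columns `cell`, `lat`, `lon` and the model
#'   variables.
#' @param future Named list of data frames like `current`, one per scenario.
#' @return Data frame of class `offset_map`: `cell`, `lat`, `lon`, one
#'   `offset_<scenario>` column per scenario, and `offset_mean`.
#' @export
genomic_offset <- function(model, current, future) {
  if (!is.list(future) || is.data.frame(future)) future <- list(scenario = future)
  tc <- transform_climate(model, current)
  out <- current[, intersect(c("cell", "lat", "lon"), names(current)), drop = FALSE]
  offs <- matrix(NA_real_, nrow = nrow(current), ncol = length(future))
  for (s in seq_along(future)) {
    f <- future[[s]]
    if (!identical(f$cell, current$cell)) {
      stop("cell mismatch between current and scenario '", names(future)[s], "' grids")
    }
    tf <- transform_climate(model, f)
    offs[, s] <- sqrt(rowSums((tc - tf)^2))
  }
  colnames(offs) <- paste0("offset_", names(future))
  out <- cbind(out, as.data.frame(offs))
  out$offset_mean <- rowMeans(offs)
  class(out) <- c("offset_map", class(out))
  out
}

#' Mean genomic offset per population
#'
#' Averages the per-cell mean offset over grid cells whose centres lie
#' within `radius_km` (haversine distance) of each population's coordinate.
#'
#' @param offset_map Output of [genomic_offset()].
#' @param pop_coords Data frame with columns `population`, `lat`, `lon`.
#' @param radius_km Radius in kilometres (default 20).
#' @return Data frame `population`, `offset`, `n_cells`; populations with no
#'   cell in radius get `NA` with a warning.
#' @export
population_offset <- function(offset_map, pop_coords, radius_km = 20) {
  cells <- cbind(offset_map$lon, offset_map$lat)
  out <- data.frame(population = pop_coords$population, offset = NA_real_,
                    n_cells = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pop_coords))) {
    d <- geosphere::distHaversine(cells, c(pop_coords$lon[i], pop_coords$lat[i]))
    sel <- d <= radius_km * 1000
    out$n_cells[i] <- sum(sel)
    if (!any(sel)) {
      warning("no grid cell within ", radius_km, " km of population ",
              pop_coords$population[i])
    } else {
      out$offset[i] <- mean(offset_map$offset_mean[sel])
    }
  }
  out
}

#' Adaptive SNP detection by redundancy analysis
#'
#' Redundancy analysis: the centred population frequency matrix is regressed
#' on the standardized climate variables by least squares, the fitted values
#' are eigen-decomposed, and each locus is scored by the squared norm of its
#' loadings (species scores, singular-value weighted) on the first `n_axes`
#' constrained axes. Significance is assessed by permuting the rows of the
#' climate table: `p = (1 + #{permuted score >= observed}) / (n_perm + 1)`;
#' loci with `p <= alpha` are reported as adaptive.
#'
#' @param freqs Populations x loci frequency matrix.
#' @param env Populations x variables climate table (rows aligned).
#' @param n_axes Constrained axes used for scoring (default 3).
#' @param n_perm Permutations (default 999).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return List: `adaptive` (locus names), `p`, `score`, `n_axes`, `seed`.
#' @export
rda_adaptive_snps <- function(freqs, env, n_axes = 3, n_perm = 999,
                              alpha = 0.05, seed = 1) {
  freqs <- as.matrix(freqs)
  env <- as.matrix(env)
  if (nrow(freqs) < ncol(env) + 2L) {
    stop("need at least ", ncol(env) + 2L, " populations for ", ncol(env),
         " variables")
  }
  x <- scale(env)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    bad <- colnames(env)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    stop("climate matrix is rank-deficient; collinear variable(s): ",
         paste(bad, collapse = ", "))
  }
  y <- scale(freqs, center = TRUE, scale = FALSE)
  q <- qr.Q(qr_x)
  k_axes <- min(n_axes, ncol(x))
  score_of <- function(qm) {
    b <- crossprod(qm, y)            # V x L
    sv <- svd(b, nu = 0)
    k <- min(k_axes, length(sv$d))
    colSums((t(sv$v[, seq_len(k), drop = FALSE]) * sv$d[seq_len(k)])^2)
  }
  obs <- score_of(q)
  set.seed(seed)
  exceed <- integer(length(obs))
  n <- nrow(freqs)
  # permutations are drawn in a canonical (name-sorted) population order so
  # that jointly relabeling the rows of both tables cannot change the result
  cn <- if (!is.null(rownames(freqs))) order(rownames(freqs)) else seq_len(n)
  for (b in seq_len(n_perm)) {
    sigma <- sample.int(n)
    perm <- seq_len(n)
    perm[cn] <- cn[sigma]
    exceed <- exceed + (score_of(q[perm, , drop = FALSE]) >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  loci <- colnames(freqs)
  if (is.null(loci)) loci <- as.character(seq_along(obs))
  list(adaptive = loci[p <= alpha], p = stats::setNames(p, loci),
       score = stats::setNames(obs, loci), n_axes = k_axes, seed = seed)
}

#' Random neutral SNP sample from intergenic annotations
#'
#' Uniform sample without replacement from loci annotated as intergenic,
#' deterministic for a fixed seed.
#'
#' @param annotations Data frame from [parse_annotations()].
#' @param n Sample size (defaults to all intergenic loci).
#' @param seed Integer seed.
#' @return Character vector of `chrom:pos` locus keys.
#' @export
sample_neutral_snps <- function(annotations, n = NULL, seed = 1) {
  pool <- which(annotations$class == "intergenic")
  if (is.null(n)) n <- length(pool)
  if (length(pool) < n) {
    stop("only ", length(pool), " intergenic loci available; ", n, " requested")
  }
  set.seed(seed)
  sel <- sort(sample(pool, n))
  paste(annotations$chrom[sel], annotations$pos[sel], sep = ":")
}
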