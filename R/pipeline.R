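# End-to-end orchestration: filtering -> polarization/load -> ROH/inbreeding
# -> windowed statistics -> turnover model and genomic offset, with one seed,
# per-stage TSV outputs, a JSON run manifest, and a per-population summary
# joining diversity, inbreeding, load and offset with their pairwise
# Spearman correlations.

#' Pipeline configuration
#'
#' Either `sim` (a [sim_config()]; the cohort is generated in memory) or
#' `input_dir` (a directory in [write_cohort()] layout) must be given. All
#' stage parameters have defaults recorded in the run manifest.
#'
#' @param sim Optional [sim_config()].
#' @param input_dir Optional cohort directory.
#' @param out_dir Output directory.
#' @param seed Integer seed for all stochastic stages.
#' @param stages Named logical toggles: `filter`, `load`, `roh`, `stats`,
#'   `offset`.
#' @param params Named list overriding stage parameters (see Details in the
#'   package vignette): `max_missing_rate`, `min_maf`, `ld_window`,
#'   `ld_step`, `ld_r2`, `window_size`, `lineage_sample_n`, `roh_window`,
#'   `roh_min_kb`, `roh_min_snps`, `roh_max_gap`, `count_mode`, `n_trees`,
#'   `r_threshold`, `n_axes`, `n_perm`, `alpha`, `radius_km`, `gf_max_loci`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL, out_dir = tempfile("run"),
                            seed = 1L, stages = NULL, params = list()) {
  if (is.null(sim) && is.null(input_dir)) {
    stop("either `sim` or `input_dir` must be supplied")
  }
  if (!is.null(input_dir)) {
    need <- file.path(input_dir, c("cohort.vcf", "annotations.tsv",
                                   "popmap.tsv", "chrom_sizes.tsv"))
    miss <- need[!file.exists(need)]
    if (length(miss)) {
      stop("input file(s) not found: ", paste(miss, collapse = ", "))
    }
  }
  defaults <- list(
    max_missing_rate = 0.2, min_maf = 0.0, ld_window = 50, ld_step = 10,
    ld_r2 = 0.2, window_size = 1e5, lineage_sample_n = 40,
    roh_window = 50, roh_min_kb = 10, roh_min_snps = 50, roh_max_gap = 1e6,
    count_mode = "alleles", n_trees = 500, r_threshold = 0.7, n_axes = 3,
    n_perm = 999, alpha = 0.05, radius_km = 20, gf_max_loci = 400,
    n_neutral = NULL
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  st <- list(filter = TRUE, load = TRUE, roh = TRUE, stats = TRUE, offset = TRUE)
  if (!is.null(stages)) st[names(stages)] <- stages
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), stages = st, params = defaults),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys `input_dir`/`out_dir`/`seed`/
#'   `stages`/`params`.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(input_dir = y$input_dir, out_dir = y$out_dir %||% tempfile("run"),
                  seed = y$seed %||% 1L, stages = y$stages,
                  params = y$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writes one TSV per result under
#' `out_dir`, a `manifest.json` recording every resolved parameter, seed and
#' input checksum, and `summary_populations.tsv` /
#' `summary_correlations.tsv` joining the per-population metrics. Reruns
#' with an identical configuration reproduce identical outputs; a stage
#' failure halts the run with the stage named, preserving earlier outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisible list with all stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  tsv <- function(x, name) {
    data.table::fwrite(x, file.path(config$out_dir, name), sep = "\t")
  }
  checksums <- NULL

  say("-- input")
  if (!is.null(config$input_dir)) {
    co <- .stage("input", read_cohort(config$input_dir))
    files <- list.files(config$input_dir, full.names = TRUE)
    checksums <- as.list(tools::md5sum(files))
    names(checksums) <- basename(files)
    pops_tbl <- unique(co$popmap[, c("population", "lat", "lon")])
    lineage_map <- NULL
    env_pops <- co$env_pops
  } else {
    co <- .stage("input", simulate_cohort(config$sim))
    pops_tbl <- co$pops
    lineage_map <- stats::setNames(co$pops$lineage, co$pops$population)
    env_pops <- co$env_pops
  }
  geno <- co$geno
  genome_length <- sum(as.numeric(co$chrom_sizes$length))

  res <- list(cohort = co)

  if (config$stages$filter) {
    say("-- filter: missingness/biallelic/MAF")
    geno <- .stage("filter", filter_sites(geno, p$max_missing_rate, p$min_maf))
    say("   retained ", n_sites(geno), " sites")
  }
  ann <- .stage("annotate", {
    tmp <- tempfile(fileext = ".tsv")
    data.table::fwrite(co$annotations, tmp, sep = "\t")
    on.exit(unlink(tmp), add = TRUE)
    parse_annotations(tmp, geno, allow_extra = TRUE)
  })
  res$filtered <- geno

  if (config$stages$load) {
    say("-- mutation load")
    res$load <- .stage("load", {
      pol <- polarize(geno)
      cls <- classify_sites(ann)
      rep <- compute_load(geno, pol, cls, count_mode = p$count_mode,
                          popmap = co$popmap)
      tsv(rep$per_class, "load_per_class.tsv")
      tsv(rep$per_sample, "load_per_sample.tsv")
      tsv(rep$per_population, "load_per_population.tsv")
      list(polarized = pol, classes = cls, report = rep)
    })
  }

  if (config$stages$roh) {
    say("-- runs of homozygosity")
    res$roh <- .stage("roh", {
      segs <- detect_roh(geno, window_snps = p$roh_window,
                         min_length_bp = p$roh_min_kb * 1e3,
                         min_snps = p$roh_min_snps, max_gap_bp = p$roh_max_gap)
      froh <- froh_by_sample(segs, genome_length, geno$samples)
      fis <- f_is(geno)
      rep <- merge(froh, fis[, c("sample", "f_is")], by = "sample", sort = FALSE)
      tsv(segs, "roh_segments.tsv")
      tsv(rep, "inbreeding.tsv")
      list(segments = segs, report = rep)
    })
  }

  if (config$stages$stats) {
    say("-- windowed diversity/divergence")
    res$stats <- .stage("stats", {
      w <- windowed_stats(geno, co$popmap, chrom_sizes = co$chrom_sizes,
                          window_size = p$window_size, lineages = lineage_map,
                          lineage_sample_n = p$lineage_sample_n)
      tsv(w, "windowed_stats.tsv")
      w
    })
  }

  if (config$stages$offset) {
    say("-- turnover model and genomic offset")
    res$offset <- .stage("offset", {
      nomiss <- filter_sites(geno, max_missing_rate = 0, min_maf = 0)
      kept <- ld_prune(nomiss, p$ld_window, p$ld_step, p$ld_r2)
      nomiss <- nomiss[, kept]
      freqs <- population_allele_freqs(nomiss, co$popmap)
      env <- env_pops[rownames(freqs), , drop = FALSE]
      # preliminary fit on a deterministic locus subsample ranks the
      # variables; redundant ones are then dropped and the model refit
      sub <- seq_len(ncol(freqs))
      if (length(sub) > p$gf_max_loci) {
        sub <- round(seq(1, length(sub), length.out = p$gf_max_loci))
      }
      pre <- fit_gradient_forest(freqs[, sub, drop = FALSE], env,
                                 n_trees = p$n_trees, seed = config$seed)
      vars <- select_climate_variables(env, pre$importance, p$r_threshold)
      say("   retained variables: ", paste(vars, collapse = ", "))
      envr <- env[, vars, drop = FALSE]
      rda <- rda_adaptive_snps(freqs, envr, n_axes = p$n_axes,
                               n_perm = p$n_perm, alpha = p$alpha,
                               seed = config$seed)
      ann_key <- paste(ann$chrom, ann$pos, sep = ":")
      ann_sub <- ann[ann_key %in% colnames(freqs), , drop = FALSE]
      n_neutral <- p$n_neutral %||% length(rda$adaptive)
      neutral <- sample_neutral_snps(ann_sub, n = min(n_neutral,
                                     sum(ann_sub$class == "intergenic")),
                                     seed = config$seed)
      say("   ", length(rda$adaptive), " adaptive and ", length(neutral),
          " neutral loci")
      gf_adp <- fit_gradient_forest(freqs[, rda$adaptive, drop = FALSE], envr,
                                    n_trees = p$n_trees, seed = config$seed)
      gf_neu <- fit_gradient_forest(freqs[, neutral, drop = FALSE], envr,
                                    n_trees = p$n_trees, seed = config$seed)
      cur <- co$climate_current
      fut <- co$climate_future
      om_adp <- genomic_offset(gf_adp, cur, fut)
      om_neu <- genomic_offset(gf_neu, cur, fut)
      po_adp <- population_offset(om_adp, pops_tbl, p$radius_km)
      po_neu <- population_offset(om_neu, pops_tbl, p$radius_km)
      tsv(om_adp, "offset_cells_adaptive.tsv")
      tsv(om_neu, "offset_cells_neutral.tsv")
      tsv(po_adp, "offset_populations_adaptive.tsv")
      tsv(po_neu, "offset_populations_neutral.tsv")
      writeLines(rda$adaptive, file.path(config$out_dir, "adaptive_loci.txt"))
      writeLines(neutral, file.path(config$out_dir, "neutral_loci.txt"))
      list(variables = vars, importance_all = pre$importance, rda = rda,
           neutral = neutral, gf_adaptive = gf_adp, gf_neutral = gf_neu,
           cells_adaptive = om_adp, cells_neutral = om_neu,
           pop_adaptive = po_adp, pop_neutral = po_neu)
    })
  }

  say("-- summary")
  res$summary <- .stage("summary", .pipeline_summary(res, co, config))
  if (!is.null(res$summary)) {
    tsv(res$summary$populations, "summary_populations.tsv")
    tsv(res$summary$correlations, "summary_correlations.tsv")
  }

  manifest <- list(
    package = "loadscape",
    version = as.character(utils::packageVersion("loadscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, stages = config$stages, params = config$params,
    simulated = is.null(config$input_dir),
    input_checksums = checksums
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(config$out_dir, "manifest.json"))
  invisible(res)
}

.pipeline_summary <- function(res, co, config) {
  pops <- sort(unique(co$popmap$population))
  tab <- data.frame(population = pops, stringsAsFactors = FALSE)
  if (!is.null(res$stats)) {
    pi_tab <- res$stats[res$stats$stat == "pi" & res$stats$unit %in% pops, ]
    agg <- tapply(pi_tab$value, pi_tab$unit, mean, na.rm = TRUE)
    tab$pi <- as.numeric(agg[tab$population])
  }
  if (!is.null(res$roh)) {
    rep <- res$roh$report
    rep$population <- co$popmap$population[match(rep$sample, co$popmap$sample)]
    tab$f_roh <- as.numeric(tapply(rep$f_roh, rep$population, mean)[tab$population])
    tab$f_is <- as.numeric(tapply(rep$f_is, rep$population, mean)[tab$population])
  }
  if (!is.null(res$load)) {
    pp <- res$load$report$per_population
    idx <- match(tab$population, pp$population)
    tab$masked_load <- pp$masked_load[idx]
    tab$realized_load <- pp$realized_load[idx]
    tab$load_dellof <- pp$homozygosity_load_dellof[idx]
  }
  if (!is.null(res$offset)) {
    tab$offset_adaptive <-
      res$offset$pop_adaptive$offset[match(tab$population,
                                           res$offset$pop_adaptive$population)]
    tab$offset_neutral <-
      res$offset$pop_neutral$offset[match(tab$population,
                                          res$offset$pop_neutral$population)]
  }
  metrics <- setdiff(names(tab), "population")
  cors <- NULL
  if (length(metrics) >= 2) {
    prs <- utils::combn(metrics, 2)
    cors <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      a <- tab[[prs[1, i]]]
      b <- tab[[prs[2, i]]]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
        return(data.frame(metric_a = prs[1, i], metric_b = prs[2, i],
                          spearman_r = NA_real_, p_value = NA_real_))
      }
      lc <- landscape_correlation(a, b)
      data.frame(metric_a = prs[1, i], metric_b = prs[2, i],
                 spearman_r = lc$estimate, p_value = lc$p.value)
    }))
  }
  list(populations = tab, correlations = cors)
}
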