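# Synthesis: one pipeline run joining diversity, inbreeding, load and offset
# per population, with pairwise Spearman correlations (the population-level
# vulnerability panel), and the edge-versus-core contrasts.
source("analysis/00_settings.R")

res <- run_pipeline(pipeline_config(input_dir = COHORT_DIR,
                                    out_dir = "results/pipeline",
                                    seed = SEED))
s <- res$summary$populations
s$edge <- s$population %in% EDGE_POPS
print(s[order(-s$offset_adaptive), ], digits = 3)

cat("\npairwise Spearman correlations across the 13 populations:\n")
print(res$summary$correlations, digits = 2)

for (m in c("realized_load", "offset_adaptive", "offset_neutral", "f_roh")) {
  cat(sprintf("edge vs core mean %-16s %.4f vs %.4f\n", paste0(m, ":"),
              mean(s[[m]][s$edge]), mean(s[[m]][!s$edge])))
}
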