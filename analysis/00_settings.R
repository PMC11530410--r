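# Shared settings for the analysis workflow. Every numbered script sources
# this file; the seed fixes the whole study.
library(loadscape)

SEED <- 20240
COHORT_DIR <- "results/cohort"
dir.create("results", showWarnings = FALSE)

EDGE_POPS <- local({
  p <- sim_config()$pops
  p$population[p$edge]
})
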