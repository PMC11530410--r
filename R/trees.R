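# R-side wrapper around the compiled bagged-regression-tree engine
# (src/gf_forest.cpp). Population counts in genotype-environment work are
# tiny, but a forest is grown per locus, so the inner loop is compiled.

# Bagged forest for one response; split records (1-based variable index,
# threshold, impurity reduction) and OOB R^2 (negatives truncated to 0).
.bagged_forest <- function(X, y, n_trees, mtry, min_split) {
  .gf_forest_cpp(X, as.numeric(y), as.integer(n_trees), as.integer(mtry),
                 as.integer(min_split))
}
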