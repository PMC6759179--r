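#!/usr/bin/env Rscript
# Step 2: the primary linkage experiment, blocking on date of birth.
#
# Runs the full 17-profile matrix (exact and Jaro-Winkler string matching;
# Fellegi-Sunter, EM, EpiLink and deterministic weighting; both missing-data
# policies; the positive-only truncation pair) over the blocked candidate
# pairs, then scales, dense-ranks, ensembles, and evaluates every column
# against the MRN gold standard. All outputs land under results/dob/.

library(linkbench)

seed <- 20
ex <- run_experiment(experiment_config(generator = generator_config(seed = seed),
                                       block_var = "dob",
                                       out_dir = "results/dob"))
print(ex)

cat("\nPer-run weight summary (distinct weights, extremes, pairs at them):\n")
print(ex$summaries, row.names = FALSE)

cat("\nExact runs produce few distinct weights; inexact runs thousands.\n")
cat(sprintf("Rank-1 pairs agree across all exact runs: %s\n",
            length(unique(ex$gold_top$n_extreme_gold_yes[1:9])) <= 2))
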