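#!/usr/bin/env Rscript
# Step 3: accuracy of every run against the alloyed MRN gold standard.
#
# Reads the analysis file written by step 2 and reports, per run: the
# rank-1/rank-2 confusion metrics, the ROC AUC, and the agreement of the
# extreme-weight groups with the gold standard (the alloyed-gold population:
# top-ranked pairs whose MRNs disagree are mostly true matches with
# corrupted MRNs).

library(linkbench)

af <- read.csv("results/dob/analysis_file.csv", check.names = FALSE)
runs <- names(default_run_matrix())
gold <- af$gold

metrics <- do.call(rbind, lapply(runs, function(nm) {
  ranks <- af[[paste0("rank_", nm)]]
  cm1 <- confusion_at_rank(ranks, gold, 1)
  data.frame(run = nm,
             sens_rank1 = cm1$sensitivity, spec_rank1 = cm1$specificity,
             ppv_rank1 = cm1$ppv, npv_rank1 = cm1$npv,
             auc = roc_auc(af[[nm]], gold)$auc)
}))
metrics[-1] <- round(metrics[-1], 4)
print(metrics, row.names = FALSE)
write.csv(metrics, "results/dob/accuracy_by_run.csv", row.names = FALSE)

top <- read.csv("results/dob/gold_agreement_top.csv")
cat(sprintf("\nTop-ranked pairs not matching on MRN (alloyed gold): %d-%d per run\n",
            min(top$n_extreme_gold_no), max(top$n_extreme_gold_no)))
cat(sprintf("Share of rank-1 pairs agreeing with the gold MRN: %.1f%%-%.1f%%\n",
            100 * min(top$n_extreme_gold_yes /
                        (top$n_extreme_gold_yes + top$n_extreme_gold_no)),
            100 * max(top$n_extreme_gold_yes /
                        (top$n_extreme_gold_yes + top$n_extreme_gold_no))))
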