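#!/usr/bin/env Rscript
# Step 1: generate the paired synthetic EHR identifier datasets.
#
# Emulates a two-institution setting: an inpatient dataset (IPD) with one row
# per admission and an outpatient dataset (OPD) with one row per person,
# sharing ~30% of persons. Identifier errors (name typos, newborn
# placeholder names, compound-surname variants, missing gender) and a
# lightly corrupted MRN gold standard are injected at the configured rates.

library(linkbench)

seed <- 20
cfg <- generator_config(seed = seed)
scen <- generate_scenario(cfg)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
write_linkage_csv(scen$ipd, "results/data/ipd.csv",
                  sidecar_path = "results/data/ipd_truth.csv")
write_linkage_csv(scen$opd, "results/data/opd.csv",
                  sidecar_path = "results/data/opd_truth.csv")

cat(sprintf("persons: %d (overlap %.0f%%)\n", cfg$n_persons,
            100 * cfg$overlap_fraction))
cat(sprintf("IPD rows: %d (%.2f admissions/person)\n", nrow(scen$ipd),
            nrow(scen$ipd) / length(unique(scen$ipd$true_person_id))))
cat(sprintf("OPD rows: %d (one per person)\n", nrow(scen$opd)))

demo <- function(df) {
  c(`age <1` = mean(df$age < 1),
    `female` = mean(df$gender == "F", na.rm = TRUE),
    `missing gender` = mean(is.na(df$gender)),
    `missing MRN` = mean(is.na(df$mrn)),
    `unique first names` = length(unique(df$first_name)),
    `unique last names` = length(unique(df$last_name)))
}
tab <- rbind(IPD = demo(scen$ipd), OPD = demo(scen$opd))
print(round(tab, 4))
write.csv(tab, "results/data/demographics.csv")
cat("wrote results/data/{ipd,opd}.csv with truth sidecars\n")
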