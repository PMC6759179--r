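# linkbench

Benchmarking record-linkage algorithms on paired EHR identifier data.

## The problem

Healthcare records for the same person are scattered across non-interoperable
systems. Linking an inpatient dataset (IPD, one row per admission) to an
outpatient dataset (OPD, one row per person) on imperfect identifiers —
first name, last name, gender, date of birth — can be done with many
algorithm families, and packaged linkage tools differ in subtle dialects:
how they compare strings, how they weight agreements, and how they treat
missing values. `linkbench` implements those families in one coherent
framework, drives them with a synthetic generator that emulates the error
structure of real paired EHR identifier data, and scores every run against a
deliberately *alloyed* gold standard (a shared medical record number that
itself carries a small error rate).

## The methods

For each blocked candidate pair (records agreeing on DOB, or YOB in the
secondary arm) and each matching field *i*, a comparison outcome
γ<sub>i</sub> ∈ {agree, disagree, missing} (exact mode) or a Jaro-Winkler
similarity s<sub>i</sub> ∈ [0, 1] (inexact mode) is computed. Weights follow
four families:

- **Fellegi-Sunter (FS)**: W = Σ<sub>i</sub> w<sub>i</sub> with
  w<sub>i</sub> = log₂(m<sub>i</sub>/u<sub>i</sub>) on agreement and
  log₂((1−m<sub>i</sub>)/(1−u<sub>i</sub>)) on disagreement, where
  m<sub>i</sub> = P(agree | match) and u<sub>i</sub> = P(agree | non-match);
  defaults m = 0.95 and u = 1/(distinct values of the field).
- **EM**: the same weights with (p, m, u) estimated endogenously by
  expectation-maximization on a two-class conditional-independence mixture
  over the binary agreement vectors.
- **EpiLink**: the normalized score W = Σ s<sub>i</sub>w<sub>i</sub> / Σ
  w<sub>i</sub> ∈ [0, 1] with field weights w<sub>i</sub> =
  log₂((1−e<sub>i</sub>)/f<sub>i</sub>) from error rates and value
  frequencies.
- **Deterministic**: the count of agreeing fields, 0–3.

A 17-run matrix crosses these families with exact/inexact string matching
and the dialect flags real packages differ on (missing-value policy,
similarity conversion, positive-only output truncation). Weights are
min-max scaled, dense-ranked (rank 1 = highest), combined by two ensembles
(average scaled weight; rank-1-or-2 vote counting), and evaluated against
the MRN gold standard: confusion metrics at rank thresholds, ROC/AUC,
weight correlations, and PCA of the scaled weight matrix.

## Worked example

```r
library(linkbench)
ex <- run_experiment(experiment_config(seed = 20))
print(ex)
#> Linkage experiment (block: dob )
#>   IPD rows: 13669  OPD rows: 13000  candidate pairs: 17788
#>   runs: 17 (0 failed)  gold positives: 6260
#>   best single-run AUC (gold): 0.9942 (R/INEX/EM)
#>   ensemble AUC (gold): average 0.9935, vote 0.9917
```

A 20,000-person scenario (30% of persons in both sources) yields ~13.7k
deduplicated inpatient rows and 13k outpatient rows; DOB blocking compares
17,788 candidate pairs of which 6,260 share the gold MRN. Every run scores
AUC ≥ 0.98; exact runs produce 4–12 distinct weights while inexact runs
produce thousands, and all 17 runs place the same ~5.7k fully agreeing
pairs at rank 1 — the behavior differences concentrate in how partial
agreements and missing values are ordered below the top.

The numbered drivers under `analysis/` walk the full study: `01_simulate.R`
(generate and summarize the paired datasets), `02_link_dob.R` (the primary
DOB-blocked experiment; writes the per-pair analysis file and run
summaries), `03_evaluate.R` (accuracy per run against the gold standard),
`04_ensemble.R` (ensembles vs single runs over 20 seeds), `05_yob_blocking.R`
(the YOB-blocked secondary arm). Each writes its tables under `results/`.

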