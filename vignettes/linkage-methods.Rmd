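---
title: "Methods: benchmarking record-linkage algorithms on synthetic EHR identifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking record-linkage algorithms on synthetic EHR identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkbench)
```

## What this package models

`linkbench` compares record-linkage algorithm families under controlled,
regenerable conditions. The object of study is not one linker but the
*matrix* of choices a practitioner faces: exact versus Jaro-Winkler string
comparison; Fellegi-Sunter, EM-estimated, EpiLink, or deterministic
weighting; blocking on date of birth versus year of birth; and the dialect
flags on which packaged tools quietly differ (missing-value policy,
similarity-to-weight conversion, truncation of non-positive weights). Every
combination is run over the same candidate pairs so that the weights,
ranks, and accuracy of the runs can be compared pair by pair.

## The probability model behind the weights

For a candidate pair and field $i$, let $\gamma_i = 1$ if the field agrees
and $0$ otherwise. The Fellegi-Sunter weight is the log-likelihood-ratio
sum

$$W = \sum_i \gamma_i \log_2\frac{m_i}{u_i} +
      (1-\gamma_i)\log_2\frac{1-m_i}{1-u_i},$$

where $m_i = P(\gamma_i = 1 \mid \text{match})$ and
$u_i = P(\gamma_i = 1 \mid \text{non-match})$. Log base 2 is used
throughout (the standard convention; agreement on a two-valued field with
$m = 0.95$, $u = 0.5$ is then worth $\log_2 1.9 \approx 0.93$ bits).
Defaults follow packaged-tool behavior: $m_i = 0.95$ for every field and
$u_i$ the reciprocal of the field's distinct-value count. The harness
counts distinct values in the outpatient dataset — the larger source with
one row per person, hence the closest thing to a population frequency
table; `default_match_params()` takes the designated dataset as an
argument.

The EM engine estimates $(p, m, u)$ from the binarized agreement vectors
under a two-class conditional-independence mixture: the E-step computes
posterior match probabilities, the M-step re-estimates $p$, $m_i$, $u_i$
as posterior-weighted frequencies. Numerical choices: initialization
$m = 0.9$, $u = 0.1$, $p = 0.01$; convergence when the largest parameter
change drops below $10^{-6}$, capped at 500 iterations; estimates clamped
to $[10^{-6}, 1-10^{-6}]$ and flagged when they degenerate; fewer than two
distinct agreement patterns is reported as unidentifiable rather than
fitted. Identical vectors are aggregated into pattern counts first, so the
per-iteration cost is that of at most $3^{\,\text{fields}}$ patterns.
A caveat worth knowing: with three fields the mixture is just-identified
(eight pattern cells against seven free parameters), so the MLE tracks the
empirical pattern table and inherits its multinomial noise amplified by an
ill-conditioned inversion. The parameter-recovery test therefore asserts
accuracy of the mean estimate over five replicate fits of 50,000 vectors —
single fits can miss the generating $m$ by several hundredths while still
sitting at a *higher* likelihood than the truth.

The EpiLink engine scores
$W = \sum_i s_i w_i / \sum_i w_i \in [0,1]$ with field weights
$w_i = \log_2((1-e_i)/f_i)$; by default the error rates and frequencies
are tied to the M/U vocabulary ($e_i = 1-m_i$, $f_i = u_i$) so one
parameter set drives all engines. Missing fields drop out of numerator and
denominator; a pair with every field missing has no defined weight and is
flagged. The deterministic engine counts agreeing fields (0–3); its
inexact dialects either count similarities above a threshold or sum them
(the `fractional` flag), the latter producing the many-valued columns that
a threshold count cannot.

Jaro similarity uses the standard matching window
$\lfloor \max(|s_1|,|s_2|)/2 \rfloor - 1$ and half-transposition count;
the Winkler bonus $\ell \cdot 0.1 \cdot (1-j)$ uses the common prefix
capped at 4 and is applied unconditionally (the most common dialect; a
boost threshold is exposed for parity experiments). Empty strings score 0
by convention. Comparisons are case sensitive and names are never
standardized — deliberately, since the study design treats raw names as
given. Gender, a one-character field, keeps the exact trichotomy even in
inexact runs.

## Missing-value policies and the run matrix

Two policies reproduce the dialects observed across packaged tools in
exact mode:

- `zero_contribution`: a missing field adds zero weight. An all-disagree
  pattern with gender missing then ranks *above* an all-disagree pattern
  with nothing missing, and the complete patterns' 8 distinct FS weights
  become 9.
- `disagreement`: missing folds into disagreement, collapsing those two
  patterns — the 8-distinct-weight dialect.

The run-profile field is named for what each policy does. A third
conceivable reading — missing as a category with its own $m/u$ — is
numerically identical to `zero_contribution` when no missing-specific
probabilities are supplied, so it is not implemented separately.

`default_run_matrix()` fixes 17 named profiles: nine exact (FS/EM/EpiLink/
deterministic across the two missing policies) and eight inexact
(threshold-binarizing conversion at 0.95 for the R-style pair,
interpolating conversion for the rest, fractional deterministic, and a
positive-only-output pair that truncates non-positive weights from its
column, emulating a tool whose negative weights are unrecoverable).
Truncated pairs are carried as `NA`, scored as never-declared in every
metric, and contribute the run's minimum scaled value (0) to the average
ensemble — a choice the ensemble section revisits.

## The synthetic generator

The generator emulates the statistical structure of a paired
inpatient/outpatient EHR extract at desk scale. Defaults (all overridable
in `generator_config()`):

- `n_persons = 20000`, `overlap_fraction = 0.3`: 30% of persons appear in
  both sources; the remainder split evenly. Full-population scale remains a
  configuration choice.
- `admission_rate = 1.5`: each inpatient person contributes
  $1 + \mathrm{Poisson}(0.5)$ admission rows — matching a roughly 1.5:1
  row-to-person ratio in hospital data; the admission-count law itself is a
  modeling choice, as real marginal distributions are rarely published.
- Age-band weights with an infant mode (11.8% under 1 year) and ages capped
  at 90; DOB is drawn uniformly inside the band and age recomputed from DOB
  at a fixed reference date, so the two are consistent by construction.
- Name pools: deterministic syllable-built pools, 2,000 first names and
  20,000 surnames, sampled with Zipf exponent 1.1 — surnames are more
  diverse than first names, which is what makes surname agreement carry
  more weight under reciprocal-count U-probabilities.
- Error channels, independent per inpatient row: one random character edit
  per name field (`typo_rate_per_field = 0.02`), inconsistent compound
  surnames (0.02), missing gender (0.002). Newborns: 10% of infants carry
  the placeholder first name "Male"/"Female" with a distinct maternal
  surname on the inpatient side only — calibrated so roughly 1% of true
  match pairs fall in this channel, the order documented for real data.
- The gold standard: outpatient rows of overlapping persons lose or change
  their inpatient MRN with probability 0.0075 (split 77% different MRN /
  22% missing / 1% misassigned to another inpatient person), making MRN
  agreement an *alloyed* gold standard with a 0.5–1% error rate; 90% of
  outpatient-only persons have no inpatient MRN at all. The hidden
  `true_person_id` sidecar lets tests measure the gold-vs-truth gap
  directly.

What the generator does **not** emulate: real name frequency tables (the
syllable pools make unrelated names more alike than real names are, which
flattens Jaro-Winkler contrast), errors in DOB itself (so YOB blocking
never *gains* true matches here, it only adds non-match pairs),
addresses, twins, and within-source identity errors. Passing tests
demonstrate correct algorithmic behavior under these controlled
conditions, not performance claims about any particular real dataset.

## Preprocessing and blocking

Harmonization recodes gender and race through explicit tables (unknown
codes become missing, with counts logged), voids implausible ZIP codes
(anything but five digits), and re-extracts YOB from DOB. Names pass
through untouched. Deduplication removes rows identical on the seven-field
key (MRN, last name, first name, gender, YOB, race, ZIP; two missing
values compare equal), and a row whose only difference is a missing ZIP
loses to a sibling with a valid ZIP. Tie-break: the lowest `record_id`
survives; output order is stable by `record_id`. Blocking emits exactly
the cross-source pairs equal on a non-missing block value; records with a
missing block value are excluded and counted, since they can never agree
on the block.

## Scaling, ranking, ensembles

Weight columns are min-max scaled to [0, 1]; a constant column maps to all
zeros and is flagged rather than erroring, keeping degenerate scenarios
runnable. Ranks are dense (ties share a rank; rank 1 = highest), which is
what makes "pairs with the highest weight" a well-defined count per run.
The average ensemble is the plain mean of the 17 scaled columns; the vote
ensemble counts runs assigning rank 1 or 2.

On ensembles, the honest desk-scale finding (computed by
`analysis/04_ensemble.R` and the corresponding acceptance test): over 20
seeded default scenarios the average-scaled-weight ensemble's median AUC
sits within ~0.001–0.002 of, but *below*, the best individual runs. At
full population scale — hundreds of thousands of blocked pairs at a few
percent match prevalence — coarse exact runs pay a large AUC tie penalty
that averaging with granular columns relieves; at 17k pairs and ~36%
prevalence that penalty is small, and averaging in the weaker truncated
and inexact columns costs more than tie-breaking gains. The package keeps
the test at the stronger claim (ensemble ≥ every run) and reports the
result as measured.

## Problem sizes and budgets

Module tests run scenarios of 300–5,000 persons; rate-conformance checks
use 5,000 (three binomial standard errors); the ensemble study uses the
full 20,000-person default across 20 seeds; the YOB arm in the analysis
scripts uses 5,000 persons, since YOB blocking multiplies the candidate
set ~100-fold. These sizes are the package's chosen desk scale: large
enough for stable rates, small enough to re-run casually.

## Known limitations

- Pure-R Jaro-Winkler is fine at desk scale but is the bottleneck for
  million-pair candidate sets (the YOB arm at full size).
- U-probabilities are global per field; value-specific (frequency-based)
  U-probabilities are out of scope.
- The EM engine estimates from binarized vectors only; similarity-valued
  EM variants are not implemented.
- The positive-only truncation emulates a reporting artifact of one tool
  family generically; no attempt is made to reproduce any tool's internal
  weight scale.
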