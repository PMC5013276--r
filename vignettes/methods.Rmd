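---
title: "Methods: screen scoring, consensus targets and signature survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen scoring, consensus targets and signature survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirscreen)
```

This vignette documents the statistical procedures in `mirscreen`, the
assumptions they make, and the design choices taken where more than one
reasonable convention exists.

## 1. Screen scoring and miRNA classification

The screen stage takes a miRNA × protein matrix of readout changes from an
RPPA mimic screen, together with a per-protein annotation assigning each
protein an oncogenic or tumor-suppressor class and a pathway group (PI3K,
MAPK or cell cycle).

**Class-vector encoding.** The annotation is encoded as a signed vector,
+1 for oncogenic and −1 for tumor-suppressor proteins. A miRNA that
represses oncogenes and de-represses tumor suppressors then produces a
readout profile anti-correlated with this vector. The encoding is
symmetric: relabelling the two classes flips the sign of every correlation
and swaps the two miRNA labels, a property the test suite asserts. With a
±1 vector the Pearson correlation equals the point-biserial correlation
with the binary class, so a single cutoff on |r| applies to both
directions.

**Filters.** Two per-miRNA statistics gate classification:

- *Coefficient of variation*, CV = sd(x)/|mean(x)| (sample SD), computed
  across the miRNA's protein readouts. This removes flat profiles that
  carry no classifiable signal. A profile with exactly zero mean gets
  CV = ∞, i.e. it passes any finite cutoff — such a profile is maximally
  variable relative to its mean, not degenerate. Default cutoff: 0.25.
- *Class correlation*, r = cor(x, c), Pearson by default with Spearman as
  an option. Default cutoff: |r| ≥ 0.5.

Both cutoffs are inclusive (≥): a miRNA sitting exactly at a cutoff is
kept. Labels are `tumor_suppressor` (r ≤ −0.5), `oncomiR` (r ≥ +0.5), else
`unclassified`. A zero-variance profile has no defined correlation and is
reported `NA`/unclassified rather than erroring the whole screen.

Whether the CV should be taken per miRNA (across its protein readouts) or
per protein is a genuinely open choice; `mirscreen` computes it per miRNA
because the filter serves per-miRNA selection — a per-protein CV could not
remove an individual miRNA's flat profile.

**Pathway co-regulation and candidate selection.** For each pathway group
the signed effect of a miRNA is the mean of (readout change × class sign)
over the group's proteins: negative means the miRNA pushes that pathway's
oncogenic output down. Candidates are tumor-suppressor calls that are
"down" in all three groups, ordered by ascending r with the miRNA id as a
deterministic tie-break (so the list is invariant to input row order —
ties at identical r are common in noiseless simulations).

**Clustering.** Heatmap row ordering uses agglomerative hierarchical
clustering (Euclidean distance, average linkage) via `stats::hclust()`;
merge heights are verified against a brute-force O(n³) oracle in the
tests. Missing readouts are imputed to the row mean before clustering and
the imputation is reported.

## 2. Consensus target prediction

Per-database prediction tables are filtered with database-specific rules:

| database style | rule | note |
|---|---|---|
| TargetScan-like | conserved sites only | flag column |
| DIANA-like | miTG score > 0.7 | strict |
| PITA-like | ddG < −10 | strict |
| miRWalk-like | none | all records pass |

Thresholds are strict inequalities because the rules are comparative
("greater than", "less than"), not "at least". Within a database,
duplicate (miRNA, gene) records — multiple transcripts or site entries —
collapse to the best score before filtering (maximum for a greater-than
rule, minimum for a less-than rule); how such duplicates should be
resolved is not dictated by the rules themselves, and best-score
collapsing is the permissive choice.

The consensus set contains genes supported by at least `min_databases`
(default 2) of the filtered sets, with their supporting-database lists.
Consensus is monotone in `min_databases` (raising it can only shrink the
set), `min_databases = 1` gives the union and `= 4` the intersection;
these properties and agreement with naive membership counting are tested.
Pathway annotation is an exact-symbol set lookup in a GMT collection — it
is deliberately *not* an enrichment test, and no p-values are attached.

## 3. Target-network signature and survival

**z-scores.** Each signature gene is standardized across samples with the
population (divide-by-n) SD: z = (x − μ)/σ. Multiple probe rows per gene
are averaged per sample *before* standardization; averaging first keeps
the per-gene variance estimate on the quantity actually summed. A
zero-variance gene is an error naming the gene (its z-score is undefined).

**Score, normalization, split.** The network score of a sample is the sum
of its signature-gene z-scores; per-gene affine transforms of expression
(a·x + b, a > 0) leave it unchanged, which the tests assert. Min–max
normalization maps the scores to [0, 1]. The cohort is split at the median
score: strictly above → `high`, at or below → `low`. The inclusive tie
rule is deterministic and reproducible; with ties at the median the low
group absorbs them.

**Follow-up horizon.** Follow-up can be truncated at a horizon (default
configuration: 5 years for distant relapse-free survival): observations
beyond it are administratively censored at the horizon rather than
deleted, which preserves their at-risk contribution. Records without
survival information are dropped and reported.

**KM and log-rank.** Kaplan–Meier curves use the product-limit estimator
with the universal tie convention (deaths precede censorings at equal
times) and the log-rank test is the unweighted two-group Mantel–Haenszel
chi-square on 1 df, both via the `survival` package; the test suite checks
both against hand-rolled brute-force oracles to 1e-10. Score–readout
correlations (e.g. against phospho-protein levels) use Pearson by default
with Spearman optional, with two-sided p-values. No multiple-testing
correction is applied anywhere in the pipeline; p-values are reported raw
at the conventional 0.05 level.

## 4. What the synthetic generators emulate

`sim_screen()` plants tumor-suppressor miRNAs (expected readout
−effect on oncogenic, +effect on tumor-suppressor proteins) and mirrored
oncomiRs in Gaussian noise. Defaults are the pipeline's reference study
conditions: 733 miRNAs × 16 proteins (10 oncogenic / 6 suppressor,
pathways cycled over PI3K/MAPK/cell cycle), 20 planted miRNAs of each
kind, effect size 1.0 and noise SD 0.3 — an RPPA-like log-ratio scale
where planted effects are clearly but not trivially separable. Gaussian
noise is conventional for RPPA log-ratios; real screens additionally show
correlated noise across proteins sharing antibodies or pathways, which the
generator does not model, so recovery rates on synthetic screens are an
upper bound on real-data behavior.

`sim_prediction_tables()` treats the four databases as independent
detectors: a true target is detected with probability `per_db_recall`,
a decoy with `per_db_fpr`, and detected records always receive scores
passing that database's cutoff (plus sub-threshold noise records that
filtering must remove). Independence makes consensus inclusion of a true
target exactly P(Binomial(4, recall) ≥ 2), the closed form the acceptance
tests check. Real databases are correlated (shared seed-match logic), so
real consensus rates would differ.

`sim_cohort()` draws gene expression as per-gene Gaussians (means
U(6, 10), SDs U(0.5, 1.5), a log2-microarray-like scale) and event times
as exponentials with hazard `baseline_hazard ·
exp(log_hazard_per_unit_score · s)` where s is the min–max-normalized
signature z-score sum. Defaults: 216 samples (the scale of a typical
breast-cancer cohort), baseline hazard 0.08/year, 20% random censoring
(independent exponential calibrated against the baseline hazard) and a
10-year administrative horizon. The log-linear hazard is the simplest
process under which a median split yields separable KM curves; real
cohorts have non-proportional hazards, covariate structure and informative
censoring that the generator does not attempt.

`sim_ct_table()` shifts treated target Ct by −log2(fold) so the expected
ΔΔCt recovers the fold change exactly at zero noise.

All generators are deterministic under a fixed seed.

## 5. Problem sizes and numerical tolerances

The test suite exercises the oracle comparisons (Pearson, CV, linkage
heights, consensus counting, KM, log-rank) on ≥ 20 random small instances
each at 1e-10; screen recovery uses 50 simulated screens at the reference
conditions; null calibration of the log-rank test uses 200 cohorts of 100
samples with zero signature effect (KS uniformity at α = 0.01 and a
binomial check of the 5% type-I error); consensus calibration uses 500
prediction draws. These sizes give Monte-Carlo standard errors well below
the asserted margins while keeping the default test run to well under a
minute per file.

## 6. Known limitations

- The screen classifier's specificity depends on the panel size: with 16
  proteins the null distribution of r has SD ≈ 1/√15, so ~5% of inert
  miRNAs cross |r| = 0.5 by chance. Candidate lists from real screens of
  this size therefore contain chance calls by design of the cutoff, and
  downstream filtering (pathway co-regulation, literature) is part of the
  procedure, not an optional extra.
- ΔΔCt assumes equal amplification efficiency between target and
  housekeeping assays; no standard-curve correction is implemented.
  Multiple housekeeping genes are combined by arithmetic mean of their Ct
  values per record.
- The unpaired two-group test defaults to the classical equal-variance
  Student t (Welch available via `var_equal = FALSE`); degenerate
  zero-variance comparisons with equal means return t = 0, p = 1 by
  convention rather than erroring.
- Survival analysis is two-group KM/log-rank only: no Cox regression,
  hazard-ratio estimation or covariate adjustment, and no multi-group
  log-rank.
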