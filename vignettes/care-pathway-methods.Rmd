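---
title: "Care-pathway sequence analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Care-pathway sequence analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CarePathways)
```

# The model

A decedent's care pathway is the succession of daily *states* over the 365
days preceding death, each state one of five places of care: acute
hospitalization (`ACUTE`), rehabilitation (`REHAB`), hospital at home
(`HAH`), psychiatry (`PSY`) and home (`HOME`, which pools ordinary home,
community care and nursing homes — the claims perspective cannot separate
them, and neither does this package). A cohort's pathways are classified by
(i) computing an optimal-matching dissimilarity between every pair of
sequences, (ii) running Ward hierarchical ascending classification on the
dissimilarity matrix, and (iii) cutting the tree into a small number of
pathway clusters that are then described by chronograms, index plots, and
per-cluster cost and patient summaries.

## Optimal matching and the LCS identity

`omDistance(x, y)` is the minimum total cost of transforming `x` into `y`
with single-state insertions/deletions (indel cost 1) and substitutions
(cost 2 between any two distinct states), computed by the standard
dynamic programme; `dissimilarityMatrix()` evaluates all pairs in compiled
code, computing the upper triangle and mirroring it. Because one
substitution never costs more than a deletion plus an insertion, this cost
scheme induces the longest-common-subsequence metric

$$ d(x, y) \;=\; |x| + |y| - 2\,\mathrm{LCS}(x, y), $$

and the test suite asserts the identity *exactly* (not to a tolerance)
against a separate LCS kernel, alongside the metric axioms, the even-parity
property for equal lengths, and an exhaustive edit-script oracle for short
sequences. Both integer-cost and floating-cost schemes are supported; with
floating costs comparisons use a 1e-9 tolerance. State-dependent
substitution matrices can be supplied through `costScheme()`, but the
default constant scheme is the reference configuration: data-driven costs
are deliberately out of scope.

Distances are computed on the full 365-day sequences without run-length
compression. For equal-length sequences under the default scheme this is
exactly the LCS metric; compression would change nothing mathematically and
only complicate the kernels.

## Ward classification

`wardLinkage()` performs agglomerative clustering with Ward's
minimum-variance criterion via the Lance–Williams update, delegating the
recursion to `stats::hclust`. The default variant applies the update to
squared dissimilarities and reports heights on the original scale
(`ward.D2`); the alternative that consumes the dissimilarities as given
(`ward.D`) sits behind `variant = "raw"`. Which of the two a given
published sequence analysis used is rarely stated; the squared variant is
the default here because on Euclidean input its greedy merge order
coincides with the textbook "minimum increase in within-cluster sum of
squares" rule, which the tests verify exhaustively against a raw-coordinate
oracle for all configurations with up to seven points. Merge heights are
checked to be non-decreasing on every run.

Two practical caveats, both consequences of greedy agglomeration:

* **Ties.** Integer-valued OM distances can produce tied merge costs, and
  under ties the merge order — hence, occasionally, the partition — depends
  on input order. Permutation invariance is therefore guaranteed only for
  dissimilarities in general position; the tests check it on continuous
  Euclidean data and on structured sequence data, not on i.i.d. random
  sequences, where ties are pervasive and no tie-break rule can restore
  invariance.
* **Memory.** The linkage operates on a dense n × n matrix. The intended
  ceiling for a single analysis is n = 10,000 (the usual per-disease sample
  size in national analyses, ~800 MB); `samplePatients()` exists precisely
  to bring a population down to such a sample. The shipped tests and
  examples run at n ≤ 300, which exercises every code path at a fraction of
  the cost.

## Choosing and naming clusters

`selectK()` implements an elbow rule: for each candidate k it takes the
ratio between the height of the merge that would collapse k clusters into
k − 1 and the height of the last merge formed within k clusters, and
returns the k maximizing that relative drop. Published pathway typologies
in this field report 2 or 3 clusters without stating a selection rule, so
the rule is an explicit design choice; it is deterministic, falls back to a
configured default on exact ties or on degenerate all-zero-height trees
(e.g. identical sequences), and is allowed to return different k for
different disease populations. A fixed `k` can always be forced in the
pipeline configuration.

`nameClusters()` maps clusters onto the three canonical narratives using
two chronogram features: the overall share of days spent in any non-HOME
state, and that share restricted to the early window (all days before the
last 90). A cluster with early share > 0.20 is "early and repeated
hospitalizations"; otherwise overall share > 0.15 yields "acute care during
the last 3 months of life"; the rest are "few and late hospitalizations".
The early threshold is set comfortably above the non-HOME share that
per-day noise alone induces (at the default 5% noise, roughly 0.05 plus the
late-pathway template's 0.11 early share), so the intended narrative is
recovered under the generator's default noise; both thresholds are
arguments, not constants.

# The synthetic cohort generator

Real national claims data are access-restricted, so the generator is a
first-class, tested module that emulates the features of a decedent claims
cohort that the analysis consumes — with ground truth attached.

**Cohort marginals** (`cohortConfig()`): defaults reproduce the published
2015 French decedent cohort: 50.6% women; age at death normal with mean
78.5, SD 14.9 years, truncated to [1, 110] by rejection; nine diagnosis
flags with the published prevalences (dementia 19.0%, COLD 17.3%, breast
cancer 2.3%, ...); Charlson index drawn as a rounded truncated normal
(mean 4.3, SD 3.7) rather than computed from codes — the code-mapping
algorithms are external and out of scope; deprivation quintiles with
published weights and a 6.7% missing category (the five weights are
conditional on non-missing, since the published table carries "Missing" as
its own row); 27% hospital palliative-care use as a flag (in real data it
comes from a dedicated admission code with no synthetic analogue); and a 5%
zero-spend fraction.

**Sequences** (`archetypeConfig()`, `simulatePathways()`): each patient is
assigned one of K archetypes by mixture weights (default 0.67/0.27/0.06,
the published dementia cluster proportions), the archetype's segment
template is expanded to 365 days, and each day is independently resampled
with probability `per_day_noise` (default 5%) to a uniformly chosen other
state. Independent noise is a deliberate simplification — real claims noise
is autocorrelated — chosen because it keeps recovery behaviour analyzable:
the expected within-archetype OM distance has a closed form ceiling, and
cluster recovery can be tested at a known noise level. The three default
templates encode the canonical narratives: (1) home for 351 days then a
14-day terminal acute stay; (2) home for 245 days then alternating
acute/rehabilitation blocks through the last 120 days; (3) repeated acute,
rehabilitation and hospital-at-home blocks starting in the first month.

**Place of death**: the templates end in hospital states, so a
`hospital_death_fraction` (default 0.59, the published hospital-death
share) is applied *after* noise: patients drawn as home deaths have the
template's trailing non-HOME run — capped at 30 days — replaced by HOME;
hospital deaths keep the template's terminal state on the last day. Doing
this after noise makes the final-day marginal exactly Binomial(n, 0.59).
Setting the fraction to `NA` disables the adjustment, restoring the exact
noiseless identity "sequence = template expansion" that the recovery
oracles rely on; the cluster-recovery checks run in that mode because the
adjustment is a calibration layer on top of the archetype model, not part
of it.

**Claims** (`costConfig()`, `simulateClaims()`): every inpatient day emits
a per-diem claim in the matching category; psychiatry days are costed into
the "physiotherapy and other services" category because the published
11-category breakdown has no psychiatry row and its footnote folds
psychiatric services into "other services". Ambulatory categories are
time-inhomogeneous Poisson event streams whose rates are multiplied
(default ×3) during the last 90 days, with lognormal event costs
(`sdlog = 1`) — matching the heavy right skew of published expenditure
tables, where means sit far above medians. Zero-spend patients are drawn at
the cohort level and suppressed entirely. Default per-diems (€420 acute,
€215 rehabilitation, €235 hospital-at-home, €300 psychiatry) and event
rates were chosen once so that category means land in the range of the
published tables under the default archetype mix; they are plumbing
defaults, not estimates.

Ground-truth archetype labels travel in a separate return value (and a
separate `ground_truth.csv` in the pipeline), and no analysis function
accepts them: recovery validation is the only consumer.

What passing tests on this generator do *not* show: robustness to
autocorrelated noise, to archetypes that differ between diseases, to
informative missingness in deprivation, or to cost–pathway dependence
beyond what per-diem accounting induces. The generator fixes the marginal
structure; it does not reproduce the joint dependence structure of real
claims.

# Costing conventions

* Means, SDs, medians and quartiles are over **all** cohort patients,
  zero-spend included; "% users" carries the user share separately. This
  makes category means sum *exactly* (same summation order) to the
  total-row mean, an identity the tests assert and the acceptance script
  recomputes from the published category means.
* The IQR is reported as the single width Q3 − Q1, with
  linear-interpolation quartiles (`stats::quantile` type 7).
* The "last 3 months" window is 90 days, configurable.
* The top expenditure decile counts N − floor(0.9 N) patients; membership
  ties at the threshold are broken by a stable rank on patient id; the
  threshold is the smallest total inside the decile.
* Full precision is kept everywhere; rounding to whole euros and
  one-decimal percentages happens only in `runReport()`.

# Descriptives and the association model

Age bands follow the published table's nine bands interpreted as half-open
intervals `[lower, upper)` with open ends `<20` and `≥90`; Charlson classes
are 0, 1–2, 3–4, ≥5; place of death is the state on the final day of the
sequence. The odds-ratio stage (`pathwayAssociation()`) is a standard
maximum-likelihood logistic regression of membership in a designated
cluster versus the rest (`stats::glm`), reporting exponentiated
coefficients with Wald 95% intervals; it refuses to report when the outcome
is constant or the fit shows (quasi-)perfect separation (detected by
convergence failure, all-extreme fitted probabilities, or runaway
coefficients), because silently exponentiating a divergent coefficient is
worse than an error. In the orchestrated pipeline that error is downgraded
to a warning and an empty association table, since small demo cohorts with
rare diagnosis flags quasi-separate routinely.

# Degenerate inputs and numerical conventions

* Sequences of any positive length are accepted by the distance kernels
  (tests use short sequences extensively); the 365-day length is enforced
  where the day-of-death semantics matter.
* The day of death is itself a sequence element (column 365): "the year
  before death" is taken to include its endpoint. This is a convention the
  source analyses leave ambiguous; episode encoding (`encodeDailyStates()`)
  documents it and the window length is an argument.
* Episodes overlapping on a day resolve by fixed care-intensity priority
  `ACUTE > REHAB > HAH > PSY > HOME`; stays crossing the 365-day boundary
  are truncated at the boundary.
* Dissimilarity matrices are validated to symmetry within 1e-9 and
  non-negativity; chronogram rows and cluster cost shares are checked to
  sum to 1 within 1e-9 and 1e-12 respectively.
* `cutTypology()` renumbers cluster labels in order of first appearance so
  labels are stable across runs; all k clusters are guaranteed non-empty by
  construction of the tree cut.

# Problem sizes

The shipped test suite and the acceptance script run the pairwise analysis
at n = 300 sequences of length 365 (≈45,000 OM distances), the generator
calibration at n = 10,000 patients, the Ward oracle at n ≤ 7 over 50
random instances, and the OM/LCS identity at 500 random pairs — sizes
chosen so that the whole validation suite completes in minutes on one core
while still exercising each component well above its asymptotic regime.

# Known limitations

* Greedy Ward on tied integer distances is order-dependent (above); for
  strict reproducibility keep input order fixed, as the pipeline does.
* The chronogram-based naming rule assumes pathway clusters that differ in
  hospital-day timing; typologies driven by psychiatry or hospital-at-home
  mixes would need different features.
* The generator's costs are per-diem-constant within hospital states, so
  within-cluster cost variance is lower than in DRG-priced reality.
* No inflation adjustment, payer/patient cost splitting, or DRG logic: all
  costs are taken as given in the claims input.
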