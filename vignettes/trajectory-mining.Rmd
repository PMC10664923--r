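---
title: "Methods: matched-sampling trajectory mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-sampling trajectory mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trajmine)
```

This vignette is the package's account of its statistical method: the model
behind each stage, the parameters that matter and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where the design was genuinely
open. Everything empirical referenced here is computed by the test suite or
by `scripts/acceptance.R`; the vignette itself states no number the code
does not reproduce.

## Data model

The unit of analysis is a *normalized event history*: per patient, the
**first** dated occurrence of each analysis-level code, date-sorted. Three
normalization steps precede everything else:

* **Level mapping.** ICD-10 codes are replaced by their hierarchy ancestor
  at the analysis depth (chapter = 0, block = 1, three-character category =
  2, subcategory = 3). The numbering is a package convention: the default
  `--lvl 2` then corresponds to three-character-category granularity, which
  matches the label granularity a practitioner expects in the output
  graphs. In CCSR mode, codes map to their Clinical Classifications
  Software Refined category regardless of level. Treatment codes (`TX:`
  prefix) bypass mapping entirely. ICD-9 codes are carried as opaque
  codes unless a crosswalk maps them; the cohort-defining anchor codes
  (`C67`, `188`, `Z85.51`, `V10.52` by default) are matched on the *raw*
  history by prefix, before mapping and deduplication.
* **Exclusion.** Whole chapters can be excluded (default: pregnancy,
  perinatal, external causes, health-status factors), with an explicit
  whitelist that wins over exclusion so personal-history anchor codes
  survive. Exclusion is closed under descendants by construction because
  membership is tested on the ancestor chain.
* **First-occurrence semantics.** Only the first occurrence of each mapped
  code enters the analysis. Diagnoses are treated as one-time onset events;
  repeat billing rows would otherwise inflate pair counts without adding
  information about progression.

## Stage 1: pair statistics

### The estimator

For an ordered pair (A, B), with a gap window `[g_min, g_max]` in whole
days:

* Exposed group `P1`: every stratifiable patient with A. A patient is
  *stratifiable* if sex and birth year are known; strata are
  (sex, birth-year bin) with `nofAgeGroups` equal-width bins over the
  observed birth-year range.
* Per iteration, a comparison group is drawn: in each stratum, as many
  unexposed patients (without A, sampled without replacement) as the
  stratum has exposed ones. Each sampled patient inherits a *reference
  date* from the exposed side: the stratum's exposure dates sorted
  ascending, matched by rank to the sample order. The comparison count
  `c_i` is the number of sampled patients whose B falls in
  `[g_min, g_max]` after their reference date.
* `RR = (n_AB / |P1'|) / (mean_i c_i / |P1'|)`, where `n_AB` counts exposed
  patients with B in the window after their own A, and `P1'` is the
  truncation-adjusted exposed set (below).
* The empirical p-value uses the add-one (Davison–Hinkley) form
  `p = (1 + #{i : c_i ≥ n_AB}) / (iterations + 1)`, so `p` can never be
  exactly zero and its floor is `1/(iterations + 1)`.

Three conventions deserve justification because the underlying design was
open:

* **Reference dates.** Counting "B after not-A" needs a time anchor for
  patients who never had A. Rank-matching within stratum (sorted exposure
  dates against the randomly ordered sample) gives every unexposed patient
  a well-defined, reproducible anchor whose marginal distribution equals
  the stratum's exposure-date distribution. The alternative — counting B
  anywhere in the unexposed history — overcounts the comparison rate for
  late-exposure strata and is only used in *exhaustive mode* (below).
* **Truncation.** If a stratum holds fewer unexposed candidates than
  exposed patients, both sides shrink to the available minimum (the first
  k exposed in patient-table order, a deterministic choice) and the
  shortfall is recorded. This keeps the two groups size-matched per
  stratum instead of silently reweighting. A pair whose exposure covers
  every stratifiable patient has no possible comparison group and is
  flagged *unsampleable* — this is why the cohort-defining anchor
  diagnosis can never itself appear in a trajectory: every patient carries
  it.
* **Exhaustive mode** (`--exhaustive-sampling`) replaces the sampling
  design with the classical two-cohort estimate: comparison group = all
  stratifiable unexposed patients, B counted by presence, one
  deterministic iteration. It exists as a validation bridge: the test
  suite checks it exactly against a brute-force oracle, and checks the
  sampled estimator against the closed-form expectation of the matched
  design (enumerating every stratum) to within 5% at 2,000 iterations.

### Selection, directionality, multiple testing

Pairs are selected when `RR > 1`, `p < alpha` (default 0.05) and at least
`minPatients` exposed patients develop B in the window. When both
orientations qualify, a two-sided exact binomial test (`stats::binom.test`
at p = 0.5) on how many both-code patients had A first versus B first keeps
the significant majority direction; ties and non-significant splits drop
both orientations.

Multiple-testing correction across pairs is available
(`p_adjust = "BH"`/`"bonferroni"`) but **off by default**, deliberately.
The empirical p-value is bounded below by `1/(iterations + 1)`; with the
default 400 iterations and the ~10^6 ordered code pairs of a full
ICD-10 level-2 scan, Benjamini–Hochberg at α = 0.05 could never reject
anything — every p-value sits above its BH threshold by construction. A
correction only becomes meaningful when `iterations` is scaled with the
number of tested pairs, so it is exposed as an explicit choice rather than
a default. The pair-level α should be read as a screening threshold
(selection also demands `RR > 1` and `minPatients` supporters); the
false-positive behaviour at the default settings is quantified directly by
the type-I acceptance test (fraction of null pairs with p < 0.05 stays
near α).

### Determinism and parallelism contract

Every pair draws from its own RNG stream seeded by a hash of
`(seed, A, B)`. Results are therefore bit-identical however the pair list
is ordered or split into work units (`workers` only partitions the
iteration space), which is asserted by the test suite.

## Stage 2: trajectory building

Selected pairs seed partial trajectories; a partial ending in Y extends
with every selected pair (Y, Z) whose Z is not already in the sequence,
provided the extended sequence keeps at least `minPatients` supporters — a
patient supports a sequence iff all its first-occurrence dates are strictly
increasing with every consecutive gap inside the window. Supporter sets are
carried along and intersected at each extension, which is simultaneously
the pruning device and the proof of support anti-monotonicity (asserted at
run time).

Only *maximal* trajectories are emitted: a partial is finalized when no
extension succeeds or it reaches `maxTrajectoryLength`; finalized sequences
shorter than `minTrajectoryLength` are discarded. The alternative reading —
also reporting extendable intermediate lengths — is available as
`--emit-prefixes`. Output is deduplicated on the code sequence (one
sequence can be reached through several extension orders), sorted
lexicographically, and numbered from 1, making trajectory IDs reproducible.
The construction is validated against an exhaustive enumerator of all
admissible sequences on randomized small cohorts.

## Stage 3: clustering

Two graph modes:

* **Trajectory mode** (default): nodes are trajectory IDs; edge weights are
  the Jaccard similarity of the trajectories as code sets. Assignment is
  total by construction — each trajectory belongs to its own node's
  cluster.
* **Code mode** (legacy): nodes are event codes, one edge per selected
  pair, weighted by the count-based Jaccard index (trajectories containing
  the consecutive pair over trajectories containing either code). A
  trajectory is assigned only if *all* its codes land in one cluster;
  cross-cluster trajectories stay unassigned. The mode is retained as a
  comparison baseline, and the acceptance script reports its unassigned
  fraction on the same trajectories the trajectory mode assigns completely.

The Markov Cluster algorithm is implemented natively on sparse matrices:
self-loops equal to each node's maximum incident weight (floor `1e-6`),
column normalization, then alternating expansion (matrix squaring) and
inflation (elementwise power, default 2.0) with pruning of entries below
`1e-5`, until the largest entry change drops under `1e-8` or 200
iterations (non-convergence keeps the current interpretation and sets a
flag). Clusters are read from attractor rows; overlapping claims resolve
to the lowest cluster index; unclaimed nodes become singletons. Cluster
labels are 0-based in decreasing size order (ties: smallest member
position), so "cluster 0" is always the largest. Inflation, pruning and
the tie-breaks are package conventions — standard MCL practice — chosen
once for determinism; the implementation is cross-checked against an
independent dense-matrix reference on bridged-clique graphs.

## The synthetic-data generator

`sim_config()`/`generate_cohort()` emulate exactly the statistical
structure the estimator assumes:

* demographics: configurable sex ratio and uniform birth years;
* an **anchor code** every patient carries (uniform early onset) —
  mirroring a cohort defined by a qualifying diagnosis, and regression
  testing the fact that an all-carrier code is unsampleable;
* **background codes**: per-patient event counts Poisson in
  `hazard × observation years`, dates uniform over the window; optionally
  age-linked through a birth-cohort multiplier
  `exp(age_slope × (age_mid − 70)/10)` (age at mid-observation), so the
  confounder is constant within sufficiently fine birth-year strata — the
  construction used to verify that matched sampling rejects a
  crude-RR-elevated but conditionally independent pair;
* **planted chains**: carriers enrolled at a configurable fraction receive
  the chain codes sequentially with per-transition penetrance and uniform
  gap distributions; `expected_truth()` derives the analytic expected
  support and a recoverability verdict for every planted pair and chain
  (a gap range outside the analysis window marks the chain unrecoverable).

What the generator does **not** model: realistic ICD code frequencies and
co-morbidity correlation structure, care-pathway dynamics (visit
clustering, censoring, mortality), repeat-billing artefacts beyond the
Poisson draw, regional or provider structure, and measurement error.
Passing the recovery tests therefore shows the pipeline correctly inverts
its own generative assumptions — elevated conditional incidence inside a
time window — not that it is robust to every artefact of real claims data.

## Numerical choices and degenerate inputs

* **Day arithmetic.** All gaps are whole days; `"6M"` = 183 days, `"5Y"` =
  1826 days, `"1D"` = 1 day (months 30.5 d, years 365.25 d, floored).
  Window bounds are inclusive.
* **Age.** De-identified inputs carry birth year only, so age at the
  anchor event is calendar-year subtraction; age bins are equal-width over
  the observed birth-year range with the maximum clamped into the last
  bin.
* **Zero comparison rates.** A pair whose comparison groups never develop
  B gets `RR = +Inf` with the p-value computed as usual; infinite RRs
  survive the `.tab` round trip.
* **Empty inputs.** An empty selected-pair list yields an empty trajectory
  set (not an error); empty selections produce header-only output files;
  a failing pipeline stage removes partial outputs and names the stage.
* **Data-quality guard.** Event rows with unparseable dates or unknown
  patient IDs are dropped with counters; above 10% dropped rows the run
  aborts.
* **No timestamps** appear in any output file, so identical seeds produce
  byte-identical runs.

## Validation problem sizes

The test suite validates at sizes chosen to make the statistical checks
sharp while keeping a full run in minutes on one core: exact-oracle
equivalence on a 200-patient cohort; sampling consistency at 2,000
iterations; planted-chain recovery on twenty 5,000-patient cohorts with
three chains each (penetrance 0.5–0.7, carrier fractions 0.10–0.15,
`minPatients` 20, 200 iterations); type-I control and confounding
rejection over twenty seeds each. The acceptance script reuses the
5,000-patient design for its headline numbers.

## Known limitations

* The comparison-group reference-date convention, while reproducible, is
  one of several defensible anchorings; estimates for pairs whose exposure
  dates are concentrated late in the observation window lean on short
  follow-up for both groups.
* First-occurrence semantics ignore recurrence and severity progression
  coded as repeat diagnoses.
* Matching is on sex and birth-year bin only; other confounders
  (region, comorbidity burden) are uncontrolled unless expressed through
  patient filters.
* MCL granularity depends on inflation; the default 2.0 is a convention,
  not a fitted value, and small weight perturbations near cluster
  boundaries can move individual trajectories between clusters.
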