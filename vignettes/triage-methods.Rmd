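---
title: "Methods: pediatric OSA triage, oximetry scoring and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pediatric OSA triage, oximetry scoring and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osatriage)
```

## The problem and the model

Children referred for suspected obstructive sleep apnea may end up with
either of two specialties: otolaryngology (ENT), when adenotonsillar
hypertrophy makes tonsillectomy and/or adenoidectomy (AT) likely, or
pediatric respirology, when the cause is more plausibly rhinitis, reflux,
restless-leg symptoms or non-surgical disease. The package implements three
fixed, published decision trees that make that routing decision from
referral-letter data, together with the oximetry scoring and the
diagnostic-evaluation machinery needed to study them.

The trees are not fitted here — they are published clinical logic, encoded
verbatim. What the package adds around them is engineering: deterministic,
auditable rule evaluation (every decision carries a replayable
`rule_path`), a full McGill oximetry scoring (MOS) pipeline from raw SpO₂
samples, closed-form and simulation-based evaluation, and a calibrated
generator that reproduces the statistical structure of the source clinic
sample so everything is testable without patient data.

Key modelling conventions, fixed throughout:

* **Positive prediction = ENT referral; positive outcome = AT received.**
  This is the only convention under which the published table's PPV equals
  the printed AT rate among ENT-routed children, so all metrics use it.
* **Prior-AT dominance.** A child with a prior AT is routed to respirology
  by all three trees before any other rule is considered (in the source
  cohort no such child had repeat surgery).
* **Missing screen flags never fire a rule.** The trees route every child;
  a missing RLS/GERD/NOSE flag or PSQ item simply pushes the child to later
  rules. No imputation is performed anywhere.
* **Records with a missing AT outcome** are excluded from evaluation with a
  reported tally; they still receive triage decisions.

### Rule order in the PSQ tree

The published figure is narrative, so the rule order follows the written
sequence with its residual group sizes: prior AT, then 4/4 PSQ items
positive (ENT), then RLS (respirology), then GERD-or-NOSE (respirology),
then 3/4 PSQ (ENT), then residual respirology. Because the narrative's
stratum sizes do not sum to the stated cohort size, the implementation
records the full rule path per child rather than committing to any
bookkeeping convention; any convention can be audited after the fact.

## McGill oximetry scoring

The source publication assigns the MOS "based on the number and depth of
oxygen desaturations" but does not restate numeric criteria; those live in
the scoring scheme it cites. The pipeline therefore exposes every
threshold in `mos_config()` rather than hard-coding any of them:

| parameter | default | units | role |
|---|---|---|---|
| `min_drop` | 4 | % SpO₂ | fall below running baseline defining an event |
| `min_event_duration` | 10 | s | shortest episode counted |
| `baseline_window` | 120 | s | trailing median window for the baseline |
| `cluster_window` | 600 | s | max gap joining an event to the current cluster |
| `min_events_per_cluster` | 5 | events | cluster qualification |
| `required_clusters` | 3 | clusters | abnormality gate |
| `depth_thresholds` | 90/85/80 | % SpO₂ | nadir tiers for scores 2/3/4 |
| `required_deep_events` | 3 | events | events below a tier threshold |
| `artifact_floor` | 70 | % SpO₂ | isolated values below are artifact |
| `max_jump` | 25 | %/sample | spike-rejection bound |
| `min_study_duration` | 14400 | s | below this the report is flagged "short study" |

Numerical choices worth knowing:

* **Baseline is a trailing 120-s median**, not a whole-night mean, so slow
  drift cannot mask events; the window includes the current sample, which
  is negligible because an event occupies well under half the window.
  The first window is back-filled with the median of the first full window.
* **Strict inequalities at nadir tiers**: a nadir of exactly 90.0 does not
  count as "below 90". This follows the "drops <90%" phrasing conventional
  in the MOS literature and is asserted by test.
* **Tie-breaks and degenerate inputs**: clustering is greedy
  left-to-right, so the partition is unique; an empty event list scores 1;
  a trace shorter than two samples is rejected; short studies are scored
  but flagged rather than refused.
* **Artifact rejection is deliberately conservative**: only isolated
  single-sample excursions (sub-floor values or same-direction spikes
  beyond `max_jump` against both neighbours) are dropped. A sustained 75%
  plateau is physiology and is kept.

Monotonicity is a design invariant: deepening any event's nadir, or adding
an event, can never lower the assigned score. The tests exercise this on
hundreds of perturbed event configurations.

## The synthetic cohort generator

`generate_cohort()` emulates the source clinic sample. The generative
order is: demographics → prior AT → tonsil grade → MOS given tonsil
stratum → AT outcome given the (prior, tonsil, MOS) stratum → screen
answers given the AT outcome. Screens are drawn *conditionally on the
outcome* because per-outcome positivity proportions are the only joint
information the source reports. All randomness flows from one seed through
a fixed per-field sub-seeding scheme, so a field block is reproducible in
isolation and a cohort is byte-identical under the same seed.

Calibration defaults taken directly from the published sample: 47% female;
age truncated-normal (8.19, 3.59²) on [0.5, 18); prior AT 18/469; ever
snore 93.7%/87.0% by outcome; snoring more than half the night 306/418 of
snorers; the tonsil 2–4 arm's MOS strata 21/122/24 of 167 with AT rates
0.78/0.50/0.71; tonsil 0–1 AT rate 0.17; screen positivity per outcome
from the published demographics table.

Where the source is silent, one value was chosen and documented, and is
not revisited:

* **Tonsil-grade marginal.** The published tree strata cover 230 children
  (63 with grades 0–1, 167 with 2–4) of 469; the remainder is assigned to
  "missing grade", the only reading consistent with the figures. Within
  the printed pooled "grade 3 and 4" group the split 52/35 was chosen to
  preserve the 167 total; nothing downstream depends on the split, only on
  the 0–1 / 2–4 / missing partition.
* **AT rate in the missing-tonsil stratum**: 0.17, matched to the low-grade
  arm; the source gives no rate for these children.
* **MOS outside tonsil 2–4**: P(MOS ≥ 2) = 0.03, consistent with the
  overall 30/443 prevalence of MOS 2+ once the 21 in the ENT arm are
  accounted for; MOS within "2+" split 0.60/0.25/0.15 over 2/3/4
  (unreported; only the 2+ vs 1 boundary matters to any tree).
* **Symptom-count magnitudes** (e.g. how many RLS symptoms a positive
  screen carries) are arbitrary small counts on the correct side of each
  screen's threshold; only the thresholded flags enter any analysis.

`stratum_expected_metrics()` is the analytic oracle: total probability
over the routing strata gives the population sensitivity, specificity, PPV
and NPV implied by a calibration. For the tonsil-based trees the generator
parameterises exactly those strata, so empirical metrics on large cohorts
converge to the oracle (tested at n = 20,000 within 0.02 absolute, a size
chosen to make Monte-Carlo error comfortably smaller than the tolerance).
For the PSQ tree the oracle instead uses the published stratum weights
(18/66/318/33/3/31 over 469) and rates (0/0.56/0.25/0.32/0.50/0.10),
because the generator's screen model — items independent given outcome,
with an optional exchangeable-correlation knob `psq_item_corr` — implies
its own PSQ-tree strata that need not reproduce the published ones. This is a real fidelity limit of the generator, not a
bug: the source gives no joint distribution of the four items with the
RLS/GERD/NOSE flags, and matching all published marginals and all tree
strata simultaneously is over-determined. Passing tests therefore show
that the tonsil-tree strata are recovered and that the PSQ closed form
reproduces the published sensitivity/specificity (0.29 vs printed 0.28 and
0.91, from the published stratum sizes themselves); they do not show that
simulated PSQ-tree metrics match the clinic's.

The published model-metric table is itself not fully self-consistent: the
PSQ model's printed LR+ (3.18) and OR (4.03) do not follow from its own
rounded sensitivity and specificity (0.28/0.91 give 3.11 and 3.93), while
the tonsil model's do. The acceptance tests assert the identities the
printed numbers actually satisfy and document, rather than chase, the
discordance. Likewise the published univariate odds ratios are not
reproducible from the printed counts (row-wise missing denominators are
the likely cause); `odds_ratio_2x2()` computes correctly from whatever
counts it is given and no attempt is made to reverse-engineer the paper's
denominators.

## Trace simulation

`generate_trace(target_mos, ...)` builds a synthetic night: baseline
97% ± 0.4% Gaussian noise, and for targets ≥ 2, three clusters of six
trapezoidal desaturations (30 s long, 60 s apart, clusters separated by
more than the clustering window) with nadirs drawn strictly inside the
target tier's band — 86–89% for target 2, 81–84% for 3, 72–79% for 4 —
so the trace scores to its target under the same configuration. The
default simulated duration is 7,200 s: long enough for the required
cluster structure with margin, short enough that round-trip tests over
hundreds of traces stay cheap; real overnight studies are longer and the
scorer flags the difference as "short study" without changing the score.
Round-trip fidelity (≥ 95% per tier, 100 traces each) is part of the
acceptance suite.

## Statistical components

2×2 odds ratios use the cross-product with a Wald interval on the log
scale (SE = √(1/a+1/b+1/c+1/d)); with the Haldane option, 0.5 is added to
every cell when any cell is zero. Two zero cells sharing a margin with no
correction yield an explicit undefined marker, not a number. The
covariate-adjusted odds ratio is a maximum-likelihood logistic regression
(`stats::glm`, IRLS, convergence 1e-8 within 100 iterations) with the
covariate as indicator contrasts; |log-OR| > 15 is reported as separation
rather than returned as an estimate. With a single binary predictor and no
covariate the logistic estimate equals the cross-product odds ratio; the
tests verify this equivalence to 1e-6 on 1,000 random tables, and the
metric identity suite (TPR+FNR = 1, DOR = LR+/LR−, …) to 1e-12.

Report display rounds half away from zero to 2 decimals, matching the
source table's presentation; all internal computation keeps full
precision.

## Problem sizes

Default test and acceptance scales, chosen to keep Monte-Carlo error well
inside each tolerance: stratum-rate recovery on one 100,000-child cohort
(3-binomial-SE bands); generator marginals at n = 20,000; oracle
convergence at n = 20,000 (0.02 absolute); trace round-trips 100 per tier
in acceptance and 12 per tier in the unit suite; logistic coverage at
n = 5,000 × 40 replicates.

## Known limitations

* The decision trees are encoded from the published narrative; the figures
  themselves were not machine-readable, and the narrative's stratum sizes
  do not reconcile exactly with the stated cohort size.
* MOS numeric criteria follow the cited scoring scheme's conventional
  values; a site using different criteria must supply its own
  `mos_config()` — discordance there is configuration, not code.
* The generator draws screens independently given outcome (up to the
  optional correlation knob) and models the surgeon only as a uniform
  categorical label with no effect on outcome; surgeon-level confounding
  must be injected by the user when studying adjusted estimators.
* No EDF oximetry parsing, no pulse-rate channel, no apnea–hypopnea index,
  and no attempt to predict post-operative symptom resolution.
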