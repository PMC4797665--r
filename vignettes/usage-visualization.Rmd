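---
title: "Visualizing and testing usage of web-based interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing and testing usage of web-based interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usageviz)
```

## The problem

Web-based behavioural interventions log every page view: who, which page,
when, and for how long. These logs answer the questions engagement
research cares about — where in the programme usage drops off, which
components get revisited, and whether usage patterns relate to
participant characteristics or outcomes — but only if the analyst can see
them. `usageviz` renders the whole cohort's usage as stacked
per-participant sequences and then carries any pattern the analyst spots
through cohort filtering into two-group statistics.

The pipeline consumes four delimited text files: a *page flow* (one row
per view: `user_id`, `page_id`, `start`, `duration_s`), a *user table*
(characteristics and outcomes), a *coding map* (page → numeric code and
page-group label; many pages share a code, each code has one label), and
a *color map* (code → hex color). `assemble_dataset()` joins them,
mapping any page missing from the coding map to the reserved code 0
("uncoded", drawn gray) so gaps in the coding file stay visible in plots
instead of silently vanishing; `strict = TRUE` turns them into errors.

## Binned sequences

Each participant's views are sorted by start time (ties keep file order)
and binned into 30-second blocks: `blocks = max(1, ceiling(duration /
30))`. Rounding up with a one-block floor guarantees every visited page
occupies visible width, at the cost of slightly inflating very short
views; with the 30-second quantum this bias is immaterial relative to
typical dwell times. Adjacent views with the same code merge into one
run, so a sequence is a run-length encoding of the participant's path
through page groups. Two properties pin the construction down and are
tested as invariants: total blocks are conserved under merging, and a
user's total equals the sum of `blocks_for()` over their raw views.

The x-axis is *cumulative viewing time*: calendar gaps between views
carry no width. "Sequence length" — the plot-ordering key — is therefore
total viewing time in blocks, not page count, matching the reading that
participants are stacked by how long they spent on the intervention,
least at the bottom. Ties order lexicographically by user id so renders
are deterministic.

## The four plot types

- **Normal** draws one horizontal lane per participant, each run a
  contiguous colored bar. The testable contract is geometric, not
  raster-level: lane count equals participant count and drawn lane width
  equals total blocks.
- **Frequency** aggregates blocks per page group over everyone — the
  quickest read of which components are most used.
- **Clustered** orders lanes by usage archetype. The clustering method is
  a reconstruction (no canonical choice exists for this plot family):
  each user's feature vector is total blocks per code, L2-normalized so
  profiles are compared by shape rather than volume; Ward (`ward.D2`)
  agglomerative clustering on Euclidean distance; `k` chosen in 2..8 by
  maximum mean silhouette width unless given. Ward on normalized totals
  was chosen for determinism and interpretability — no random restarts,
  no sensitivity to lane order — and the whole procedure is reproducible
  bit-for-bit, which the SVG output preserves (the cairo device writes
  byte-identical files for identical input).
- **Group** facets normal-style panels by a categorical user attribute
  (e.g. trial arm) on a shared x scale. Empty levels keep an empty,
  labelled panel so absence is visible.

## Occasions and reuse

"Reuse" of a component means coming back to it: viewing a page group on a
*session occasion* later than the occasion of first exposure. Logs do not
record logins, so occasions are reconstructed: a gap of more than 60
minutes between a user's consecutive views starts a new occasion. The
threshold is a design choice — long enough that reading a long page does
not split a sitting, short enough that same-day revisits count — and is
exposed as `gap_minutes` everywhere reuse is computed.

## Percentages, two conventions

Usage tables print percentages two ways, and the conventions differ:
one-decimal percentages are *truncated* (104/132 → 78.7, 76/132 → 57.5),
while whole-number percentages are *rounded half away from zero*
(120/132 → 91). `usage_summary()` and `reuse_summary()` report both
(`pct_1dp`, `pct_int`) so either style can be reproduced exactly.

## Cohorts and moderator statistics

Filters select participants by exposure (`seen`, `not_seen`, `reused`,
`not_reused` of a page group) or by user-table predicates, combining by
conjunction only — OR is expressible by unioning two cohorts — which
keeps the recorded provenance unambiguous. `usage_indicator()` converts a
filter into a 0/1 user-table column, the "usage variable" that moderator
analysis runs against. Exports are CSV (one row per member: user data,
per-filter indicators, `total_blocks`), chosen as the canonical format
because it is bit-reproducible and diffable.

`moderator_report()` compares the indicator's two groups on each
requested variable: numeric variables by a pooled-variance t test (Welch
on request), categorical ones by Pearson χ² without continuity
correction, the combination that reproduces SPSS-style printed output.
Sample SDs use the n−1 denominator throughout, and group 0 (non-users)
comes first, so t signs follow the non-users-minus-users convention.
The summary-statistics entry points (`pooled_t_from_summary()`,
`welch_t()`) exist so published tables — n, mean, SD per group — can be
re-tested without raw data; the sample-level routes are defined as
summaries-then-test, making the two routes agree to machine precision.
Tests cross-check them against `t.test()` and `chisq.test()`, against an
exhaustive permutation test at small n, and against the 2×2 closed form
N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)). No multiplicity adjustment is applied
by default (the analyses this reproduces report unadjusted p values); a
Benjamini–Hochberg column is available via `adjust = TRUE`.

## The synthetic generator

`generate_usage()` emits the four files plus a ground-truth record for a
cohort that has the statistical structure the analyses assume:

- **Tunnelled core.** Week 1 is the first core session in two parts
  (part 2 reached with probability `p_part2 = 0.91`); weeks 2 and 3
  unlock the support and physical-activity sessions in sequence, each
  opening with a goal-and-weight review.
- **Attrition.** Continuation into each next week is Bernoulli with
  probability `q` (default 0.9), with an extra multiplier
  `early_drop = 0.8` on the step into week 2 to emulate the sharp
  (~20%) first-to-second-session drop typical of these interventions.
  With `early_drop = 1` retention is purely geometric, `q^(week−1)` —
  the configuration used for calibration checks, where session-3
  retention at q = 0.9 converges to 0.81.
- **Optional content and tools.** Post-core weeks hold a review plus one
  optional session with probability `p_opt = 0.5`. The food diary is
  first exposed in week 1, the steps diary in week 3; eligible users
  draw Poisson(`reuse_rate = 1`) reuse occasions in later active weeks,
  so reuse is detectable by the occasion rule on the emitted log itself
  (tests verify the detector against the generator's latent flags).
- **Dwell times.** Log-normal, `meanlog = 3.4`, `sdlog = 0.8` (median
  ≈30 s) — an invented but plausible scale, documented as such.
- **Outcome.** `weight_change = β₀ + β₁·reused_steps_diary + N(0, σ_w)`
  kg lost, defaults β₀ = 2.63, β₁ = 3.15, σ_w = 5.7 — group means and a
  pooled SD on the scale of the published moderator analysis this
  emulates, so power studies at that study size (136 users, 17 reusers)
  are meaningful. At those parameters the analytic two-sample power at
  α = 0.05 is ≈0.56, and Monte-Carlo power over seeded replicates of the
  moderator report matches it within sampling error; under β₁ = 0 the
  rejection rate sits at the nominal 0.05.

What the generator does *not* emulate: circadian/weekday timing, device
effects, page-level heterogeneity within a group, or correlation between
attrition and the outcome beyond the reuse pathway. Passing tests
therefore demonstrate that the machinery is correct under the stated
model, not that any particular real cohort behaves this way.

## Numerical and scale choices

Calibration checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerance being checked: retention at n = 2000
(3 binomial SEs ≈ 0.026 around 0.81), type-I error over 1000 outcome
replicates, power over a few hundred. Degenerate inputs are handled
explicitly: zero-duration views still occupy one block; zero pooled
variance with equal means gives t = 0 (p = 1) and with unequal means an
infinite t with a warning; a zero χ² margin is an error rather than a
NaN. Percentage truncation adds 1e-9 before flooring to keep exact
decimal fractions from rounding down through floating-point error.

## Limitations

Equivalence with any specific historical tool's clustered plots cannot
be asserted, since the clustering method is a reconstruction. The reuse
definition depends on the occasion threshold; analyses sensitive to it
should vary `gap_minutes`. XLSX export is not provided — CSV is the
canonical export format. Moderator tests are unadjusted two-group
comparisons by design; no regression adjustment for baseline covariates
is offered.
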