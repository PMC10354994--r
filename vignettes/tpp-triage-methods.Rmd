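---
title: "Methods: TPP-based triage of a medicine development pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TPP-based triage of a medicine development pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpptriage)
```

## The problem and the model

Landscape analyses of drug R&D pipelines face a prioritization question:
given dozens or hundreds of candidate medicines at varying stages of
development, which are worth further investment? `tpptriage` implements a
drug-agnostic answer built around a target product profile (TPP) — a
strategic document listing the minimum and preferred characteristics a new
medicine should have. The workflow has four stages:

1. **Eligibility screen.** Candidates are excluded if any of six ordered
   criteria apply: (C1) already marketed for the indication, (C2)
   WHO-recommended or otherwise in routine use, (C3) already recommended for
   a subgroup of the target population, (C4) halted after negative
   outcomes, (C5) indicated as inferior to current treatments, (C6) under
   investigation for a different labour/birth indication. These judgements
   are expert curation; the package takes them as six boolean evidence
   flags on each registry record and never infers them from text. When
   several criteria apply, all are recorded and the lowest-numbered one is
   reported as primary — the source method lists the criteria in order but
   does not state tie handling, so this convention preserves the full
   information while matching the ordered listing.

2. **Dual rating.** Each screened-in candidate in clinical development
   (Phase I–III) is rated independently by two raters on nine critical TPP
   parameters. Six use a five-level ordinal scale (met preferred / met
   minimum / partially met minimum / not met / unknown). Trial *setting*
   uses a three-level scale (trials in both high-income and LMIC settings /
   a single setting / not stated), and *stability* (cold chain) and *WHO
   EML listing* use met / not met / unknown. These scales are exactly the
   coding visible in the published figure legends, which is the only
   printed description of the rating instrument; the EML parameter admits
   `unknown` for robustness even though its legend shows only two colors
   (it scores as zero either way).

3. **Adjudication.** Agreeing parameters pass through; disagreements are
   settled by a third rater. Whether the third rater re-rated everything or
   only disagreements is not stated in the source; the package resolves
   only disagreements, which makes `adjudicate()` symmetric in its two
   inputs whenever the third map covers all disagreements (a property the
   test suite verifies). A disagreement without a third-rater level leaves
   the sheet unresolved and unscorable — failing loudly rather than
   guessing.

4. **Scoring and tiers.** Levels map to integer codes, parameters to
   weights, and the weighted sum is compared, as a fraction of the maximum
   achievable score, against phase-specific cuts to yield high / medium /
   low potential.

## Tunable parameters, defaults, and why

The published analysis quantified matching with supplementary scoring
tables that are not reproduced in the main text. The package therefore
treats the entire scheme as configuration with documented defaults
(`default_scheme()`), calibrated only by the stated qualitative facts:
efficacy and safety carry greater weight, and an all-preferred candidate
must rank high while an all-not-met candidate ranks low at every phase.

| Constant | Default | Rationale |
|---|---|---|
| level codes | 3 / 2 / 1 / 0, unknown = 0 | equal-spaced ordinal coding; `unknown` conservative (a grey cell earns nothing) |
| weights | efficacy = safety = 2, others = 1 | source states direction ("greater weight"), not magnitude; any factor > 1 is accepted |
| tier cuts | high ≥ 0.70, medium ≥ 0.40 of max, all phases | fractions of the achievable maximum, so they are invariant to rescaling codes/weights |
| boundary ties | upper tier (≥) | must be fixed for determinism; documented in the config |
| unknown policy | `score_zero` | the alternative `exclude_and_renormalize` drops grey cells from numerator and maximum; provided because the source ranks candidates with many grey cells without stating their arithmetic treatment |

Whether the published thresholds were absolute scores or fractions, and
whether they differed by phase, is unrecoverable from the main text; both
are expressible in the config (`scoring_scheme()`, `write_scheme()`,
`read_scheme()`), and a scheme round-trips through its JSON config exactly.

Activity status uses a single cutoff year: a candidate is active iff its
last update year is known and ≥ 2018 ("no updates since 2018"). The source
never states how activity was judged for candidates with publications but
no registry updates; the single-year rule is an explicit simplification,
and unknown years count inactive.

## Percentages

All reported percentages are rounded **half-up** to one decimal
(`percent1()`), the rule consistent with the printed values (14/36 → 38.9,
12/58 → 20.7, 28/92 → 30.4). One printed value, 74.1% for 132/178 (exact
74.157…), is inconsistent with any standard rounding; the package reports
74.2 and that pair is excluded from the verification set.

## The synthetic generator: what it emulates and what it does not

`generate_registry()` samples candidates independently from configurable
marginal distributions over phase, product type, archetype, indication and
activity, with independent Bernoulli exclusion flags on clinical
candidates. The defaults are the published landscape's marginals (60.1%
preclinical, 74.1% drugs, 46.1% new entities, 38.2% active, exclusion-flag
rates proportioned to 27 exclusions among 71 clinical candidates).
`generate_sheets()` emulates the dual-rater workflow: rater B copies rater
A per parameter with a configurable agreement probability (default 0.8 — a
plausible value for trained raters on a nine-item ordinal instrument; the
source reports no agreement statistic) and otherwise draws uniformly among
the other admissible levels.

The generator deliberately does **not** emulate: correlations between
fields (real registries correlate phase with activity and archetype with
subclass), the long-tailed subclass vocabulary, rater biases that are
systematic rather than independent per parameter, or any association
between a candidate's true promise and its ratings. A green property test
on generated data therefore establishes the *mechanical* correctness of
screening, adjudication and scoring — determinism, partition and
monotonicity invariants — not any epidemiological claim.

The `aim_fixture()` registries are the opposite: deterministic transcripts.
The `flow` fixture realizes every printed marginal exactly by filling
categories in fixed blocks (joint structure beyond the printed marginals is
arbitrary but fixed, and only marginals are asserted); the per-criterion
split of the 27 exclusions beyond the printed 7 marketed + 11 off-label is
a synthetic 3/2/2/2 allocation. The `preclinical_tables` fixture transcribes
the two printed subclass tables (36 prevention + 58 management rows; the
same two molecules, resveratrol and rolipram, appear under both scopes, and
one non-ASCII name is transliterated). Product type is not given in those
tables and is filled deterministically (antibody/protein/cell rows →
biologic; herbal/polyphenol rows → dietary supplement; otherwise drug); no
test asserts it. The `clinical_ranks` fixture carries the 17 named
high/medium candidates with their narrative phases and placeholder names
for the 27 unnamed low-tier candidates. The printed per-figure counts (21 +
22 assessed; 6 + 4 high and 2 + 5 medium) do not reconcile exactly with the
printed totals (44 remaining; 27 low); the fixture follows the totals, so
it contains one more low-tier Phase II management row than the figure
counts imply. Every fixture re-checks its asserted counts at construction
and raises an integrity error on transcription drift.

## Numerical and degenerate-input choices

* Rounding is `floor(10 · x + 0.5) / 10` on the percentage scale — exact
  halves go up, never to even.
* Tier boundaries use ≥, so 0.70 is high and 0.40 is medium under the
  defaults.
* An empty registry summarizes to zero totals and empty tables rather than
  erroring; a zero denominator in `percent1()` is an error.
* An all-unknown sheet under `exclude_and_renormalize` has no defined
  score and raises a degenerate-input error; under `score_zero` it scores
  0.
* The worst admissible level differs by scale: the setting scale has no
  `not_met`, so its floor is `unknown` (also code 0). Uniform "all not
  met" sheets are representable on every other parameter.
* Only Phase I–III candidates are tiered; Phase IV, marketed and
  preclinical candidates raise an unsupported-phase error in `rank_tier()`
  (the source assessed preclinical candidates descriptively only).
* Matrix rows are ordered phase III → II → I, then score descending, then
  name — the published figures' exact row order is not recoverable, so
  this is a deterministic convention. Stability's "green" legend color is
  rendered with the light-green token.

## Known limitations

* End-to-end reproduction of the published per-candidate scores and tiers
  is impossible: the per-cell ratings exist only as figure imagery and the
  scoring constants only in unavailable supplementary tables. The
  acceptance suite therefore combines fixture-tally reproduction of every
  printed count with property-based checks (monotonicity across 10⁴
  generated sheets, weight dominance, boundary tables, adjudication
  symmetry, generator calibration, round-trips).
* Eligibility flags are inputs, not inferences; the package contains no
  literature mining.
* The registry model is one snapshot; no longitudinal pipeline dynamics.
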