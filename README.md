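# tpptriage

Prioritizing candidate medicines in an R&D pipeline against a target product
profile (TPP). The package implements the triage workflow used in landscape
analyses of the preterm-birth medicine pipeline: a curated registry of
candidate medicines is screened through six ordered exclusion criteria,
survivors in clinical development (Phase I–III) are rated by two independent
raters against nine critical TPP parameters, ratings are adjudicated,
converted to weighted scores, and mapped to phase-specific **high / medium /
low potential** tiers. Results are rendered as traffic-light matrices
(candidate × parameter, colored cells, final-rank column) and landscape
summary tables.

It is aimed at product-development and maternal-health researchers who run
TPP-matching exercises over pipeline databases, and at anyone who wants a
reproducible, fully configurable reimplementation of the method for other
disease areas.

## The method

Each candidate `i` receives, for each of nine parameters `p` (trial setting,
efficacy, companion diagnostic, clinical monitoring, safety, administration
route, adherence, cold-chain stability, WHO EML listing), an ordinal rating
level. Levels map to codes `c(level)` (defaults: met preferred = 3, met
minimum = 2, partially met = 1, not met = 0, unknown = 0) and parameters to
weights `w_p` (defaults: efficacy = safety = 2, others = 1). The weighted
score is

```
S_i = Σ_p  w_p · c(level_ip),      S_max = c(met_preferred) · Σ_p w_p = 33
```

and the tier is a step function of `S_i / S_max` with phase-specific cuts
(defaults: high ≥ 0.70, medium ≥ 0.40, boundaries belong to the upper tier).
The published supplementary scoring constants are not available; the default
scheme is this package's documented convention and every constant is
configurable via a JSON scheme file (see `?scoring_scheme`).

## Worked example

```r
library(tpptriage)

flow <- aim_fixture("flow")          # 178-candidate landscape fixture
summarize_registry(flow)
#> <tpp_landscape> 178 candidate(s)
#>  status: active 68 (38.2%), inactive 110 (61.8%)
#>  phase: preclinical 107 (60.1%), phase1 11 (6.2%), phase2 30 (16.9%), phase3 23 (12.9%), phase4 7 (3.9%)
#>  product_type: drug 132 (74.2%), biologic 14 (7.9%), dietary_supplement 32 (18.0%)
#>  archetype: new_entity 82 (46.1%), repurposed 96 (53.9%)

screen_registry(flow)$report
#> <tpp_flow_report> total=178 screened=71 excluded=27 remaining=44
#>   primary criterion: C1=7 C2=11 C3=3 C4=2 C5=2 C6=2
```

38.2% of the pipeline is in active development, 60.1% is preclinical; of the
71 clinical-phase candidates, 27 are excluded (marketed, WHO-recommended,
subgroup-covered, halted, inferior, or investigated for another labour
indication) leaving 44 for TPP matching. Rating, adjudication and tiering:

```r
sh_a <- rating_sheet("cand-1", "rater_a", c(
  setting = "both_settings", efficacy = "met_minimum",
  companion_diagnostic = "met_preferred", clinical_monitoring = "met_preferred",
  safety = "met_minimum", administration = "met_preferred",
  adherence = "partial_minimum", stability = "met", eml_listing = "not_met"))
sh_b <- rating_sheet("cand-1", "rater_b", replace(sh_a$levels, "efficacy", "partial_minimum"))

adj <- adjudicate(sh_a, sh_b, third = c(efficacy = "met_minimum"))
sc  <- score_sheet(adj$merged)
sc$weighted_score; sc$score_fraction
#> [1] 24
#> [1] 0.7272727
rank_tier(sc$score_fraction, "phase2")
#> [1] "high"
```

A score of 24/33 (72.7%) clears the 70% cut: high potential. Traffic-light
export (`export_matrix(..., format = "svg")`) draws one colored cell per
rating plus the final-rank column; CSV export round-trips the token grid.

The tier tally of the published 44 screened-in clinical candidates is
shipped as a fixture:

```r
tally_tiers(aim_fixture("clinical_ranks"))
#>   high medium    low
#>     10      7     27
```

## Synthetic data

`generator_config()` / `generate_registry()` / `generate_sheets()` produce
seeded registries with configurable marginal distributions and paired rating
sheets with a configurable inter-rater agreement probability — the defaults
encode the published landscape's marginals. See the methods vignette
(`vignettes/tpp-triage-methods.Rmd`) for what the generator does and does
not emulate.

## Command line

```sh
Rscript inst/cli/tpp-triage validate registry.csv
Rscript inst/cli/tpp-triage screen registry.csv --out flow.json
Rscript inst/cli/tpp-triage rank registry.csv sheets.csv --scheme scheme.json --out ranks.csv
Rscript inst/cli/tpp-triage matrix ranks.csv sheets.csv --format svg --out fig.svg
```

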