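# pocmcda

Quantitative multi-criteria decision analysis (MCDA) for prioritising
candidate point-of-care (POC) testing "use cases" — condition/test pairings
such as *lactate testing in suspected sepsis* — for evaluation in a platform
trial, as practised in health technology assessment for emergency medical
services. The package is for analysts running or auditing such
prioritisation exercises: it turns stakeholder surveys and workshop votes
into a transparent, reproducible scoring pipeline, and adds the robustness
analyses a one-off workshop rarely has time for.

## The method

Stakeholders score each option $o$ on each criterion $c$ using an ordinal
rating scale; votes are averaged into mean ratings $s_{o,c}$; criterion
weights $w_c$ are the mean 0–10 importance scores from an expert survey,
used raw (not normalised). The option score is the weighted sum

$$T_o = \sum_c w_c\, s_{o,c},$$

options are ranked by $T_o$ and the top *k* (default 3) are selected.
"Satisfice" (deal-breaker) rules — contiguous tails of a rating scale, e.g.
evidence levels {0,1,2} — exclude options: by explicit panel decision before
scoring, or as an ineligibility flag when the unrounded mean rating falls in
the tail during scoring. Two robustness procedures quantify rank stability:
a leave-one-out jackknife over stakeholders, and Monte-Carlo perturbation of
the weights by unit-median log-normal factors. A synthetic stakeholder-panel
generator (clamped-and-rounded normal responses around a latent consensus)
makes every stage testable by parameter recovery.

## Worked example

The package bundles a complete prioritisation of POC-test use cases for UK
ambulance services: twelve candidates, seven struck out by the panel as
meeting deal-breakers, five scored against four weighted criteria.

```r
library(pocmcda)

apply_exclusions(ems_poc_usecases(), ems_poc_excluded())$surviving$id
#> [1] "lactate_trauma" "sars_cov2_rti"  "lactate_sepsis" "troponin_ami"
#> [5] "ketones_dka"

cfg <- ems_poc_criteria()                 # 4 criteria, weights 7.2/8.8/7.0/5.9
pm  <- ems_poc_printed_matrix()           # published means and final scores
m   <- score_from_means(cfg, pm$cells[, c("option", "criterion", "mean")])
m$ranking
#> # A tibble: 5 × 5
#>   option         total  rank top_k tied
#>   <chr>          <dbl> <int> <lgl> <lgl>
#> 1 troponin_ami    72.0     1 TRUE  FALSE
#> 2 lactate_sepsis  66.3     2 TRUE  FALSE
#> 3 lactate_trauma  55.8     3 TRUE  FALSE
#> 4 ketones_dka     45.6     4 FALSE FALSE
#> 5 ntprobnp_ahf    39.3     5 FALSE FALSE
```

The top three — troponin in suspected myocardial infarction, lactate in
sepsis, lactate in trauma — are the options selected for the platform trial.
Exactly one of the twenty cells trips a satisfice rule (ketones ×
diagnostic accuracy, mean 1.69 on a "levels 0–2" rule), so that option is
flagged ineligible but still scored (`m$options$eligible`). Verification of
the published matrix against its own printed weights:

```r
verify_printed_matrix(cfg, pm$cells, pm$totals)$criteria
#> # A tibble: 4 × 5
#>   criterion              weight implied_weight n_inconsistent consistent
#>   <chr>                   <dbl>          <dbl>          <int> <lgl>
#> 1 care_pathway              7.2           9.59              5 FALSE
#> 2 diagnostic_accuracy       8.8           8.80              0 TRUE
#> 3 clinical_effectiveness    7             6.99              0 TRUE
#> 4 population_size           5.9           5.9               0 TRUE
```

i.e. the care-pathway row of the source matrix cannot be reconciled with its
stated weighting (its finals imply a multiplier near 9.59) — the engine
detects this rather than reproducing it. An end-to-end run from files:

```r
run_pipeline(
  config = system.file("extdata", "usecase_config.yaml", package = "pocmcda"),
  votes = system.file("extdata", "synthetic_votes.csv", package = "pocmcda"),
  out_dir = "out", seed = 7, reps = 10000
)
```

writes the scoring matrix (CSV + plain-text report), ranking, exclusion
records, sensitivity tables and a digest-bearing manifest. A thin CLI with
subcommands (`weights`, `screen`, `score`, `rank`, `sensitivity`,
`simulate`, `run`) is installed at `inst/scripts/pocmcda`. The bundled
`synthetic_votes.csv` / `synthetic_importance.csv` are generator output, not
human data.

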