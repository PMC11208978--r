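# raCEA

Cost-effectiveness of rheumatoid arthritis (RA) treatment sequences that
start with biosimilar infliximab, biosimilar adalimumab, or leflunomide
after methotrexate failure, from a public-payer perspective. The package is
aimed at health-economic modellers: it implements a lifetime multistate
Markov cohort model over 6-month cycles with ACR-response-based switching,
per-cycle discontinuation, HAQ-DI-driven utility and mortality, and a
terminal supportive-care state, plus the full uncertainty toolkit
(probabilistic sensitivity analysis, acceptability curves, tornado
diagrams, scenario grid).

## The model in brief

Patients enter at age 56 with baseline disability HAQ-DI 1.6 and move
through first line → pooled TNFi → pooled non-TNFi → pooled JAKi →
supportive care. In the first cycle of the first line the cohort splits by
ACR response category (forced differences of cumulative ACR20/50/70 rates)
with category-specific HAQ-DI improvements; non-responders switch at cycle
end, and on any switch HAQ-DI rebounds to its value at that line's entry.
Key mappings:

* utility = 0.74 − 0.17 × HAQ-DI, QALYs = utility × years, discounted 3.5%/yr
* adjusted mortality = general mortality × 1.33^HAQ-DI (capped at 1)
* supportive-care HAQ-DI trajectory: −0.04, +0.2, then +0.28 per cycle to a
  ceiling of 3
* ICER = Δcost / ΔQALY, judged against WTP US$48,555/QALY; dominance =
  lower cost and higher QALY; NMB = WTP × QALY − cost

Published first-line inputs are built in; everything unpublished (life
table, later-line classes, supportive-care cost split) is generated
synthetic, provenance-tagged, and frozen — see `fixture_manifest()` and the
methods vignette (`vignettes/model-methods.Rmd`).

## Worked example

```r
library(raCEA)

cfg <- base_case_config()      # bundled fixture: published + synthetic values
fit <- run_model(cfg)
summary(fit)
#>                strategy   cost incremental_cost qaly incremental_qaly      icer
#> 1           Leflunomide 111893        Reference 6.10        Reference Reference
#> 2 Biosimilar infliximab 109351           -2 541 6.36             0.26    -9 642
#> 3 Biosimilar adalimumab 101823          -10 070 6.47             0.38   -26 554
```

Both biosimilar-initiated sequences cost less and yield more QALYs than the
leflunomide sequence (negative ICERs with positive QALY gains: dominant).
Probabilistic sensitivity analysis and the acceptability curve:

```r
psa <- run_psa(cfg, n_iter = 1000, seed = 1)
cc  <- ceac(psa)
plot(cc)    # adalimumab-first is the most likely cost-effective strategy
tor <- tornado(cfg)             # one-way DSA, sorted bar widths
scn <- run_scenarios(cfg)       # published scenario grid
```

ICER arithmetic on published lifetime totals reproduces the published
values exactly:

```r
icer(list(label = "infliximab", cost = 152326, qaly = 15.35),
     list(label = "leflunomide", cost = 154632, qaly = 14.82))
#> infliximab vs leflunomide: dCost -2306, dQALY 0.53, ICER -4351 (dominant)
price_reduction(940, 7073)   # 87 (% vs adalimumab originator)
price_reduction(1654, 3609)  # 54 (% vs infliximab originator)
```

Command-style entry points (`cmd_base_case()`, `cmd_psa()`, `cmd_dsa()`,
`cmd_scenarios()`, `cmd_gen_fixtures()`) write CSV tables plus a JSON run
manifest; `inst/cli/racea.R` wraps them for shell use.

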