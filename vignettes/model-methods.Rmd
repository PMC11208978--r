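---
title: "A lifetime Markov model for biosimilar-initiated treatment sequences in rheumatoid arthritis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov model for biosimilar-initiated treatment sequences in rheumatoid arthritis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raCEA)
```

## The decision problem

More than half of patients with rheumatoid arthritis (RA) fail methotrexate
monotherapy. The next step is contested: conventional synthetic DMARDs such
as leflunomide are cheap, while biological DMARDs respond better but cost
far more per cycle. Biosimilars of infliximab and adalimumab, priced 54% and
87% below their originators, change that trade-off. `raCEA` implements a
lifetime multistate Markov cohort model, from a public-payer perspective,
comparing three treatment sequences after methotrexate failure: first-line
leflunomide (reference), biosimilar infliximab, or biosimilar adalimumab,
each followed by a pooled TNF-inhibitor class, a pooled non-TNFi biologic
class, a pooled JAK-inhibitor class, and finally supportive care.

## Model structure

The cohort (starting age 56, 72.7% women, baseline HAQ-DI 1.6) moves through
the sequence in 6-month cycles. Disease severity is tracked on the Health
Assessment Questionnaire Disability Index (HAQ-DI, 0 best to 3 worst), which
drives utility, mortality, and nothing else needs to be remembered — which is
what keeps the expanded state space small.

* **First cycle of the first line.** The cohort splits into four ACR
  response categories (the forced differences of the cumulative ACR20/50/70
  trial rates, a Dirichlet split) and each category takes its HAQ-DI change
  (−0.16, −0.45, −0.70, −1.02). Patients below ACR20 move to the next line
  at cycle end.
* **Maintenance.** HAQ-DI is constant while on a drug; each cycle a fixed
  discontinuation fraction (15.4% infliximab, 12.9% adalimumab, 36.5%
  leflunomide per cycle; pooled-class values later) abandons the line.
* **Rebound.** On leaving a line, HAQ-DI returns to its value at that
  line's entry. By induction every line is entered at the baseline score,
  so each line contributes at most two states (entry cycle, maintenance),
  and the first line contributes four entry strata plus three maintenance
  strata.
* **Later lines.** Pooled classes apply a single mean HAQ-DI improvement in
  their entry cycle; the second-line TNFi improvement is weaker for
  patients whose first line was already a TNFi (biosimilar arms) than for
  TNFi-naive patients (leflunomide arm).
* **Supportive care.** A terminal tunnel: HAQ-DI changes by −0.04, +0.2,
  then +0.28 per cycle until the ceiling of 3, tracked state-by-state so
  time-in-state-dependent rules (the trajectory itself, steroid costing)
  stay Markovian.
* **Mortality.** A sex-blended general-population per-cycle death
  probability (72.7% female weight), multiplied by 1.33^HAQ-DI and capped
  at 1. The run ends at the horizon or age 100.

Within a cycle the order of events is: death at the state's current HAQ-DI,
then cost and QALY accrual by survivors for the full cycle, then end-of-cycle
switching. A line's first-cycle HAQ change is applied at entry, so the entry
state's score — used for that cycle's mortality and accrual — already
includes it; in particular non-responders carry their −0.16 improvement for
the single cycle they spend on the drug before rebounding. The source for
this timing is ambiguous, so it is fixed here for definiteness; an optional
half-cycle correction (weight 0.5 on the first and last cycle) is available
and off by default, since there is no evidence the published analysis used
one.

## Outcomes

Utility is linear in disability, `utility = 0.74 − 0.17 × HAQ-DI`, and QALYs
accrue as utility × cycle length (0.5 years) per surviving cycle. Costs per
cycle combine drug acquisition (infliximab has a loading-dose first cycle of
\$2,792, then \$1,654), expected adverse-event costs (per-cycle probabilities
of pneumonia, herpes zoster, tuberculosis and hepatitis B times per-episode
costs — events affect cost only), and supportive-care costs. Both streams
are discounted at 3.5% per year; all costs are 2022 US dollars (US\$1 =
HK\$7.78). Incremental cost-effectiveness ratios are judged against a
willingness-to-pay of \$48,555/QALY (one GDP per capita); the raw ratio is
reported even when negative, together with a dominance label, because a
negative ICER alone is ambiguous. Net monetary benefit (`wtp × QALY − cost`)
operationalizes "cost-effective" everywhere a binary call is needed.

## Synthetic inputs and what they stand for

The published first-line inputs are entered verbatim and tagged `"paper"` in
the provenance manifest. Three inputs are not published and ship as clearly
tagged synthetic stand-ins, frozen at packaging time (seed 20240626):

* **Life table.** A Gompertz–Makeham table per sex (annual hazard
  `A + B e^{θx}`), calibrated once to a long-lived high-income population:
  blended remaining life expectancy at 56 of about 26 years. It is smooth
  and lacks the accident hump and cohort effects of a real national table;
  none of those features matter at ages 56+ where the model lives.
* **Later-line classes.** For each class a few synthetic member drugs are
  drawn around class anchors and pooled by random market shares via
  share-weighted means — the same pooling the model applies to real
  classes. Constraints: per-cycle costs stay between the printed
  leflunomide (124) and infliximab maintenance (1654) anchors
  (TNFi 1500, non-TNFi 1300, JAKi 1100 before pooling jitter);
  improvements are weaker than the first-line category-weighted mean, and
  TNFi-experienced ≤ TNFi-naive.
* **Supportive-care costs.** Nonpharmacological care is delivered in
  two-month courses — one intraarticular steroid injection plus roughly
  four biweekly physiotherapy attendances — at the anchored \$2,891 per
  course, three courses per 6-month cycle. Steroid injections recur every
  six months and at most twice in a lifetime, implemented as a steroid
  component in the first two supportive-care cycles only. The
  courses-per-cycle reading was chosen by triangulation: with one course
  per cycle the first-line drug premium of a biosimilar (≈\$10k present
  value) can never be repaid by leaving supportive care later — the
  downstream cost stream would have to exceed \$200k present value, more
  than the published totals themselves — whereas three courses per cycle
  reproduces the published incremental costs almost exactly
  (infliximab −2,541 here vs −2,306 published; adalimumab −10,070 vs
  −9,213) and the published cost scale. The choice was frozen before the
  test suite was finalized and is not revisited.

Because of these stand-ins the fixture's absolute totals are not the
published ones; what the passing tests show is that the *arithmetic* (ICERs,
increments, price reductions) reproduces the published numbers exactly from
published inputs, and that the *qualitative* base case — both biosimilar
sequences dominate leflunomide, with adalimumab the most likely
cost-effective strategy — is reproduced by the full pipeline. Absolute QALY
totals here are roughly half the published ones; the published values are
consistent with utility accrued per cycle without the half-year cycle-length
factor, while this package keeps the dimensionally standard utility × years
(so a cohort at utility 0.74 for T years accrues exactly 0.74 T QALYs, a
closed form the tests verify at 1e-9).

## Uncertainty analysis

**Probabilistic.** Every uncertain parameter carries a distribution:
Dirichlet for the ACR split (one effective sample size per drug, fitted by
least squares to the printed cumulative SDs, since any partial sum of a
Dirichlet is Beta with SD `sqrt(m(1−m)/(N+1))`), Beta by method of moments
for probabilities (with a uniform-on-range fallback and warning when
`s² ≥ m(1−m)`), Gamma by method of moments for costs and HAQ-change
magnitudes (negative means sampled on the magnitude, sign restored), and
uniform on the printed range for baseline HAQ-DI. Missing SDs default to
25% of the mean, logged. Parameters printed once — the category HAQ
changes, adverse-event episode costs, baseline HAQ-DI, all later-line and
supportive-care values — are sampled once per draw and shared across
strategies; parameters are independent across draws because no correlation
structure is published. Each iteration uses a substream seed derived from
the base seed and the iteration counter, so results do not depend on
execution order. The acceptability curve gives each strategy, at each
willingness-to-pay on a \$0–80,000 grid, the fraction of draws in which it
attains the strictly highest net monetary benefit, with exact ties splitting
credit equally (a measure-zero event under continuous draws that matters
only in degenerate tests).

**Deterministic.** The tornado analysis moves each scalar parameter alone
to the ends of its 95% interval — the printed range where one exists,
mean ± 1.96 SD clipped to the parameter's support otherwise (the printed
hepatitis-B range for adalimumab is internally inconsistent and is treated
as absent) — and each cumulative ACR rate individually with monotonicity
clamping. Bars are sorted by ICER excursion width; an entry whose base-case
ICER escapes its own excursion interval is flagged non-monotone rather than
silently trusted.

**Scenarios.** The grid covers two alternative (synthetic, config-resident)
linear HAQ-to-utility mappings, horizons of 5–40 years, discount rates of
0% and 5%, starting ages 51 and 61, a simplified sequence in which
first-line failures move directly to supportive care, and removal of
nonpharmacological supportive-care costs. Scenario 0 must reproduce the
base case bit for bit, and an invalid override fails only its own scenario.

## Numerical choices and validation

Occupancy (including the dead accumulator) is asserted to sum to 1 within
1e-10 every cycle. The supportive-care tunnel is truncated where the HAQ
ceiling is reached (a guard caps pathological non-deteriorating
trajectories at 60 tunnel states). Problem sizes used by the validation
suite were chosen to keep the full pipeline — base case, 1,000-iteration
PSA, tornado, scenario grid — within a few minutes on one CPU: the engine
is deterministic, so PSA precision is limited only by iteration count, and
1,000 iterations put a standard error of about 1 percentage point on the
acceptability probabilities.

The engine's independent oracle is a brute-force individual-level
microsimulation (in the test helpers, deliberately outside the package
namespace) that re-implements the clinical rules patient by patient and
samples deaths, switches and adverse events; engine totals must agree with
the oracle's means within three standard errors on randomized small
configurations with 100,000 simulees. Closed-form limits (QALYs = 0.74 T;
discounting monotone in the rate; exact cost decomposition; ICER
antisymmetry) pin the accounting.

## Known limitations

Adverse events carry cost but no utility decrement or excess
discontinuation; there is no treatment re-challenge, dose escalation, or
individual-level heterogeneity beyond the response strata; parameters are
sampled independently in the PSA; the societal perspective (productivity
loss) is out of scope; and the synthetic stand-ins, however constrained,
are not the unpublished supplementary data — conclusions from this package
are about the model's behaviour, not new evidence about the drugs.
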