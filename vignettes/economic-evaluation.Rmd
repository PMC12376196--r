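---
title: "Standardized economic evaluation of alcohol harm-reduction interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized economic evaluation of alcohol harm-reduction interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcocea)
```

## The evaluation model

alcocea computes standardized return-on-investment measures for alcohol
harm-reduction interventions from a societal perspective. Two measures are
produced per intervention:

* the **benefit–cost ratio**,

  $$\mathrm{BCR} = \frac{\text{resource savings} + \text{monetized health improvement}}{\text{implementation cost}},$$

* the **incremental cost-effectiveness ratio**,

  $$\mathrm{ICER} = \frac{\text{implementation cost} - \text{resource savings}}{\text{health improvement in QALYs}},$$

where the QALY denominator is obtained by dividing the intangible
(monetized-health) savings by a value of a statistical life year (VSLY).
Two outcomes are dominant and carry no finite ratio: when resource savings
alone cover a positive cost, the ICER is in the `NET_SAVING` state; when the
implementation cost is zero or negative (a revenue-raising tax shift), the
BCR is in the `NO_COST` state. Both sentinels are first-class values — they
appear in CSV output as literal tokens, never as empty cells, so round-trips
are unambiguous.

At a willingness-to-pay threshold (A$50,000 per QALY by default),
`classify()` maps each row to one of `cost_saving`, `cost_effective`
(finite ICER at or below the threshold — the boundary counts as
cost-effective), `not_cost_effective`, or `no_cost_dominant`.

All monies are AUD in a single reference price year carried as metadata; the
package deliberately performs no inflation adjustment or multi-currency
arithmetic beyond the ratio multipliers described below.

## Costing

Intervention costs follow the ingredients ("bottom-up") approach: each line
item is a quantity times a unit price (`ingredient_cost()`), and
`total_intervention_cost()` sums the non-overhead items. Overhead and joint
costs are excluded — delivering one intervention is unlikely to move them —
but the excluded amount is reported so the decision is auditable.

Capital items (equipment, development costs) are converted to an
**equivalent annual cost** with the annuity factor $r/(1-(1+r)^{-n})$ at the
configured discount rate (3%/year by default), degenerating to straight-line
apportionment at rate 0. The source methodology says only that multi-year
resource use was "annualized"; the equivalent-annual-cost form was chosen
because the same 3% rate is applied to future cost savings elsewhere in the
analysis, and it is exactly NPV-consistent: discounting the annual
equivalent over the lifetime recovers the capital cost to machine precision
(a property the test suite checks by brute force).

Special costing rules for environmental interventions:

* **Foregone consumption** (advertising bans, outlet density, sales hours,
  minimum pricing) is costed at half the pre-tax purchase price of the
  alcohol not consumed, representing profits across the supply chain. The
  0.5 profit share is a parameter of `consumption_reduction_cost()` for
  sensitivity analysis; the default is the published convention.
* **Volumetric tax changes** cost the administrative shift plus the
  deadweight loss (consumer benefit lost minus tax revenue gained); the
  total may be negative, which is the one admissible source of negative
  intervention cost (`validate_record()` rejects negative costs in any
  non-pricing category).
* **Establishment liability** is an upper bound: 7.1% of the expected
  annual claims value (claims × 51% last-drink-at-licensed-premises × 50%
  who would sue) plus court costs. The 51% share was measured in late-night
  roadside data and its WA-wide applicability is not settled, so it is an
  explicit parameter; court costs are unquantified in the source and
  default to $0 so the rule is reproducible.
* **Participant time** is valued at 60% of the wage rate for travel and 90%
  for delay.

Cross-jurisdiction conversion (`convert_cost()`) multiplies by the matching
index ratio: occupation salary ratios for labor-oriented costs,
purchasing-power parity for non-labor costs, pre-tax drink-price ratios for
consumption costs. Conversion is exactly invertible by construction.

## Benefits and QALYs

Two routes produce benefit components:

1. `direct_benefit()`: relative harm reduction × current incidence ×
   per-person or per-event harm unit cost, separately for the resource and
   intangible components (the bases must match; a mismatch is an error, not
   a silent recycle).
2. `transfer_benefit()`: benefits computed for a source jurisdiction scaled
   by the destination/source ratio of costs per alcohol-attributable harm.

Spillover benefits (reduced drug use, smoking, violence) are a separate
additive component included only when the intervention is effective against
alcohol harm. Demonstration-stage estimates are attenuated by 25%
(`apply_demonstration_discount()`), reflecting the usual effectiveness loss
at scale-up; the discount multiplies every component, so it commutes with
benefit transfer. Multi-year benefit streams are present-valued with
`discount_stream()` at 3%/year before entering the ratios; single-year
benefits bypass discounting.

## The VSLY: calibrated, not assumed

The published tables convert intangible savings to QALYs through a VSLY
that is never printed. The package therefore ships **no default VSLY**.
Instead, `implied_vsly()` inverts the ICER algebra row by row —
$\widehat{\mathrm{VSLY}} = \text{intangible} \times \mathrm{ICER} /
(\text{cost} - \text{resource})$ — and `calibrate_vsly()` aggregates the
inversion over a table, excluding rows with net cost under $50 where
whole-dollar printing dominates the quotient.

```{r}
calibrate_vsly(load_fixture("table4_rows"))
calibrate_vsly(load_fixture("table5_rows"))
```

The environmental/workplace/health table implies a remarkably tight band
around A$182,000 (CV ≈ 0.13%), the youth/school table a distinctly higher
band around A$232,000. The discrepancy is real, unexplained by the source
(differential discounting of youth outcomes is one possibility), and the
package reports it rather than reconciling it: calibrations are always
per-table.

## Printed values are data; contradictions are flagged

The packaged fixtures preserve the published cells verbatim, including
sentinel labels and one literal `$0` cost/QALY cell. Two rows print labels
their own components contradict: the mandated ignition-interlock row prints
"Net saving" with a stored net cost of $118, and Project Toward No Drugs
prints `$0` although its components imply a net saving.
`consistency_report()` flags both (`icer_ok = FALSE`) and never corrects
them.

For fixture tables, `evaluate_portfolio()` classifies from the printed ICER
cell by default (`use_printed = TRUE`): the printed label is the published
verdict, and with it the environmental table yields 18 cost-saving rows.
With `use_printed = FALSE` classification is recomputed from stored
components, which demotes the interlock row to `cost_effective` and the
negative-cost tax row to `no_cost_dominant` (16 cost-saving rows). Both
views are legitimate; the default favors fidelity to the publication and
leaves disagreement detection to the consistency report.

BCR recomputation tolerances mirror the printing conventions: ratios
printed with one decimal are compared within ±0.15 (a $19 printed cost can
hide half a dollar of precision — the Prime for Life row moves from 18.2 to
18.6 for exactly this reason), and integer-printed ratios (the pricing rows
63 and 1,537) are compared at printed precision. Component sums are checked
within $1. ICER agreement is judged only on rows with net cost ≥ $250;
below that, printed rounding of a $1–$100 denominator can move the ratio by
several percent (the liability row has net cost $1), so those rows get `NA`
rather than a misleading verdict.

## Registry structure

The two league tables print 50 rows. Positive Action appears twice (grades
3–8 and 3–5); both rows map to one intervention identity, reproducing the
published overall count of 49. The published category overview counts 4
pricing interventions while 5 pricing rows are printed; the registry keeps
all 5 rows and documents the discrepancy. One rated intervention
(subsidized ridesharing) carries no printed cost-effectiveness row and so
appears in the ratings and adjustments fixtures only.

## The synthetic generator

`generate_portfolio()` draws complete raw inputs — ingredient lists with
log-normal unit prices (median $50, log-sd 0.8), occasional capital items
(probability 0.2, lifetimes 2–10 years) and overhead lines (probability
0.15); relative reductions uniform on [0.02, 0.30]; incidence
1 + Poisson(49) per denominator unit so exposure is never zero; per-event
harm costs log-normal (median $2,000, log-sd 0.7) split by a Beta-drawn
intangible share with mean 0.8 (concentration 50), matching the ~80–85%
intangible share of the printed environmental rows; demonstration-stage
probability 0.2 — and computes each intervention's exact BCR, ICER, QALYs
and classification from closed-form expressions coded *inside the
generator*, deliberately duplicating rather than importing the pipeline.
That ground-truth table is the independent oracle: re-deriving the records
through the package's own costing and benefit stages must reproduce it to
1e-9 relative error, and does so to ~1e-15 in the test suite (at 1,000
interventions across five seeds — sizes chosen so the whole validation runs
comfortably on one core). `perturb_rounding()` additionally applies
whole-dollar printing to the records and checks that BCR deviations stay
within the analytic worst-case bound $u/c' + T\,u/(2\,c\,c')$ for rounding
unit $u$.

What the generator does *not* emulate: study-level effectiveness
heterogeneity, meta-analytic pooling, correlated errors between cost and
effectiveness, or real distributional tails. Passing the recovery tests
demonstrates that the pipeline's arithmetic is exact and its
classifications consistent — not that the package would reproduce any
particular new empirical dataset.

## Known limitations

* The source reports no standard errors, so the package emits point
  estimates only — no confidence intervals, no probabilistic sensitivity
  analysis.
* The AUD price year of the published tables is unstated; it is carried as
  unset metadata.
* The inter-table VSLY discrepancy is surfaced, not resolved; ICER
  cross-checks are only valid within a table.
* Benefit inputs (drinks reduced, consumer welfare losses, effectiveness)
  are taken as given; no demand-elasticity modeling derives them from price
  changes.
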