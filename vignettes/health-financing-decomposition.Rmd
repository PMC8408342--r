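---
title: "Decomposing growth in domestic government health expenditure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing growth in domestic government health expenditure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiscalspace)
```

## The model

Domestic general government health expenditure factors exactly into three
observable drivers:

$$\mathrm{GGHED} = \mathrm{GDP} \times \frac{\mathrm{GGE}}{\mathrm{GDP}}
  \times \frac{\mathrm{GGHED}}{\mathrm{GGE}}.$$

Writing $g$, $y$, $e$, $h$ for the total-period growth rates of GGHE-D,
GDP, the government-size ratio GGE/GDP and the prioritization ratio
GGHE-D/GGE (each defined as end/base − 1), taking logs of the factorization
in both anchor years gives the additive identity

$$\ln(1+g) = \ln(1+y) + \ln(1+e) + \ln(1+h),$$

so each log term over $\ln(1+g)$ is the share of GGHE-D growth
attributable to economic growth, expansion of government relative to the
economy, and reallocation of the budget towards health. The identity is an
accounting decomposition, not a causal model: it assumes only that the six
underlying levels are positive and measured in a common constant-dollar
unit, and it says nothing about why any driver moved.

`decompose_gghed()` is the primary entry point and takes the **six levels**
rather than pre-computed rates, so the identity holds at machine precision
by construction (the residual $\ln(1+g) - \sum \ln(1+\cdot)$ is reported
and is $\le 10^{-12}$ in every test). `decompose_from_rates()` exists for
reproducing tables whose inputs are already rounded growth rates; there the
residual is generally nonzero and is reported as-is, never silently folded
into one of the components. Growth rates at or below −100% have no
logarithm and are rejected. When GGHE-D did not change ($\ln(1+g)=0$) the
shares are undefined and flagged rather than returned as infinities.

`component_share()` computes one share directly as
$\ln(c_1/c_0)/\ln(\mathrm{GGHED}_1/\mathrm{GGHED}_0)$; only the ratio of
the component pair matters, so ratio values expressed in percent (22.6,
24.5) and as fractions (0.226, 0.245) give identical shares.

## Panel data model and validation

A panel is one row per (country, year) with population and the financing
indicators in a single unit scale, declared as a panel-level tag (the
default, millions of constant 2010 US$, matches how group-level tables are
usually published, while per-capita tables use dollars per person — the
`pc_scale = 1e6` factor converts between the two). Blank cells and the
tokens `NA`/`N/A` are read as missing, never as zeros, because source
tables publish `N/A` for genuinely unreported components.

`validate_panel()` checks the accounting identity CHE = GGHE-D + EXT + OOP
+ VPP + other private whenever all five components are present. Published
databases do not state their rounding slack, so the tolerance is ours: a
relative gap above 1% is a warning, above 5% an error, both configurable.
Order-of-magnitude checks (OOP ≤ CHE, GGHE-D ≤ GGE ≤ GDP) are warnings
only, since exceptional fiscal years can violate them legitimately.

## Cohort and grouping conventions

The default inclusion rule keeps a country when its population in the 2015
reference year is **at least** 600,000 and when GDP, GGE, GGHE-D, CHE and
OOP are all present in both anchor years (2000 and 2015). Two conventions
were genuinely open and are fixed as follows:

- *Boundary.* Descriptions of the population rule differ between "more
  than" and "less than" phrasings; we include at exactly the threshold
  (rule: population ≥ threshold) so the decision is deterministic.
- *GGE requirement.* The decomposition cannot run without GGE, so GGE is
  in the required set even though completeness criteria are sometimes
  quoted without it.
- *Order.* The population rule is checked first; a country failing both
  rules is reported under the population rule, and a country with missing
  population in the reference year is excluded under the same rule with an
  explicit annotation.

Income groups are an **input table**, not computed: GNI per capita is not
part of the data model, and start-of-period classification tables are
published. Groups are fixed at the base year and held constant across all
analysis years, which avoids the selection bias of end-of-period grouping
(a fast-growing country would otherwise migrate out of the group whose
trajectory it drove). Countries not classified at the base year (newly
independent states) are retained as an `UNCLASSIFIED` group and excluded
from the four income-group aggregates. Each focus country adds a singleton
reporting group and a complement group ("LIC excluding …"), the standard
presentation when one economy dominates its group.

## Aggregation conventions

Group indicators are expenditure-weighted: levels are exact sums over
members with data, and ratios are ratios of the summed numerator and
denominator, so a billion-person economy carries a billion-person weight.
The package also computes the country-weighted average (plain mean of
member ratios, one vote per country) because the two conventions can
diverge substantially and the divergence itself is informative.

Two missing-data rules apply:

- *Ratios* use complete pairs: a member missing either component is
  dropped from **both** sums, keeping the numerator and denominator over
  an identical country set.
- *CHE composition shares* treat a missing component as zero with a
  `flagged` marker, because CHE composition is still publishable when one
  minor component (typically EXT) is unreported; dropping the country
  entirely would discard the four components that are present.

## Growth metrics

Both metrics are endpoint formulas — no log-linear regression smoothing:
total percent change $(x_1/x_0 - 1)\times 100$ and the annualized compound
rate $((x_1/x_0)^{1/(t_1-t_0)} - 1)\times 100$ with the exponent
denominator equal to the year difference (15 for 2000–2015). Stored values
keep full precision; presentation rounding is one decimal,
half-away-from-zero (`round_half_up()`), applied only in reports.

## Benchmarks and outliers

The Abuja flag tests government health spending as a share of GGE against
15%. The default numerator is GGHE-D **plus** external health expenditure
(government health spending from domestic and external sources, the
concept used in share-of-budget charts), with missing EXT contributing
zero; a GGHE-D-only variant is selectable since the two concepts are used
in different contexts. The GDP-band flag tests at 5%, the lower edge of
the 5–6%-of-GDP range discussed for universal health coverage; the upper
edge is informational. Flags carry the signed gap in percentage points and
are monotone in the threshold. Capital expenditure is not added to any
numerator — shares computed from current expenditure only slightly
understate the totals — and this is documented rather than adjusted.

The outlier screen has no published reference rule, so ours is explicit
and configurable: country values of an indicator ratio (and their period
changes) are flagged when strictly outside the nearest-rank percentile
cutoffs — the sorted values at ranks $\lceil p \cdot n\rceil$ for
$p = 0.01, 0.99$ — with ties broken deterministically by (value, iso3) and
tied values always sharing the same fate. Below 10 countries the
percentile rule refuses to run; absolute bounds remain available.

## The synthetic generator

`generate_panel()` exists so every pipeline stage can be tested without
redistributable source data. It emulates the *structure* of a GHED-like
panel: per-country multiplicative trajectories in which GDP, GGE/GDP,
GGHE-D/GGE and population each compound at the constant per-year factor
$(1+\text{rate})^{1/\text{span}}$ derived from a total-period group rate,
and CHE built additively from its five components in every cell. Growth
applied this way makes endpoint formulas exact regardless of intermediate
years, so a noise-free run must return the configured $(y, e, h)$ to
$10^{-9}$ relative — the sharpest possible end-to-end check. When noise is
requested it is lognormal multiplicative on levels, applied to the
components before CHE is re-summed, so additivity survives noise.

Defaults describe four income groups of 15 countries each plus two
focus-style large economies, observed 2000–2015. The group growth
parameters are total-period rates consistent with annualized group trends
of roughly 6.3/7.1/3.3/1.5% per year for GDP in low- to high-income groups
(e.g. a 15-year GDP rate of 1.50 for the low-income group), with
government-size and prioritization drifts of the same order as observed
group trajectories; base levels (GDP per capita from a few hundred to tens
of thousands of dollars, GGE/GDP from ~0.2 to ~0.4, OOP shares of CHE
from 0.60 down to 0.16) are GHED-like orders of magnitude. These are
structural stand-ins, not statistical replicas: the generator does not
reproduce real-world marginals, cross-country correlation, within-period
rate variation, or reclassification dynamics. Passing tests therefore
demonstrate correctness of the computations and conventions, not fidelity
of any real-world estimate. Missingness is injected independently per
(indicator, year) cell at configured rates with the mask recorded, which
is enough to exercise the inclusion filters but does not mimic the
block-wise missingness of real reporting.

All randomness is scoped to the configured seed (`withr::with_seed`), so a
configuration fully determines its panel.

## Problem sizes and numerical choices

The test suite generates its own fixtures: the shared default panel is 62
countries × 16 years; property-style loops use 20–30 random cases under
fixed seeds; the brute-force filter oracle runs on a 200-country panel and
the percentile oracle on 120–150 countries. The whole suite completes in
well under a minute on one CPU. Tolerances in tests reflect the
computation class: machine-precision identities at $10^{-12}$, noise-free
parameter recovery at $10^{-9}$ relative, sampling-based recovery at loose
relative bounds.

## Known limitations

- Constant-dollar conversion, deflation and upstream gap-filling are out
  of scope: inputs are assumed already expressed in constant dollars.
- The decomposition is not applied to external assistance, and efficiency
  of spending is not analysed.
- Reproducing full published group tables requires the original database
  snapshot; the package pins only cells that reproduce exactly from
  published aggregate inputs and treats full-cohort counts as external
  checks, not unit tests.
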