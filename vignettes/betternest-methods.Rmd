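---
title: "How the BetterNest Score is computed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the BetterNest Score is computed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betternest)
```

## The instrument and its model

The BetterNest Score is a household environmental-exposure screening index
for people who are considering pregnancy, pregnant, or parenting young
children. It is a *positive* health index: higher scores mean lower
environmental risk and more protective habits, a deliberate
motivational-interviewing framing that reports what the respondent is doing
well rather than what they should fear.

The instrument asks nine questions in macro-to-micro order: life stage (Q1,
never scored, but it selects the wording of two later questions), zipcode
(Q2, scored from county surveillance data), then tobacco smoke (Q3),
conventional cleaning products (Q4), pesticide spraying (Q5), plastics in
contact with food (Q6), organic-produce habits (Q7), daily personal-care
product volume (Q8), and ingredient checking (Q9).

Eight domain subscores, each an integer between 1 and 10, feed the index:

* **lead** — the percentage of county housing built before 1980 (a proxy for
  lead paint and plumbing) banded at fixed quintile cut-points
  41.05 / 50.3 / 58.8 / 69.3 % into subscores 9, 7, 5, 3, 1;
* **air** — the county's annual-average PM2.5 concentration banded at the
  EPA annual-standard anchors: below 12 µg/m³ scores 9, 12–15 µg/m³
  (inclusive) scores 5, above 15 µg/m³ scores 1;
* **tobacco, cleaning, pesticides, plastics, produce** — the raw score of
  the selected option (options are ordered most-to-least protective and
  scores decrease down that order);
* **personal_care** — a 3×3 lookup: the ingredient-checking answer (Q9) is
  scored under the product-volume modifier (Q8 ∈ {9, 5, 1}), so checking
  "all the time" scores 10/7/5 under low/medium/high product volume,
  "sometimes" 8/6/3, "never" 7/3/1. Q8 contributes no ninth domain; it only
  contextualizes Q9.

The final index is the **unweighted arithmetic mean of the eight subscores,
rounded half-up to one decimal**:

$$\text{score} = \operatorname{round}_{0.1}\!\left(\tfrac{1}{8}\sum_{d=1}^{8} s_d\right)$$

Unweighted averaging keeps the index interpretable for a non-technical
audience; the instrument is a screening and education tool, not a dose
estimate.

## Numerical choices

**Rounding.** "Rounded to the tenths" admits several conventions, but the
index's published minimum pins one down: the worst attainable subscore
vector sums to 10, a mean of exactly 1.25, and the published minimum is 1.3.
That forces rounding half *away from zero*; banker's rounding (R's
`round()`) would give 1.2. `aggregate_score()` therefore works in exact
integer arithmetic on `sum * 10` and applies a single half-up rounding step
— there is no floating-point accumulation anywhere in the pipeline.

**Band edges.** The printed lead bands ("41.05–<50.3", "58.8–<69.3",
">69.3") leave a value of exactly 69.3 unassigned. We use uniformly
half-open bands `[lower, upper)` with the top band `[69.3, 100]`. The
percentage is a continuous measure, so the convention is practically
immaterial, but it must be pinned for tests — every edge is asserted in a
table-driven test. The PM2.5 middle band is read as the closed interval
`[12, 15]`, consistent with its neighbours being "<12" and ">15". The PM2.5
bands are the fixed printed cut-points, not empirical tertiles recomputed
from data.

**Degenerate inputs.** Incomplete response sets are rejected, never imputed:
with only nine questions, a partial mean would silently change what the
index measures. A postal code absent from the crosswalk is a hard error
rather than a national-median fallback. Out-of-range county measures
(percentage outside [0, 100], negative or non-finite PM2.5) are domain
errors.

**Tie-breaks.** Recommendations go to the three lowest-scoring domains;
among ties we use stable instrument order (lead, air, tobacco, cleaning,
pesticides, plastics, produce, personal_care), so ties favor the broader,
macro-level environmental domain. This is a design choice — the published
description does not specify a tie-break — and it is deterministic and
pinned by tests.

## Verifying the published claims by enumeration

The final score factors through the eight subscores, and the county
questions factor through their bands, so the full response space is the
cross-product of 5 lead bands × 3 air bands × the option sets of Q3–Q9,
with Q8 and Q9 jointly contributing 9 combinations:
5·3·4·3·3·4·3·9 = 58,320 outcomes. `enumerate_scores()` scores all of them
(well under a second) and certifies:

```{r}
enum <- enumerate_scores()
glance(enum)
```

* the attainable range is exactly **1.3 to 9.4** — by construction nobody
  sees a perfect 10.0 (there is always room to improve) or a bare 1.0 (the
  tool never tells a respondent they failed outright);
* **monotonicity**: improving any single answer — including moving Q8
  toward fewer products at fixed Q9, since every row of the modifier matrix
  increases with the Q8 modifier — never lowers the final score. This is
  checked as zero adjacent-pair decreases along every axis of the
  58,320-cell score array;
* the score histogram (`tidy(enum)`, plotted by `autoplot(enum)`) sums to
  58,320 and is identical across runs.

The enumeration is also the oracle harness for the recommendation contract:
for every outcome, `select_recommendations()` is compared against a
brute-force "sort all eight, take the first three with the stable
tie-break" reference.

## The synthetic county table

Live county surveillance data (housing age and modeled PM2.5) requires
network access and a maintained crosswalk, so `generate_geo_fixture()`
produces a deterministic, seed-controlled synthetic stand-in: counties are
cycled through the five lead bands and three air bands (all bands are
exercised whenever `n_counties >= 15`), measures are drawn uniformly within
each band, and each county gets one to three unique five-digit postal
codes. The CSV files carry a `# vintage:` comment for provenance; scoring
ignores it.

What the fixture does *not* emulate: the real national distribution of
housing age and PM2.5 (real counties are not uniform within bands and the
bands are not equally populated), ZIP codes that straddle county lines
(each synthetic code maps to exactly one county, matching the tool's
zip-to-county simplification), and any correlation between housing age and
air quality. Passing tests therefore demonstrate the *algorithmic* contract
— banding, lookup, aggregation, reporting — not calibration against real
surveillance data. Because every subscore path is exercised exhaustively by
`enumerate_scores()`, this costs no coverage: any real county falls into
one of the enumerated bands.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| lead cut-points | 41.05, 50.3, 58.8, 69.3 | % pre-1980 housing | fixed quintile anchors of the county distribution |
| PM2.5 cut-points | 12, 15 | µg/m³ annual mean | EPA annual-standard anchors |
| `n_counties` | 15 | counties | fixture size; ≥ 15 guarantees full band coverage |
| `seed` | — | integer | controls all fixture draws |
| `factsheet_base_url` | `https://example.org/factsheets` | URL | base for the `{factsheet_url}` link slot in recommendations |

The cut-points live in the packaged instrument definition
(`inst/extdata/instrument.json`) and are validated on load; they are part
of the instrument, not user-tunable knobs.

## Recommendations and tone

Each of the eight domains has one recommendation template with a
`{factsheet_url}` link slot. Three templates (lead, plastics,
personal-care) are the tool's published texts and are pinned byte-for-byte
in tests; the other five are authored stand-ins in the same register,
marked `canonical = FALSE` and excluded from byte-exact tests. All
templates must pass a small fear-framing blocklist
(`check_recommendation_tone()`) and end with a factsheet pointer — the
mechanical residue of the motivational-interviewing constraint that
feedback be non-judgmental and autonomy-supportive.

Reports also include a per-domain contribution table (each domain
contributes subscore/8 points of the final index). This extends the
launched tool: it answers focus-group users who asked which exposures
contribute most to their score.

## Known limitations

* County-level banding can mask hyper-local variation; census-tract
  granularity is out of scope.
* The index is a screening and education instrument, not a clinical
  diagnostic or exposure-dose estimate; no weighting or biomarker
  calibration is attempted.
* The zip-to-county crosswalk assumes one county per ZIP; many real ZIPs
  straddle counties.
* Five of the eight recommendation texts are authored stand-ins, not the
  launched tool's copy.
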