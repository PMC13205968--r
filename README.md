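# betternest

Household environmental-exposure screening for pregnant women and parents.

The perinatal period is both a critical window of susceptibility to
environmental exposures (endocrine-disrupting chemicals, lead, fine
particulate air pollution, tobacco smoke, pesticides) and a moment of
unusually high motivation to act. **betternest** implements the BetterNest
Score: a nine-question screening instrument that converts survey answers
plus county-level surveillance data (percentage of pre-1980 housing as a
lead proxy; annual-average PM2.5) into a single 1.0–10.0 *positive* health
index — higher means lower risk — together with the respondent's three
highest-priority behavioral recommendations, phrased in a non-judgmental,
motivational-interviewing register.

## The score

Eight integer domain subscores $s_d \in [1, 10]$ are combined as an
unweighted mean, rounded half-up to one decimal:

$$\text{score} = \operatorname{round}_{0.1}\!\Big(\tfrac{1}{8}\sum_{d=1}^{8} s_d\Big)$$

* **lead**: county % pre-1980 housing banded at 41.05 / 50.3 / 58.8 / 69.3 %
  into 9 / 7 / 5 / 3 / 1;
* **air**: county annual PM2.5 banded at the EPA anchors — < 12 µg/m³ → 9,
  12–15 µg/m³ → 5, > 15 µg/m³ → 1;
* **tobacco, cleaning, pesticides, plastics, produce**: the raw score of
  the selected response option;
* **personal_care**: the ingredient-checking answer (Q9) scored through a
  3×3 modifier matrix indexed by daily product volume (Q8); Q8 itself never
  enters the mean.

Over all 58,320 attainable response combinations the score spans exactly
**1.3 to 9.4**: no one gets a perfect 10 (there is always room to improve)
and no one gets a bare 1. The package ships an exhaustive enumerator that
certifies this range, the score distribution, and the property that
improving any single answer never lowers the score.

## Worked example

```r
library(betternest)

# synthetic county table standing in for federal surveillance data
geo <- generate_geo_fixture(15, seed = 7)

resp <- tibble::tibble(
  life_stage = "currently_pregnant", postal_code = "47381",
  Q3 = "few_times_week",   # around smokers a few times a week
  Q4 = "weekly",           # conventional cleaners weekly
  Q5 = "sometimes_unsure", # pesticides sometimes / not sure
  Q6 = "few_week",         # plastics contact a few times a week
  Q7 = "sometimes",        # sometimes buys organic
  Q8 = "ten_to_18",        # 10-18 personal care products daily
  Q9 = "sometimes"         # sometimes checks ingredients
)

scored <- score_responses(resp, geo)
scored[, c("lead", "air", "tobacco", "cleaning", "pesticides",
           "plastics", "produce", "personal_care", "score")]
#> # A tibble: 1 × 9
#>    lead   air tobacco cleaning pesticides plastics produce personal_care score
#>   <int> <int>   <int>    <int>      <int>    <int>   <int>         <int> <dbl>
#> 1     9     9       6        6          5        3       5             6   6.1

scored$recommendations[[1]][, c("rank", "domain_key", "subscore")]
#> # A tibble: 3 × 3
#>    rank domain_key subscore
#>   <int> <chr>         <int>
#> 1     1 plastics          3
#> 2     2 pesticides        5
#> 3     3 produce           5
```

The respondent's zipcode resolved to a county in the cleanest lead and air
bands (subscores 9 and 9); the subscores sum to 49, the exact mean is
49/8 = 6.125, and half-up tenths rounding prints **6.1**. The three
lowest-scoring domains — plastics (3), then pesticides and produce (5 each,
ordered by the instrument's macro-to-micro tie-break) — become the three
recommendations, each rendered from its template with a factsheet link.

The enumeration harness certifies the printed range claims:

```r
glance(enumerate_scores())
#> # A tibble: 1 × 4
#>   n_outcomes min_score max_score monotonicity_violations
#>        <int>     <dbl>     <dbl>                   <dbl>
#> 1      58320       1.3       9.4                       0
```

`tidy()` returns the score histogram, `autoplot()` plots it, and
`tidy(scored)` gives a per-domain contribution table (each domain
contributes subscore/8 points of the final index).

## Command line

A thin Rscript wrapper ships at `inst/cli/betternest`:

```sh
betternest gen-fixtures --n-counties 15 --seed 7 --out fixtures/
betternest score --responses answers.json --geodata fixtures/ --format text
betternest interactive --geodata fixtures/ --save-responses answers.json
betternest enumerate --out summary.json
betternest validate --responses answers.json
```

Exit codes: 0 ok, 2 validation error, 3 geodata error, 4 I/O/usage error.
Responses are a flat JSON object
(`{"life_stage": ..., "postal_code": ..., "Q3": ..., ..., "Q9": ...}`);
geodata is a directory with `counties.csv` and `crosswalk.csv`.

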