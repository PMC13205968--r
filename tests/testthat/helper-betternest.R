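# shared fixtures, built in code

# three handmade counties spanning the clean / middling / high-risk bands
make_test_geo <- function() {
  bn_geotable(
    counties = tibble::tibble(
      county_id = c("CLEAN", "MID", "RISKY"),
      pct_pre1980_housing = c(30, 55, 80),
      pm25_annual = c(8, 13, 20)
    ),
    crosswalk = tibble::tibble(
      postal_code = c("00001", "00002", "00003"),
      county_id = c("CLEAN", "MID", "RISKY")
    )
  )
}

make_responses <- function(postal_code = "00001",
                           life_stage = "currently_pregnant",
                           Q3 = "never_public", Q4 = "green_only",
                           Q5 = "never_rarely", Q6 = "almost_never",
                           Q7 = "always_dirtydozen", Q8 = "under_10",
                           Q9 = "all_the_time") {
  tibble::tibble(
    life_stage = life_stage, postal_code = postal_code,
    Q3 = Q3, Q4 = Q4, Q5 = Q5, Q6 = Q6, Q7 = Q7, Q8 = Q8, Q9 = Q9
  )
}

best_responses <- function(postal_code = "00001") make_responses(postal_code)

worst_responses <- function(postal_code = "00003") {
  make_responses(
    postal_code = postal_code,
    Q3 = "daily_smoker", Q4 = "daily", Q5 = "regularly", Q6 = "daily",
    Q7 = "never_cheapest", Q8 = "over_18", Q9 = "never"
  )
}

# independent half-up oracle: the exact mean of 8 integers has at most three
# decimals (sum * 0.125), so decide the tenths digit from exact thousandths
oracle_mean8_half_up <- function(sum8) {
  thousandths <- sum8 * 125L
  base <- thousandths %/% 100L
  (base + as.integer(thousandths %% 100L >= 50L)) / 10
}

# brute-force 3-smallest selection with stable instrument-order tie-break
oracle_pick3 <- function(subscores) {
  ord <- order(subscores, seq_along(subscores))
  ord[1:3]
}
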