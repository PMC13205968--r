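#' Lead-risk subscore from county housing age
#'
#' Bands the percentage of county housing built before 1980 — a proxy for
#' residential lead paint and plumbing risk — into a subscore using fixed
#' quintile cut-points (41.05, 50.3, 58.8, 69.3, derived from the national
#' county distribution). Bands are half-open `[lower, upper)`, with the top
#' band `[69.3, 100]`; a higher percentage means older housing and a lower
#' (riskier) subscore.
#'
#' @param pct Numeric vector of percentages in \[0, 100\].
#' @return Integer vector of subscores in \{9, 7, 5, 3, 1\}.
#' @export
#' @examples
#' lead_subscore(c(35, 41.05, 60, 75))
lead_subscore <- function(pct) {
  if (anyNA(pct) || any(!is.finite(pct)) || any(pct < 0 | pct > 100)) {
    abort("pct_pre1980_housing must be finite and in [0, 100]",
      class = "bn_domain_error")
  }
  scores <- c(9L, 7L, 5L, 3L, 1L)
  scores[findInterval(pct, c(41.05, 50.3, 58.8, 69.3)) + 1L]
}

#' Air-quality subscore from annual-average PM2.5
#'
#' Bands a county's annual-average fine particulate concentration into a
#' subscore anchored to the EPA annual PM2.5 standards: below 12 ug/m3 scores
#' 9, 12 to 15 ug/m3 (inclusive on both ends) scores 5, and above 15 ug/m3
#' scores 1.
#'
#' @param pm25 Numeric vector of concentrations in ug/m3, non-negative.
#' @return Integer vector of subscores in \{9, 5, 1\}.
#' @export
#' @examples
#' air_subscore(c(10, 12, 13.5, 15, 16.2))
air_subscore <- function(pm25) {
  if (anyNA(pm25) || any(!is.finite(pm25)) || any(pm25 < 0)) {
    abort("pm25_annual must be finite and non-negative", class = "bn_domain_error")
  }
  dplyr::case_when(pm25 < 12 ~ 9L, pm25 <= 15 ~ 5L, TRUE ~ 1L)
}

#' Construct a validated county environmental table
#'
#' @param counties Data frame with columns `county_id`,
#'   `pct_pre1980_housing` (percent, \[0, 100\]) and `pm25_annual`
#'   (ug/m3, >= 0).
#' @param crosswalk Data frame with columns `postal_code` (unique five-digit
#'   strings) and `county_id`; every `county_id` must exist in `counties`.
#' @param vintage Data-vintage label carried through CSV round-trips; scoring
#'   ignores it.
#' @return An object of class `bn_geotable`.
#' @export
bn_geotable <- function(counties, crosswalk, vintage = "2020") {
  counties <- tibble::as_tibble(counties)
  crosswalk <- tibble::as_tibble(crosswalk)
  need_cty <- c("county_id", "pct_pre1980_housing", "pm25_annual")
  need_xw <- c("postal_code", "county_id")
  if (!all(need_cty %in% names(counties)) || nrow(counties) == 0L) {
    abort("counties table must be non-empty with columns county_id, pct_pre1980_housing, pm25_annual",
      class = "bn_malformed_geo_csv")
  }
  if (!all(need_xw %in% names(crosswalk)) || nrow(crosswalk) == 0L) {
    abort("crosswalk table must be non-empty with columns postal_code, county_id",
      class = "bn_malformed_geo_csv")
  }
  if (anyDuplicated(counties$county_id)) {
    abort("duplicate county_id in counties table", class = "bn_malformed_geo_csv")
  }
  if (anyDuplicated(crosswalk$postal_code)) {
    abort("duplicate postal_code in crosswalk", class = "bn_malformed_geo_csv")
  }
  bad <- !is.finite(counties$pct_pre1980_housing) |
    counties$pct_pre1980_housing < 0 | counties$pct_pre1980_housing > 100 |
    !is.finite(counties$pm25_annual) | counties$pm25_annual < 0
  if (any(bad)) {
    abort("county measures out of range (pct in [0,100], pm25 >= 0)",
      class = "bn_malformed_geo_csv")
  }
  dangling <- setdiff(crosswalk$county_id, counties$county_id)
  if (length(dangling) > 0L) {
    abort(paste0("crosswalk references unknown county_id: ",
                 paste(dangling, collapse = ", ")),
      class = "bn_dangling_crosswalk", county_id = dangling)
  }
  structure(
    list(counties = counties[need_cty], crosswalk = crosswalk[need_xw],
         vintage = vintage),
    class = "bn_geotable"
  )
}

#' @export
print.bn_geotable <- function(x, ...) {
  cat("<bn_geotable> vintage", x$vintage, "-", nrow(x$counties), "counties,",
      nrow(x$crosswalk), "postal codes\n")
  print(x$counties)
  invisible(x)
}

#' Resolve postal codes to county records
#'
#' Looks each postal code up in the geotable crosswalk. A code absent from
#' the crosswalk is a hard error — no national-median fallback — so a typo
#' cannot silently corrupt the index.
#'
#' @param postal_code Character vector of five-digit postal codes.
#' @param geo A `bn_geotable`.
#' @return A tibble with one row per input code: `postal_code`, `county_id`,
#'   `pct_pre1980_housing`, `pm25_annual`.
#' @export
resolve_county <- function(postal_code, geo) {
  stopifnot(inherits(geo, "bn_geotable"))
  unknown <- setdiff(postal_code, geo$crosswalk$postal_code)
  if (length(unknown) > 0L) {
    abort(paste0("postal code not in crosswalk: ",
                 paste(unique(unknown), collapse = ", ")),
      class = "bn_unknown_postal_code", postal_code = unique(unknown))
  }
  tibble::tibble(postal_code = postal_code) |>
    dplyr::left_join(geo$crosswalk, by = "postal_code") |>
    dplyr::left_join(geo$counties, by = "county_id")
}

# band ranges the fixture generator draws from; chosen so every printed band
# is exercised, including values close to each cut-point
lead_band_ranges <- rbind(
  c(5, 41.05), c(41.05, 50.3), c(50.3, 58.8), c(58.8, 69.3), c(69.3, 95)
)
air_band_ranges <- rbind(c(4, 12), c(12, 15), c(15, 25))

#' Generate a synthetic county environmental table
#'
#' Produces a deterministic, seed-controlled stand-in for the federal
#' county-level surveillance data the tool scores against (county percentage
#' of pre-1980 housing and annual-average PM2.5). Counties are cycled through
#' the five lead bands and three air bands so that all bands are represented
#' whenever `n_counties >= 15`; measures are drawn uniformly within each
#' band and every county receives one to three unique postal codes.
#'
#' @param n_counties Number of counties, >= 1.
#' @param seed Integer seed controlling all draws.
#' @return A `bn_geotable`.
#' @export
#' @examples
#' geo <- generate_geo_fixture(15, seed = 7)
#' geo$counties
generate_geo_fixture <- function(n_counties, seed) {
  stopifnot(n_counties >= 1)
  withr::local_seed(seed)
  i <- seq_len(n_counties)
  lead_band <- ((i - 1L) %% 5L) + 1L
  air_band <- ((i - 1L) %% 3L) + 1L
  pct <- stats::runif(n_counties,
    lead_band_ranges[lead_band, 1], lead_band_ranges[lead_band, 2])
  pm25 <- stats::runif(n_counties,
    air_band_ranges[air_band, 1], air_band_ranges[air_band, 2])
  counties <- tibble::tibble(
    county_id = sprintf("C%04d", i),
    pct_pre1980_housing = round(pct, 2),
    pm25_annual = round(pm25, 2)
  )
  n_codes <- sample(1:3, n_counties, replace = TRUE)
  codes <- sprintf("%05d", sample(0:99999, sum(n_codes)))
  crosswalk <- tibble::tibble(
    postal_code = codes,
    county_id = rep(counties$county_id, n_codes)
  )
  bn_geotable(counties, crosswalk, vintage = "2020")
}

#' Write a geotable to CSV files
#'
#' Writes `counties.csv` (with a `# vintage:` header comment recording data
#' provenance) and `crosswalk.csv` into a directory, in the dialect
#' [read_geotable()] reads back.
#'
#' @param geo A `bn_geotable`.
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_geotable <- function(geo, dir) {
  stopifnot(inherits(geo, "bn_geotable"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cty_path <- file.path(dir, "counties.csv")
  writeLines(paste0("# vintage: ", geo$vintage), cty_path)
  readr::write_csv(geo$counties, cty_path, append = TRUE, col_names = TRUE)
  readr::write_csv(geo$crosswalk, file.path(dir, "crosswalk.csv"))
  invisible(dir)
}

#' Read a geotable from CSV files
#'
#' Expects `counties.csv` (header `county_id,pct_pre1980_housing,pm25_annual`,
#' UTF-8, dot decimal separator, optional `#` comment lines) and
#' `crosswalk.csv` (header `postal_code,county_id`) in `dir`. Referential
#' integrity is enforced: a crosswalk row pointing at a county absent from
#' the counties table is an error naming that county.
#'
#' @param dir Directory containing the two CSV files.
#' @return A `bn_geotable`.
#' @export
read_geotable <- function(dir) {
  cty_path <- file.path(dir, "counties.csv")
  xw_path <- file.path(dir, "crosswalk.csv")
  if (!file.exists(cty_path) || !file.exists(xw_path)) {
    abort(paste0("expected counties.csv and crosswalk.csv in ", dir),
      class = "bn_malformed_geo_csv")
  }
  first <- readLines(cty_path, n = 1L)
  vintage <- if (grepl("^# vintage:", first)) {
    trimws(sub("^# vintage:", "", first))
  } else {
    "unknown"
  }
  counties <- tryCatch(
    readr::read_csv(cty_path, comment = "#", show_col_types = FALSE,
      col_types = readr::cols(
        county_id = readr::col_character(),
        pct_pre1980_housing = readr::col_double(),
        pm25_annual = readr::col_double()
      )),
    error = function(e) abort(paste0("malformed counties.csv: ", conditionMessage(e)),
      class = "bn_malformed_geo_csv")
  )
  crosswalk <- tryCatch(
    readr::read_csv(xw_path, comment = "#", show_col_types = FALSE,
      col_types = readr::cols(
        postal_code = readr::col_character(),
        county_id = readr::col_character()
      )),
    error = function(e) abort(paste0("malformed crosswalk.csv: ", conditionMessage(e)),
      class = "bn_malformed_geo_csv")
  )
  probs <- dplyr::bind_rows(readr::problems(counties), readr::problems(crosswalk))
  if (nrow(probs) > 0L) {
    abort(paste0("malformed geodata CSV at row ", probs$row[1], ": ",
                 probs$expected[1]),
      class = "bn_malformed_geo_csv")
  }
  bn_geotable(counties, crosswalk, vintage = vintage)
}
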