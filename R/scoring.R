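#' Personal-care subscore from the modifier matrix
#'
#' The product-volume question (Q8) never enters the final mean directly;
#' it contextualizes the ingredient-checking question (Q9) through a 3x3
#' lookup: checking ingredients "all the time" scores 10/7/5 under low,
#' medium and high product volume, "sometimes" scores 8/6/3, and "never"
#' scores 7/3/1. Every row of the matrix increases with the Q8 modifier, so
#' using fewer products can only help the score.
#'
#' @param q8_modifier Integer vector in \{9, 5, 1\} (Q8 option modifiers, in
#'   decreasing-protection order: <10, 10-18, >18 daily products).
#' @param q9_option Character vector in `"all_the_time"`, `"sometimes"`,
#'   `"never"`.
#' @param instrument A `bn_instrument`.
#' @return Integer vector of personal-care subscores.
#' @export
#' @examples
#' personal_care_subscore(9, "all_the_time")
#' personal_care_subscore(c(5, 1), c("sometimes", "never"))
personal_care_subscore <- function(q8_modifier, q9_option,
                                   instrument = bn_instrument()) {
  mm <- instrument$modifier_matrix
  key <- paste(q9_option, q8_modifier)
  lut <- stats::setNames(mm$subscore, paste(mm$q9_option, mm$q8_modifier))
  if (any(!key %in% names(lut))) {
    abort(paste0("invalid Q8 modifier / Q9 option combination: ",
                 key[!key %in% names(lut)][1]),
      class = "bn_unknown_option")
  }
  unname(lut[key])
}

option_score_lookup <- function(instrument, qid, option_id) {
  o <- instrument$options
  sel <- o[o$qid == qid, ]
  lut <- stats::setNames(sel$raw_score, sel$option_id)
  unname(lut[option_id])
}

#' Compute the eight domain subscores
#'
#' Resolves each respondent's postal code to county measures, bands them
#' into the lead and air subscores, takes the printed raw score of each
#' selected option for the tobacco, cleaning, pesticides, plastics and
#' produce questions, and derives the personal-care subscore from the Q8
#' modifier and Q9 option via the modifier matrix. Q8 contributes no ninth
#' domain of its own.
#'
#' @param data A responses data frame (validated with [validate_responses()];
#'   validation is applied here regardless).
#' @param geo A `bn_geotable`.
#' @param instrument A `bn_instrument`.
#' @return A tibble of class `bn_subscores`: one row per respondent with
#'   `postal_code`, `county_id` and the eight integer domain columns
#'   `lead`, `air`, `tobacco`, `cleaning`, `pesticides`, `plastics`,
#'   `produce`, `personal_care`.
#' @export
#' @examples
#' geo <- generate_geo_fixture(15, seed = 7)
#' resp <- bn_example_responses()
#' resp$postal_code <- geo$crosswalk$postal_code[1]
#' compute_subscores(resp, geo)
compute_subscores <- function(data, geo, instrument = bn_instrument()) {
  data <- validate_responses(data, instrument)
  county <- resolve_county(data$postal_code, geo)
  out <- tibble::tibble(
    postal_code = data$postal_code,
    county_id = county$county_id,
    lead = lead_subscore(county$pct_pre1980_housing),
    air = air_subscore(county$pm25_annual),
    tobacco = option_score_lookup(instrument, "Q3", data$Q3),
    cleaning = option_score_lookup(instrument, "Q4", data$Q4),
    pesticides = option_score_lookup(instrument, "Q5", data$Q5),
    plastics = option_score_lookup(instrument, "Q6", data$Q6),
    produce = option_score_lookup(instrument, "Q7", data$Q7),
    personal_care = personal_care_subscore(
      option_score_lookup(instrument, "Q8", data$Q8), data$Q9, instrument
    )
  )
  class(out) <- c("bn_subscores", class(out))
  out
}

# Exact aggregation: the final index is the unweighted mean of the eight
# integer subscores, rounded half-up (half away from zero) to one decimal.
# Done in integer arithmetic on sum*10 so there is no floating-point drift
# and exactly one rounding step: a mean of 1.25 rounds to 1.3, never 1.2.
round_mean8_half_up <- function(sum8) {
  sum8 <- as.integer(sum8)
  num <- sum8 * 10L
  q <- num %/% 8L
  r <- num %% 8L
  (q + as.integer(2L * r >= 8L)) / 10
}

#' Aggregate subscores into the final index
#'
#' Appends the final score — the unweighted arithmetic mean of the eight
#' domain subscores, rounded half-up to one decimal — to a subscore table.
#' Over all attainable subscore combinations the score spans 1.3 to 9.4:
#' the instrument is constructed so no one sees a perfect 10 (there is
#' always room to improve) or a bare 1 (no one is told they failed).
#'
#' @param data A data frame containing the eight domain columns (see
#'   [compute_subscores()]).
#' @return `data` with an added `score` column (one decimal place).
#' @export
#' @examples
#' aggregate_score(tibble::tibble(
#'   lead = 1, air = 1, tobacco = 1, cleaning = 2, pesticides = 1,
#'   plastics = 1, produce = 2, personal_care = 1
#' ))
aggregate_score <- function(data) {
  missing <- setdiff(bn_domain_order, names(data))
  if (length(missing) > 0L) {
    abort(paste0("missing subscore columns: ", paste(missing, collapse = ", ")),
      class = "bn_domain_error")
  }
  sub <- as.matrix(data[bn_domain_order])
  if (anyNA(sub) || any(sub != round(sub)) || any(sub < 1 | sub > 10)) {
    abort("subscores must be integers in [1, 10]", class = "bn_domain_error")
  }
  data$score <- round_mean8_half_up(rowSums(sub))
  data
}

#' Score survey responses
#'
#' The full pipeline: validate the responses, resolve each postal code to
#' county measures, compute the eight domain subscores, aggregate them into
#' the final 1.0-10.0 index (higher = lower environmental risk), and attach
#' the three highest-priority recommendations per respondent.
#'
#' @inheritParams compute_subscores
#' @param factsheet_base_url Base URL substituted into recommendation
#'   factsheet links.
#' @return A tibble of class `bn_scores`: one row per respondent with
#'   `life_stage`, `postal_code`, `county_id`, the eight subscore columns,
#'   `score`, and a `recommendations` list-column of three-row tibbles.
#' @export
#' @examples
#' geo <- generate_geo_fixture(15, seed = 7)
#' resp <- bn_example_responses()
#' resp$postal_code <- geo$crosswalk$postal_code[1]
#' scored <- score_responses(resp, geo)
#' scored$score
score_responses <- function(data, geo, instrument = bn_instrument(),
                            factsheet_base_url = bn_default_factsheet_url) {
  data <- validate_responses(data, instrument)
  sub <- compute_subscores(data, geo, instrument)
  sub <- aggregate_score(sub)
  recs <- select_recommendations(sub, factsheet_base_url = factsheet_base_url)
  out <- dplyr::bind_cols(
    data[c("life_stage", "wording_variant")], sub
  )
  out$recommendations <- lapply(
    split(recs, recs$respondent),
    function(d) tibble::as_tibble(d[setdiff(names(d), "respondent")])
  )
  out$instrument_version <- instrument$version
  class(out) <- c("bn_scores", setdiff(class(out), "bn_subscores"))
  out
}

#' Tidy a scored-responses table into long domain form
#'
#' One row per respondent x domain, with the domain subscore and its
#' contribution to the final index (each domain contributes subscore/8
#' points), supporting the per-domain contribution summary in reports.
#'
#' @param x A `bn_scores` tibble from [score_responses()].
#' @param ... Unused.
#' @return A tibble with columns `respondent`, `domain_key`, `subscore`,
#'   `points` (subscore/8) and `share` (fraction of the summed subscores).
#' @export
tidy.bn_scores <- function(x, ...) {
  long <- tibble::as_tibble(x)[bn_domain_order]
  long$respondent <- seq_len(nrow(long))
  long <- tidyr::pivot_longer(long, -"respondent",
    names_to = "domain_key", values_to = "subscore")
  long |>
    dplyr::group_by(.data$respondent) |>
    dplyr::mutate(
      points = .data$subscore / 8,
      share = .data$subscore / sum(.data$subscore)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(domain_key = factor(.data$domain_key, levels = bn_domain_order)) |>
    dplyr::arrange(.data$respondent, .data$domain_key)
}

#' Plot the domain subscores of scored responses
#'
#' @param object A `bn_scores` tibble from [score_responses()].
#' @param ... Unused.
#' @return A ggplot: one bar per domain (faceted by respondent when several
#'   rows are scored), higher bars = more protective.
#' @export
autoplot.bn_scores <- function(object, ...) {
  long <- tidy(object)
  p <- ggplot2::ggplot(long,
    ggplot2::aes(x = .data$domain_key, y = .data$subscore)) +
    ggplot2::geom_col(fill = "#2a9d8f") +
    ggplot2::scale_y_continuous(limits = c(0, 10), breaks = seq(0, 10, 2)) +
    ggplot2::labs(x = NULL, y = "domain subscore (higher = more protective)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (length(unique(long$respondent)) > 1L) {
    p <- p + ggplot2::facet_wrap(~respondent)
  }
  p
}
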