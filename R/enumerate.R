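#' Full factorial grid of attainable subscore vectors
#'
#' The final score factors through the eight domain subscores, and the
#' county questions factor through their bands, so the instrument's whole
#' response space is the cross-product of 5 lead bands x 3 air bands x the
#' Q3..Q9 option sets (with Q9 scored through the Q8 modifier matrix):
#' 5 * 3 * 4 * 3 * 3 * 4 * 3 * (3 * 3) = 58,320 outcomes. Within each axis,
#' levels are ordered from least to most protective.
#'
#' @param instrument A `bn_instrument`.
#' @return A tibble with 58,320 rows: index columns `lead_band`, `air_band`,
#'   `q3`..`q9` (level ranks, 1 = least protective) and the eight domain
#'   subscore columns.
#' @export
subscore_grid <- function(instrument = bn_instrument()) {
  opt_scores <- function(qid) {
    sort(instrument$options$raw_score[instrument$options$qid == qid])
  }
  lead_levels <- sort(instrument$lead_scores)
  air_levels <- sort(instrument$air_scores)
  q3 <- opt_scores("Q3"); q4 <- opt_scores("Q4"); q5 <- opt_scores("Q5")
  q6 <- opt_scores("Q6"); q7 <- opt_scores("Q7")
  q8_mods <- sort(instrument$options$raw_score[instrument$options$qid == "Q8"])
  q9_levels <- c("never", "sometimes", "all_the_time")

  grid <- tidyr::expand_grid(
    lead_band = seq_along(lead_levels),
    air_band = seq_along(air_levels),
    q3 = seq_along(q3), q4 = seq_along(q4), q5 = seq_along(q5),
    q6 = seq_along(q6), q7 = seq_along(q7),
    q8 = seq_along(q8_mods), q9 = seq_along(q9_levels)
  )
  grid$lead <- lead_levels[grid$lead_band]
  grid$air <- air_levels[grid$air_band]
  grid$tobacco <- q3[grid$q3]
  grid$cleaning <- q4[grid$q4]
  grid$pesticides <- q5[grid$q5]
  grid$plastics <- q6[grid$q6]
  grid$produce <- q7[grid$q7]
  grid$personal_care <- personal_care_subscore(
    q8_mods[grid$q8], q9_levels[grid$q9], instrument
  )
  grid
}

# count adjacent-pair decreases along dimension d of a score array whose
# axes are ordered worst -> best
count_dim_decreases <- function(arr, d) {
  n <- dim(arr)[d]
  idx_lo <- rep(list(quote(expr = )), length(dim(arr)))
  idx_hi <- idx_lo
  idx_lo[[d]] <- seq_len(n - 1L)
  idx_hi[[d]] <- seq_len(n - 1L) + 1L
  lo <- do.call(`[`, c(list(arr), idx_lo, list(drop = FALSE)))
  hi <- do.call(`[`, c(list(arr), idx_hi, list(drop = FALSE)))
  sum(hi < lo)
}

#' Exhaustively enumerate the attainable score space
#'
#' Scores every one of the 58,320 combinations of lead band, air band and
#' Q3..Q9 response options, certifying the instrument's printed claims: the
#' attainable range is exactly 1.3 to 9.4 (no respondent can score a perfect
#' 10.0 or a bare 1.0), and improving any single answer — including moving
#' Q8 toward fewer products at fixed Q9 — never lowers the final score.
#'
#' @param instrument A `bn_instrument`.
#' @param raw_means Also keep the exact (unrounded) means in the histogram?
#' @return An object of class `bn_enumeration`: a list with `n_outcomes`,
#'   `min_score`, `max_score`, `histogram` (tibble `score`, `n`, and
#'   `mean_exact` when `raw_means`), and `monotonicity_violations`.
#' @export
#' @examples
#' enum <- enumerate_scores()
#' glance(enum)
enumerate_scores <- function(instrument = bn_instrument(), raw_means = FALSE) {
  grid <- subscore_grid(instrument)
  sums <- as.integer(rowSums(as.matrix(grid[bn_domain_order])))
  scores <- round_mean8_half_up(sums)

  if (raw_means) {
    histogram <- tibble::tibble(sum8 = sums) |>
      dplyr::count(.data$sum8) |>
      dplyr::mutate(
        mean_exact = .data$sum8 / 8,
        score = round_mean8_half_up(.data$sum8)
      ) |>
      dplyr::group_by(.data$score, .data$mean_exact) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
      dplyr::arrange(.data$score, .data$mean_exact) |>
      dplyr::select("score", "mean_exact", "n")
  } else {
    histogram <- tibble::tibble(score = scores) |>
      dplyr::count(.data$score) |>
      dplyr::arrange(.data$score)
  }

  # the grid is a full factorial in standard expand order, so the scores
  # reshape into an array with one axis per question/band, each ordered
  # worst -> best; monotonicity = no decrease along any axis
  dims <- c(5L, 3L, 4L, 3L, 3L, 4L, 3L, 3L, 3L)
  # expand_grid varies the LAST column fastest; reverse so dim 1 is fastest
  arr <- array(scores, dim = rev(dims))
  violations <- sum(vapply(seq_along(dims),
    function(d) count_dim_decreases(arr, d), numeric(1)))

  structure(
    list(
      n_outcomes = nrow(grid),
      min_score = min(scores),
      max_score = max(scores),
      histogram = histogram,
      monotonicity_violations = violations
    ),
    class = "bn_enumeration"
  )
}

#' @export
print.bn_enumeration <- function(x, ...) {
  cat("<bn_enumeration>", x$n_outcomes, "outcomes\n")
  cat("  score range:", sprintf("%.1f", x$min_score), "to",
      sprintf("%.1f", x$max_score), "\n")
  cat("  monotonicity violations:", x$monotonicity_violations, "\n")
  invisible(x)
}

#' @describeIn enumerate_scores one-row summary of the enumeration.
#' @param x,object A `bn_enumeration`.
#' @param ... Unused.
#' @export
glance.bn_enumeration <- function(x, ...) {
  tibble::tibble(
    n_outcomes = x$n_outcomes,
    min_score = x$min_score,
    max_score = x$max_score,
    monotonicity_violations = x$monotonicity_violations
  )
}

#' @describeIn enumerate_scores the score histogram as a tibble.
#' @export
tidy.bn_enumeration <- function(x, ...) {
  x$histogram
}

#' @describeIn enumerate_scores bar chart of the score distribution.
#' @export
autoplot.bn_enumeration <- function(object, ...) {
  h <- object$histogram |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$score, y = .data$n)) +
    ggplot2::geom_col(width = 0.08, fill = "#264653") +
    ggplot2::labs(
      x = "final score (1.0–10.0 index)",
      y = "response combinations",
      title = "Attainable score distribution over the full response space"
    ) +
    ggplot2::theme_minimal()
}
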