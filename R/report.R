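#' Build the report for one scored respondent
#'
#' Assembles the score, the eight domain subscores, the three
#' recommendations and — following user feedback asking which exposures
#' contribute most to the result — a per-domain contribution table (each
#' domain contributes subscore/8 points of the final index). This
#' contribution summary is an extension beyond the launched tool.
#'
#' @param scored A `bn_scores` tibble from [score_responses()].
#' @param row Which respondent (row) to report on.
#' @return A list mirroring the report JSON: `score`, `subscores`,
#'   `recommendations`, `contributions`, `instrument_version`.
#' @export
bn_report <- function(scored, row = 1L) {
  stopifnot(inherits(scored, "bn_scores"), row >= 1L, row <= nrow(scored))
  x <- tibble::as_tibble(scored)[row, ]
  recs <- x$recommendations[[1]]
  contrib <- tidy(scored)[tidy(scored)$respondent == row, ]
  list(
    score = x$score,
    subscores = as.list(x[bn_domain_order]),
    recommendations = purrr::pmap(
      recs[c("rank", "domain_key", "subscore", "text", "link")], list
    ),
    contributions = purrr::pmap(
      data.frame(
        domain_key = as.character(contrib$domain_key),
        subscore = contrib$subscore,
        points = contrib$points,
        share = round(contrib$share, 4)
      ),
      list
    ),
    instrument_version = x$instrument_version
  )
}

#' Render a report as JSON or text
#'
#' @inheritParams bn_report
#' @param format `"json"` or `"text"`.
#' @return A character vector of report lines (length 1 for JSON).
#' @export
format_report <- function(scored, row = 1L, format = c("json", "text")) {
  format <- match.arg(format)
  rep <- bn_report(scored, row)
  if (format == "json") {
    return(as.character(
      jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ))
  }
  lines <- c(
    sprintf("Your BetterNest Score: %.1f / 10", rep$score),
    "(higher scores mean lower environmental risk and more protective habits)",
    "",
    "Where your score comes from:"
  )
  for (co in rep$contributions) {
    lines <- c(lines, sprintf("  %-14s subscore %2d  (%.3f of %.1f points)",
      co$domain_key, co$subscore, co$points, rep$score))
  }
  lines <- c(lines, "", "Your top three recommendations:")
  for (r in rep$recommendations) {
    lines <- c(lines, sprintf("  %d. [%s] %s", r$rank, r$domain_key, r$text))
  }
  lines
}

#' Write a report to a file or standard output
#'
#' @inheritParams format_report
#' @param path Output file, or `NULL` for standard output.
#' @return The report lines, invisibly.
#' @export
write_report <- function(scored, path = NULL, row = 1L,
                         format = c("json", "text")) {
  lines <- format_report(scored, row = row, format = format)
  if (is.null(path)) cat(lines, sep = "\n") else writeLines(lines, path)
  invisible(lines)
}
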