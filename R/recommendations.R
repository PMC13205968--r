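#' @rdname render_recommendation
#' @format NULL
#' @export
bn_default_factsheet_url <- "https://example.org/factsheets"

# Fear-framing lexicon recommendations must avoid: feedback is framed in a
# motivational-interviewing register (autonomy-supportive, non-judgmental).
bn_tone_blocklist <- c(
  "danger", "dangerous", "toxic to your baby", "poison", "deadly",
  "warning", "beware", "alarming", "you must", "you are harming"
)

#' Check recommendation text against the tone blocklist
#'
#' @param text Character vector of recommendation texts.
#' @return Logical vector: `TRUE` where the text is non-empty and free of
#'   fear-framing phrases.
#' @export
check_recommendation_tone <- function(text) {
  nzchar(text) &
    !purrr::map_lgl(tolower(text), function(t) {
      any(stringr::str_detect(t, stringr::fixed(bn_tone_blocklist)))
    })
}

#' Load the recommendation templates
#'
#' One template per scored domain, each with a `{factsheet_url}` link slot
#' and ending with a factsheet pointer. Three templates (lead, plastics,
#' personal_care) are the tool's published texts (`canonical = TRUE`); the
#' other five are authored stand-ins in the same register.
#'
#' @param path Path to a templates JSON file; defaults to the packaged one.
#' @return A tibble with columns `domain_key`, `canonical`, `template`.
#' @export
bn_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "recommendation_templates.json",
      package = "betternest")
  }
  raw <- jsonlite::read_json(path)
  out <- purrr::imap_dfr(raw, function(x, key) {
    tibble::tibble(domain_key = key, canonical = isTRUE(x$canonical),
      template = x$template)
  })
  if (!setequal(out$domain_key, bn_domain_order)) {
    abort("templates must cover exactly the eight scored domains",
      class = "bn_bad_instrument")
  }
  stopifnot(all(check_recommendation_tone(out$template)))
  out[match(bn_domain_order, out$domain_key), ]
}

#' Render the recommendation for one domain
#'
#' @param domain_key One of the eight scored domain keys (see
#'   [bn_domains()]).
#' @param subscore The domain's integer subscore, carried into the result.
#' @param factsheet_base_url Base URL for factsheet links; the rendered link
#'   is `<base>/<domain_key>`.
#' @param templates Template table from [bn_templates()].
#' @return A one-row tibble: `domain_key`, `subscore`, `text`, `link`,
#'   `canonical`.
#' @export
#' @examples
#' render_recommendation("lead", 1)
render_recommendation <- function(domain_key, subscore,
                                  factsheet_base_url = bn_default_factsheet_url,
                                  templates = bn_templates()) {
  row <- templates[templates$domain_key == domain_key, ]
  if (nrow(row) != 1L) {
    abort(paste0("unknown domain_key: ", domain_key), class = "bn_unknown_option")
  }
  link <- paste0(factsheet_base_url, "/", domain_key)
  tibble::tibble(
    domain_key = domain_key,
    subscore = as.integer(subscore),
    text = stringr::str_replace(row$template, stringr::fixed("{factsheet_url}"), link),
    link = link,
    canonical = row$canonical
  )
}

#' Select the three highest-priority recommendations
#'
#' Picks, for each respondent, the three lowest-scoring domains (lower
#' subscores mean more exposure risk) and renders their recommendation
#' texts. Ties are broken by stable instrument order, macro-to-micro, so a
#' tie favors the broader environmental domain. Output is ordered ascending
#' by subscore within respondent.
#'
#' @param data A data frame with the eight domain subscore columns (e.g.
#'   from [compute_subscores()]), one respondent per row.
#' @inheritParams render_recommendation
#' @return A tibble with three rows per respondent: `respondent` (input row
#'   number), `rank`, `domain_key`, `subscore`, `text`, `link`, `canonical`.
#' @export
#' @examples
#' sub <- tibble::tibble(
#'   lead = 1, air = 5, tobacco = 10, cleaning = 9, pesticides = 9,
#'   plastics = 1, produce = 9, personal_care = 3
#' )
#' select_recommendations(sub)[, c("rank", "domain_key", "subscore")]
select_recommendations <- function(data,
                                   factsheet_base_url = bn_default_factsheet_url,
                                   templates = bn_templates()) {
  missing <- setdiff(bn_domain_order, names(data))
  if (length(missing) > 0L) {
    abort(paste0("missing subscore columns: ", paste(missing, collapse = ", ")),
      class = "bn_domain_error")
  }
  long <- tibble::as_tibble(data)[bn_domain_order]
  long$respondent <- seq_len(nrow(long))
  long <- tidyr::pivot_longer(long, -"respondent",
    names_to = "domain_key", values_to = "subscore")
  long$domain_pos <- match(long$domain_key, bn_domain_order)
  picked <- long |>
    dplyr::arrange(.data$respondent, .data$subscore, .data$domain_pos) |>
    dplyr::group_by(.data$respondent) |>
    dplyr::slice_head(n = 3) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  # vectorized render (same substitution as render_recommendation)
  tmpl_idx <- match(picked$domain_key, templates$domain_key)
  link <- paste0(factsheet_base_url, "/", picked$domain_key)
  tibble::tibble(
    respondent = picked$respondent,
    rank = picked$rank,
    domain_key = picked$domain_key,
    subscore = as.integer(picked$subscore),
    text = stringr::str_replace(templates$template[tmpl_idx],
      stringr::fixed("{factsheet_url}"), link),
    link = link,
    canonical = templates$canonical[tmpl_idx]
  )
}
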