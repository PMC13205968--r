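#' Load the nine-question screening instrument
#'
#' Reads the packaged instrument definition (questions, life-stage wording
#' variants, ordered response options and their raw scores, the county
#' banding cut-points, and the product-volume x ingredient-check modifier
#' matrix) and validates it against the instrument's structural invariants:
#' exactly nine questions with unique ids; Q1 unscored; Q2 scored from county
#' data; Q8 carrying modifier values 9/5/1; every other option carrying an
#' integer raw score in 1..10, non-increasing down the printed option order.
#'
#' @param path Path to an instrument JSON file. Defaults to the definition
#'   shipped with the package.
#' @return An object of class `bn_instrument`: a list with elements
#'   `version`, `life_stages`, `questions` (tibble: `qid`, `domain_key`,
#'   `n_options`), `prompts` (tibble: `qid`, `life_stage`, `prompt`),
#'   `options` (tibble: `qid`, `position`, `option_id`, `text`,
#'   `score_kind`, `raw_score`), `modifier_matrix` (tibble: `q9_option`,
#'   `q8_modifier`, `subscore`), `lead_thresholds`, `lead_scores`,
#'   `air_thresholds`, `air_scores`.
#' @export
#' @examples
#' instr <- bn_instrument()
#' instr$questions
bn_instrument <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "instrument.json", package = "betternest")
  }
  raw <- jsonlite::read_json(path)

  questions <- purrr::map_dfr(raw$questions, function(q) {
    tibble::tibble(
      qid = q$qid, domain_key = q$domain_key, n_options = length(q$options)
    )
  })

  prompts <- purrr::map_dfr(raw$questions, function(q) {
    p <- q$prompts
    if (!is.null(p$default)) {
      tibble::tibble(
        qid = q$qid, life_stage = unlist(raw$life_stages),
        prompt = p$default
      )
    } else {
      tibble::tibble(
        qid = q$qid, life_stage = names(p), prompt = unlist(p, use.names = FALSE)
      )
    }
  })

  options <- purrr::map_dfr(raw$questions, function(q) {
    if (length(q$options) == 0L) {
      return(tibble::tibble(
        qid = character(), position = integer(), option_id = character(),
        text = character(), score_kind = character(), raw_score = integer()
      ))
    }
    purrr::imap_dfr(q$options, function(o, i) {
      tibble::tibble(
        qid = q$qid, position = as.integer(i), option_id = o$option_id,
        text = o$text, score_kind = o$score_kind,
        raw_score = if (is.null(o$raw_score)) NA_integer_ else as.integer(o$raw_score)
      )
    })
  })

  modifier_matrix <- purrr::imap_dfr(raw$modifier_matrix, function(row, q9) {
    tibble::tibble(
      q9_option = q9,
      q8_modifier = as.integer(names(row)),
      subscore = as.integer(unlist(row, use.names = FALSE))
    )
  })

  instr <- structure(
    list(
      version = raw$version,
      life_stages = unlist(raw$life_stages),
      questions = questions,
      prompts = prompts,
      options = options,
      modifier_matrix = modifier_matrix,
      lead_thresholds = as.numeric(unlist(raw$lead_bands$thresholds)),
      lead_scores = as.integer(unlist(raw$lead_bands$scores)),
      air_thresholds = as.numeric(unlist(raw$air_bands$thresholds)),
      air_scores = as.integer(unlist(raw$air_bands$scores))
    ),
    class = "bn_instrument"
  )
  validate_instrument(instr)
  instr
}

validate_instrument <- function(instr) {
  q <- instr$questions
  if (nrow(q) != 9L || anyDuplicated(q$qid) || !setequal(q$qid, paste0("Q", 1:9))) {
    abort("instrument must define exactly nine questions Q1..Q9 with unique ids",
      class = "bn_bad_instrument")
  }
  opts <- instr$options
  if (!all(opts$raw_score[opts$qid == "Q1"] %in% NA_integer_)) {
    abort("Q1 options must be unscored", class = "bn_bad_instrument")
  }
  if (q$n_options[q$qid == "Q2"] != 0L) {
    abort("Q2 is scored from county data and carries no options",
      class = "bn_bad_instrument")
  }
  if (!identical(opts$raw_score[opts$qid == "Q8"], c(9L, 5L, 1L))) {
    abort("Q8 must carry modifier values 9, 5, 1", class = "bn_bad_instrument")
  }
  raw_qids <- paste0("Q", c(3:7))
  raw <- opts[opts$qid %in% raw_qids, ]
  if (anyNA(raw$raw_score) || !all(raw$raw_score >= 1L & raw$raw_score <= 10L)) {
    abort("raw option scores must be integers in [1, 10]",
      class = "bn_bad_instrument")
  }
  # printed option order runs from most to least protective
  non_increasing <- vapply(
    split(raw$raw_score[order(raw$position)], raw$qid[order(raw$position)]),
    function(s) all(diff(s) < 0), logical(1)
  )
  if (!all(non_increasing)) {
    abort("option scores must decrease down the printed option order",
      class = "bn_bad_instrument")
  }
  mm <- instr$modifier_matrix
  if (nrow(mm) != 9L || !setequal(mm$q8_modifier, c(9L, 5L, 1L)) ||
      !setequal(unique(mm$q9_option), c("all_the_time", "sometimes", "never"))) {
    abort("modifier matrix must be the full 3x3 Q9-option by Q8-modifier table",
      class = "bn_bad_instrument")
  }
  invisible(instr)
}

#' @export
print.bn_instrument <- function(x, ...) {
  cat("<bn_instrument> version", x$version, "\n")
  cat("  9 questions,", nrow(x$options), "options,",
      nrow(x$modifier_matrix), "modifier-matrix cells\n")
  print(x$questions)
  invisible(x)
}

#' Question wording for a life stage
#'
#' Returns the prompt text for a question under the wording variant selected
#' by the respondent's life stage (only the cleaning and plastics questions
#' have a child-at-home variant; all others have a single wording).
#'
#' @param instrument A `bn_instrument`.
#' @param qid Question id, `"Q1"`..`"Q9"`.
#' @param life_stage One of `"considering_pregnancy"`, `"currently_pregnant"`,
#'   `"child_at_home"`.
#' @return A single string.
#' @export
bn_prompt <- function(instrument, qid, life_stage) {
  stopifnot(inherits(instrument, "bn_instrument"))
  if (!life_stage %in% instrument$life_stages) {
    abort(paste0("unknown life stage: ", life_stage), class = "bn_unknown_option")
  }
  p <- instrument$prompts
  out <- p$prompt[p$qid == qid & p$life_stage == life_stage]
  if (length(out) != 1L) {
    abort(paste0("unknown question id: ", qid), class = "bn_unknown_option")
  }
  out
}

answer_qids <- paste0("Q", 3:9)

#' Validate a set of survey responses
#'
#' Checks a data frame of raw responses (one respondent per row) against the
#' instrument: every answer-bearing question Q3..Q9 must be present with a
#' valid option id, `life_stage` must be one of the three Q1 options,
#' `postal_code` must be a five-digit string, and unknown columns are
#' rejected. Incomplete response sets are rejected rather than imputed; a
#' partial mean would silently change what the index measures.
#'
#' @param data A data frame with columns `life_stage`, `postal_code` and
#'   `Q3`..`Q9` (character option ids).
#' @param instrument A `bn_instrument`; defaults to the packaged one.
#' @return `data` as a validated tibble with an added `wording_variant`
#'   column recording which Q4/Q6 wording the respondent saw.
#' @export
#' @examples
#' resp <- bn_example_responses()
#' validate_responses(resp)
validate_responses <- function(data, instrument = bn_instrument()) {
  data <- tibble::as_tibble(data)
  data$wording_variant <- NULL
  expected <- c("life_stage", "postal_code", answer_qids)
  unknown <- setdiff(names(data), expected)
  if (length(unknown) > 0L) {
    abort(paste0("unknown response fields: ", paste(unknown, collapse = ", ")),
      class = "bn_unknown_option")
  }
  missing_cols <- setdiff(expected, names(data))
  missing_q <- intersect(missing_cols, answer_qids)
  if (length(missing_q) > 0L) {
    abort(paste0("missing answer for ", missing_q[1]),
      class = "bn_missing_answer", qid = missing_q[1])
  }
  if (length(missing_cols) > 0L) {
    abort(paste0("missing response fields: ", paste(missing_cols, collapse = ", ")),
      class = "bn_missing_answer")
  }
  if (nrow(data) == 0L) {
    abort("no responses to validate", class = "bn_missing_answer")
  }

  bad_stage <- !data$life_stage %in% instrument$life_stages
  if (any(bad_stage)) {
    abort(paste0("unknown option for Q1: ", data$life_stage[bad_stage][1]),
      class = "bn_unknown_option", qid = "Q1")
  }
  bad_zip <- !grepl("^[0-9]{5}$", data$postal_code)
  if (any(bad_zip)) {
    abort(paste0("postal code must be five digits, got: ",
                 data$postal_code[bad_zip][1]),
      class = "bn_bad_postal_code")
  }
  for (qid in answer_qids) {
    ans <- data[[qid]]
    if (anyNA(ans)) {
      abort(paste0("missing answer for ", qid),
        class = "bn_missing_answer", qid = qid)
    }
    valid <- instrument$options$option_id[instrument$options$qid == qid]
    bad <- !ans %in% valid
    if (any(bad)) {
      abort(paste0("unknown option for ", qid, ": ", ans[bad][1]),
        class = "bn_unknown_option", qid = qid)
    }
  }
  data$wording_variant <- ifelse(
    data$life_stage == "child_at_home", "child_at_home", "pregnancy"
  )
  data[, c(expected, "wording_variant")]
}

#' Read a responses JSON file
#'
#' Parses the flat responses format `{"life_stage": ..., "postal_code": ...,
#' "Q3": option_id, ..., "Q9": option_id}` (a single object or an array of
#' such objects) and validates it with [validate_responses()].
#'
#' @param path Path to a JSON file.
#' @inheritParams validate_responses
#' @return A validated responses tibble.
#' @export
read_responses <- function(path, instrument = bn_instrument()) {
  parsed <- jsonlite::read_json(path)
  if (!is.null(names(parsed))) parsed <- list(parsed)
  rows <- purrr::map_dfr(parsed, function(rec) {
    tibble::as_tibble(purrr::map(rec, as.character))
  })
  validate_responses(rows, instrument)
}

#' Write responses to a JSON file
#'
#' @param data A responses data frame (see [validate_responses()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path) {
  keep <- intersect(c("life_stage", "postal_code", answer_qids), names(data))
  recs <- purrr::pmap(data[keep], function(...) list(...))
  if (length(recs) == 1L) recs <- recs[[1]]
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Example response set
#'
#' A single complete, valid response row used in documentation examples.
#'
#' @return A one-row responses tibble.
#' @export
bn_example_responses <- function() {
  tibble::tibble(
    life_stage = "currently_pregnant",
    postal_code = "00001",
    Q3 = "few_times_week",
    Q4 = "weekly",
    Q5 = "sometimes_unsure",
    Q6 = "few_week",
    Q7 = "sometimes",
    Q8 = "ten_to_18",
    Q9 = "sometimes"
  )
}
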