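test_that("instrument has nine questions and the expected structure", {
  instr <- bn_instrument()
  expect_s3_class(instr, "bn_instrument")
  expect_equal(nrow(instr$questions), 9L)
  expect_setequal(instr$questions$qid, paste0("Q", 1:9))
  expect_equal(instr$questions$n_options[instr$questions$qid == "Q2"], 0L)
  # seven answer-bearing questions, eight scored domains
  expect_equal(sum(instr$questions$n_options > 0), 8L) # Q1 + Q3..Q9
  expect_equal(nrow(bn_domains()), 8L)
})

test_that("option texts and scores match the golden transcription byte-for-byte", {
  golden <- readr::read_csv(test_path("table1-golden.csv"),
    col_types = "cicc", na = character())
  golden$score <- suppressWarnings(as.integer(golden$score))
  instr <- bn_instrument()
  opts <- instr$options[order(instr$options$qid, instr$options$position), ]
  opts <- opts[opts$qid %in% unique(golden$qid), ]
  golden <- golden[order(golden$qid, golden$position), ]
  expect_identical(opts$qid, golden$qid)
  expect_identical(opts$position, golden$position)
  expect_identical(opts$text, golden$text)
  expect_identical(opts$raw_score, golden$score)
})

test_that("lead/air band definitions and the modifier matrix match the printed table", {
  instr <- bn_instrument()
  expect_identical(instr$lead_thresholds, c(41.05, 50.3, 58.8, 69.3))
  expect_identical(instr$lead_scores, c(9L, 7L, 5L, 3L, 1L))
  expect_identical(instr$air_thresholds, c(12, 15))
  expect_identical(instr$air_scores, c(9L, 5L, 1L))
  mm <- instr$modifier_matrix
  cell <- function(q9, q8) mm$subscore[mm$q9_option == q9 & mm$q8_modifier == q8]
  expect_identical(
    c(cell("all_the_time", 9), cell("all_the_time", 5), cell("all_the_time", 1),
      cell("sometimes", 9), cell("sometimes", 5), cell("sometimes", 1),
      cell("never", 9), cell("never", 5), cell("never", 1)),
    c(10L, 7L, 5L, 8L, 6L, 3L, 7L, 3L, 1L)
  )
})

test_that("option scores are non-increasing down each question's printed order", {
  instr <- bn_instrument()
  raw <- instr$options[instr$options$score_kind %in% c("raw", "modifier"), ]
  for (qid in unique(raw$qid)) {
    s <- raw$raw_score[raw$qid == qid][order(raw$position[raw$qid == qid])]
    expect_true(all(diff(s) < 0), label = paste("scores decrease for", qid))
  }
  # Q9 columns of the modifier matrix also decrease down the printed order
  mm <- instr$modifier_matrix
  for (m in c(9L, 5L, 1L)) {
    col <- sapply(c("all_the_time", "sometimes", "never"),
      function(o) mm$subscore[mm$q9_option == o & mm$q8_modifier == m])
    expect_true(all(diff(col) < 0))
  }
})

test_that("prompt wording varies by life stage only for Q4 and Q6", {
  instr <- bn_instrument()
  stages <- instr$life_stages
  for (qid in paste0("Q", 1:9)) {
    texts <- unique(vapply(stages, function(s) bn_prompt(instr, qid, s), ""))
    if (qid %in% c("Q4", "Q6")) {
      expect_length(texts, 2L)
      # pregnant-track users (considering or currently) share one wording
      expect_identical(
        bn_prompt(instr, qid, "considering_pregnancy"),
        bn_prompt(instr, qid, "currently_pregnant")
      )
    } else {
      expect_length(texts, 1L)
    }
  }
  expect_match(bn_prompt(instr, "Q6", "child_at_home"), "your child")
})

test_that("a tampered instrument definition fails validation", {
  path <- withr::local_tempfile(fileext = ".json")
  raw <- jsonlite::read_json(
    system.file("extdata", "instrument.json", package = "betternest"))
  bad <- raw
  bad$questions[[3]]$options[[1]]$raw_score <- 99
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(bn_instrument(path), class = "bn_bad_instrument")
  bad <- raw
  bad$questions[[9]] <- NULL
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(bn_instrument(path), class = "bn_bad_instrument")
})

test_that("validate_responses accepts complete records and rejects bad ones", {
  resp <- make_responses()
  ok <- validate_responses(resp)
  expect_s3_class(ok, "tbl_df")
  expect_equal(ok$wording_variant, "pregnancy")
  expect_equal(
    validate_responses(make_responses(life_stage = "child_at_home"))$wording_variant,
    "child_at_home"
  )
  # idempotent
  expect_identical(validate_responses(ok), ok)

  expect_error(validate_responses(resp[setdiff(names(resp), "Q5")]),
    class = "bn_missing_answer", regexp = "Q5")
  na5 <- resp; na5$Q5 <- NA_character_
  expect_error(validate_responses(na5), class = "bn_missing_answer", regexp = "Q5")
  expect_error(validate_responses(make_responses(postal_code = "ABC12")),
    class = "bn_bad_postal_code")
  expect_error(validate_responses(make_responses(postal_code = "1234")),
    class = "bn_bad_postal_code")
  expect_error(validate_responses(make_responses(Q7 = "nope")),
    class = "bn_unknown_option", regexp = "Q7")
  expect_error(validate_responses(make_responses(life_stage = "toddler")),
    class = "bn_unknown_option")
  extra <- resp; extra$Q10 <- "x"
  expect_error(validate_responses(extra), class = "bn_unknown_option",
    regexp = "Q10")
})

test_that("responses survive a JSON write/read round-trip", {
  path <- withr::local_tempfile(fileext = ".json")
  resp <- validate_responses(make_responses(Q3 = "home_smoker"))
  write_responses(resp, path)
  back <- read_responses(path)
  expect_identical(back, resp)
  # an array of records round-trips too
  two <- validate_responses(dplyr::bind_rows(make_responses(), worst_responses("00002")))
  write_responses(two, path)
  expect_identical(read_responses(path), two)
})
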