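test_that("the personal-care modifier matrix reproduces all nine printed cells", {
  cases <- tibble::tribble(
    ~q8, ~q9,            ~expected,
    9L,  "all_the_time", 10L,
    5L,  "all_the_time", 7L,
    1L,  "all_the_time", 5L,
    9L,  "sometimes",    8L,
    5L,  "sometimes",    6L,
    1L,  "sometimes",    3L,
    9L,  "never",        7L,
    5L,  "never",        3L,
    1L,  "never",        1L
  )
  expect_identical(personal_care_subscore(cases$q8, cases$q9), cases$expected)
  expect_error(personal_care_subscore(4, "sometimes"), class = "bn_unknown_option")
  expect_error(personal_care_subscore(9, "rarely"), class = "bn_unknown_option")
})

test_that("compute_subscores assembles the eight domains from answers and county data", {
  geo <- make_test_geo()
  instr <- bn_instrument()

  best <- compute_subscores(best_responses("00001"), geo, instr)
  expect_identical(
    unname(unlist(best[c("lead", "air", "tobacco", "cleaning", "pesticides",
                         "plastics", "produce", "personal_care")])),
    c(9L, 9L, 10L, 9L, 9L, 10L, 9L, 10L)
  )

  worst <- compute_subscores(worst_responses("00003"), geo, instr)
  expect_identical(
    unname(unlist(worst[c("lead", "air", "tobacco", "cleaning", "pesticides",
                          "plastics", "produce", "personal_care")])),
    c(1L, 1L, 1L, 2L, 1L, 1L, 2L, 1L)
  )

  # mixed case hand-assembled from the printed table rows
  mixed <- compute_subscores(
    make_responses(postal_code = "00002", Q3 = "few_times_week", Q4 = "weekly",
      Q5 = "sometimes_unsure", Q6 = "few_week", Q7 = "sometimes",
      Q8 = "ten_to_18", Q9 = "sometimes"),
    geo, instr
  )
  expect_identical(
    unname(unlist(mixed[c("lead", "air", "tobacco", "cleaning", "pesticides",
                          "plastics", "produce", "personal_care")])),
    c(5L, 5L, 6L, 6L, 5L, 3L, 5L, 6L)
  )
  # Q8 is a modifier, not a ninth domain
  expect_length(intersect(names(mixed), bn_domains()$domain_key), 8L)
})

test_that("aggregation takes the exact eight-domain mean and rounds half-up", {
  vec <- function(x) {
    stats::setNames(as.data.frame(as.list(x)), bn_domains()$domain_key)
  }
  # printed extremes: 10/8 = 1.25 -> 1.3 (half-up), 75/8 = 9.375 -> 9.4
  expect_identical(aggregate_score(vec(c(1, 1, 1, 2, 1, 1, 2, 1)))$score, 1.3)
  expect_identical(aggregate_score(vec(c(9, 9, 10, 9, 9, 10, 9, 10)))$score, 9.4)
  # 41/8 = 5.125 -> 5.1 (the half-digit is beyond the tenths place)
  expect_identical(aggregate_score(vec(c(5, 5, 6, 6, 5, 3, 5, 6)))$score, 5.1)

  expect_error(aggregate_score(vec(c(0, 1, 1, 2, 1, 1, 2, 1))),
    class = "bn_domain_error")
  expect_error(aggregate_score(vec(c(1.5, 1, 1, 2, 1, 1, 2, 1))),
    class = "bn_domain_error")
  expect_error(aggregate_score(data.frame(lead = 5)), class = "bn_domain_error")
})

test_that("aggregation agrees with an exact-arithmetic oracle for every attainable sum", {
  # every integer sum 8..80 is attainable with eight subscores in [1, 10]
  for (s in 8:80) {
    base <- rep(s %/% 8L, 8L)
    base[seq_len(s %% 8L)] <- base[seq_len(s %% 8L)] + 1L
    stopifnot(sum(base) == s, all(base >= 1 & base <= 10))
    df <- stats::setNames(as.data.frame(as.list(base)), bn_domains()$domain_key)
    expect_identical(aggregate_score(df)$score, oracle_mean8_half_up(s),
      label = paste("sum", s))
  }
})

test_that("score_responses composes the full pipeline deterministically", {
  geo <- make_test_geo()
  best <- score_responses(best_responses("00001"), geo)
  worst <- score_responses(worst_responses("00003"), geo)
  expect_identical(best$score, 9.4)
  expect_identical(worst$score, 1.3)
  expect_s3_class(best, "bn_scores")
  expect_equal(nrow(best$recommendations[[1]]), 3L)
  # bit-identical on identical inputs
  expect_identical(score_responses(best_responses("00001"), geo), best)
  # several respondents scored at once
  both <- score_responses(
    dplyr::bind_rows(best_responses("00001"), worst_responses("00003")), geo)
  expect_identical(both$score, c(9.4, 1.3))
})

test_that("improving any single answer never lowers the score", {
  geo <- make_test_geo()
  instr <- bn_instrument()
  base <- make_responses(postal_code = "00002", Q3 = "home_smoker",
    Q4 = "weekly", Q5 = "sometimes_unsure", Q6 = "few_week", Q7 = "sometimes",
    Q8 = "ten_to_18", Q9 = "sometimes")
  base_score <- score_responses(base, geo, instr)$score
  for (qid in paste0("Q", 3:9)) {
    opts <- instr$options[instr$options$qid == qid, ]
    cur_pos <- opts$position[opts$option_id == base[[qid]][1]]
    for (better in opts$option_id[opts$position < cur_pos]) {
      improved <- base
      improved[[qid]] <- better
      expect_gte(score_responses(improved, geo, instr)$score, base_score)
    }
  }
})

test_that("tidy() exposes per-domain contributions that sum to the exact mean", {
  geo <- make_test_geo()
  scored <- score_responses(best_responses("00001"), geo)
  long <- tidy(scored)
  expect_equal(nrow(long), 8L)
  expect_equal(sum(long$points), 75 / 8)
  expect_equal(sum(long$share), 1)
  expect_s3_class(autoplot(scored), "ggplot")
})
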