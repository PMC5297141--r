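intervals_lpwp <- function() data.frame(
  label = c("learning", "proficiency", "worsening", "proficiency"),
  start_case = c(1L, 11L, 21L, 31L),
  end_case = c(10L, 20L, 30L, 40L)
)

frame_records <- function(n_cases = 40) {
  data.frame(
    operator_id = "A",
    case_id = sprintf("A-%02d", seq_len(n_cases)),
    node_order = 1L,
    date_order = seq_len(n_cases),
    outcome = rep(c("S", "F"), length.out = n_cases),
    attending_assist = rep(c(0L, 1L), length.out = n_cases),
    cytopathologist = rep(c(1L, 0L), length.out = n_cases),
    midazolam_mg = rep(c(6, 10, 12, 8), length.out = n_cases),
    fentanyl_ug = rep(c(100, 300, 250, 400), length.out = n_cases)
  )
}

test_that("dose dichotomization is inclusive and interval labels attach", {
  fr <- build_analysis_frame(frame_records(), intervals_lpwp())
  expect_identical(fr$high_midazolam,
                   as.integer(frame_records()$midazolam_mg >= 10))
  expect_identical(fr$high_fentanyl,
                   as.integer(frame_records()$fentanyl_ug >= 300))
  # a midazolam dose exactly at the threshold counts as high
  expect_identical(fr$high_midazolam[fr$unit_id == "A-02"], 1L)
  # rows in the worsening interval carry the outcome, others do not
  expect_identical(fr$outcome_nonproficient,
                   as.integer(fr$case_index >= 21 & fr$case_index <= 30))
  expect_identical(fr$outcome_nonproficient[fr$interval == "proficiency"],
                   rep(0L, 20))
  # custom thresholds are honoured
  fr2 <- build_analysis_frame(frame_records(), intervals_lpwp(),
                              fentanyl_threshold = 200)
  expect_identical(fr2$high_fentanyl,
                   as.integer(frame_records()$fentanyl_ug >= 200))
})

test_that("rows with missing covariates are dropped with a logged count", {
  rec <- frame_records()
  rec$fentanyl_ug[c(3, 7, 9)] <- NA
  expect_message(
    fr <- build_analysis_frame(rec, intervals_lpwp()),
    "dropped 3 row\\(s\\)")
  expect_identical(nrow(fr), 37L)
  expect_identical(attr(fr, "n_dropped"), 3L)
})

test_that("records outside the supplied intervals are rejected", {
  iv <- intervals_lpwp()[1:3, ]  # cases 31..40 uncovered
  expect_error(build_analysis_frame(frame_records(), iv),
               "not covered by the supplied intervals")
})

test_that("case-level analysis collapses nodes and ORs any failure", {
  rec <- frame_records(10)
  rec2 <- rec
  rec2$node_order <- 2L
  rec2$outcome <- "F"
  both <- rbind(rec, rec2)
  iv <- data.frame(label = c("learning", "worsening"),
                   start_case = c(1L, 6L), end_case = c(5L, 10L))
  fr <- build_analysis_frame(both, iv, unit = "case")
  expect_identical(nrow(fr), 10L)
  expect_identical(fr$outcome_failure, rep(1L, 10))
})

test_that("univariable fits reproduce the cross-product odds ratio", {
  # exposed: 10 events / 50; unexposed: 30 events / 50 -> OR = (10*20)/(40*30)
  fr <- data.frame(
    outcome_nonproficient = c(rep(1, 10), rep(0, 40), rep(1, 30), rep(0, 20)),
    attending_assist = c(rep(1, 50), rep(0, 50))
  )
  fit <- fit_environment(fr, covariates = "attending_assist")
  expect_equal(fit$table$odds_ratio, (10 * 20) / (40 * 30), tolerance = 1e-6)
  expect_equal(fit$table$odds_ratio, 0.1666667, tolerance = 1e-6)
  expect_true(fit$table$ci_low < fit$table$odds_ratio &&
                fit$table$odds_ratio < fit$table$ci_high)

  # random nondegenerate 2x2 tables against the closed form
  set.seed(8)
  for (rep in 1:10) {
    a <- sample(2:28, 1); b <- sample(2:28, 1)
    c_ <- sample(2:28, 1); d <- sample(2:28, 1)
    fr2 <- data.frame(
      outcome_nonproficient = c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d)),
      attending_assist = c(rep(1, a + b), rep(0, c_ + d))
    )
    fit2 <- fit_environment(fr2, covariates = "attending_assist")
    expect_equal(fit2$table$odds_ratio, (a * d) / (b * c_), tolerance = 1e-6)
  }
})

test_that("identical event rates give OR 1 and p near 1", {
  fr <- data.frame(
    outcome_nonproficient = rep(c(rep(1, 15), rep(0, 35)), 2),
    attending_assist = c(rep(1, 50), rep(0, 50))
  )
  fit <- fit_environment(fr, covariates = "attending_assist")
  expect_equal(fit$table$odds_ratio, 1, tolerance = 1e-6)
  expect_gt(fit$table$p_value, 0.99)
})

test_that("separation is flagged under ML and Firth returns finite estimates", {
  fr <- data.frame(
    outcome_nonproficient = c(rep(1, 10), rep(0, 10)),
    attending_assist = c(rep(1, 10), rep(0, 10))
  )
  ml <- fit_environment(fr, covariates = "attending_assist")
  expect_identical(ml$table$separation_flag, 1L)
  fi <- fit_environment(fr, method = "firth", covariates = "attending_assist")
  expect_true(is.finite(fi$table$estimate))
  expect_true(is.finite(fi$table$ci_low) && fi$table$ci_low > 0)
  expect_identical(fi$table$separation_flag, 1L)
  expect_gt(fi$table$odds_ratio, 1)
})

test_that("Firth matches ML closely on well-behaved data", {
  set.seed(21)
  n <- 4000
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x1 - 0.5 * x2))
  fr <- data.frame(outcome_nonproficient = y, attending_assist = x1,
                   cytopathologist = x2)
  ml <- fit_environment(fr, covariates = c("attending_assist", "cytopathologist"))
  fi <- fit_environment(fr, method = "firth",
                        covariates = c("attending_assist", "cytopathologist"))
  expect_equal(fi$table$estimate, ml$table$estimate, tolerance = 0.02)
  expect_equal(fi$table$se, ml$table$se, tolerance = 0.02)
})

test_that("relabelling the outcome flips every coefficient sign", {
  set.seed(13)
  n <- 500
  fr <- data.frame(
    outcome_nonproficient = rbinom(n, 1, 0.35),
    attending_assist = rbinom(n, 1, 0.5),
    cytopathologist = rbinom(n, 1, 0.4),
    high_midazolam = rbinom(n, 1, 0.3),
    high_fentanyl = rbinom(n, 1, 0.2)
  )
  flipped <- fr
  flipped$outcome_nonproficient <- 1L - fr$outcome_nonproficient
  for (m in c("wald_ml", "firth")) {
    f1 <- fit_environment(fr, method = m)
    f2 <- fit_environment(flipped, method = m)
    expect_equal(f2$table$estimate, -f1$table$estimate, tolerance = 1e-6)
    expect_equal(f2$table$p_value, f1$table$p_value, tolerance = 1e-6)
  }
})

test_that("degenerate and collinear frames raise informative errors", {
  fr <- data.frame(outcome_nonproficient = rep(0, 20),
                   attending_assist = rbinom(20, 1, 0.5))
  expect_error(fit_environment(fr), "degenerate outcome")

  set.seed(2)
  fr2 <- data.frame(
    outcome_nonproficient = rbinom(40, 1, 0.4),
    attending_assist = rep(c(0, 1), 20)
  )
  fr2$cytopathologist <- fr2$attending_assist
  expect_error(
    fit_environment(fr2,
                    covariates = c("attending_assist", "cytopathologist")),
    "collinear covariates: 'attending_assist' and 'cytopathologist'")
  expect_error(fit_environment(fr2[, 1, drop = FALSE]),
               "no model covariates")

  fr3 <- data.frame(outcome_nonproficient = rbinom(30, 1, 0.5),
                    attending_assist = rep(1L, 30))
  expect_error(fit_environment(fr3), "degenerate covariate: 'attending_assist'")
})
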