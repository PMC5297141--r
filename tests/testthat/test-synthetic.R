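test_that("the replica scenario reproduces the study's cohort structure", {
  rec <- generate_cohort(replica_scenario())
  expect_identical(nrow(rec), 222L)
  counts <- table(rec$operator_id)
  expect_identical(as.vector(counts[c("A", "B", "C")]), c(84L, 89L, 49L))
  cases <- tapply(rec$case_id, rec$operator_id,
                  function(x) length(unique(x)))
  expect_identical(as.vector(cases[c("A", "B", "C")]), c(47L, 50L, 34L))
  expect_identical(length(unique(rec$case_id)), 131L)
  # schema and invariants
  expect_identical(names(rec),
                   c("operator_id", "case_id", "node_order", "date_order",
                     "outcome", "attending_assist", "cytopathologist",
                     "midazolam_mg", "fentanyl_ug"))
  expect_identical(anyDuplicated(rec[, c("case_id", "node_order")]), 0L)
  expect_identical(rec$date_order, seq_len(222L))
  expect_true(all(rec$outcome %in% c("S", "F")))
  expect_true(all(rec$midazolam_mg >= 0 & rec$fentanyl_ug >= 0))
  # validates cleanly (case-level covariates constant within case)
  expect_silent(validate_records(rec))
})

test_that("cohort generation is deterministic and operator streams are isolated", {
  sc <- replica_scenario()
  expect_identical(generate_cohort(sc, seed = 77), generate_cohort(sc, seed = 77))
  expect_false(identical(generate_cohort(sc, seed = 77),
                         generate_cohort(sc, seed = 78)))

  # dropping operator C must not perturb A's and B's draws
  sc_ab <- simulation_scenario(operators = sc$operators[1:2], seed = sc$seed)
  full <- generate_cohort(sc, seed = 50)
  ab <- generate_cohort(sc_ab, seed = 50)
  for (id in c("A", "B")) {
    cols <- c("case_id", "node_order", "outcome", "midazolam_mg")
    a1 <- full[full$operator_id == id, cols]
    a2 <- ab[ab$operator_id == id, cols]
    rownames(a1) <- rownames(a2) <- NULL
    expect_identical(a1, a2)
  }
})

test_that("empirical failure fraction matches the configured rate", {
  # zero covariate effects so the phase baseline is the marginal rate
  covs <- list(
    attending_assist = list(prevalence = 0.5, effect = 0),
    cytopathologist = list(prevalence = 0.5, effect = 0),
    midazolam = list(shape = 8, scale = 1, unit = 0.5, threshold = 10,
                     effect = 0),
    fentanyl = list(shape = 7, scale = 20, unit = 25, threshold = 300,
                    effect = 0)
  )
  sc <- simulation_scenario(operators = list(
    list(id = "X", phases = data.frame(n_attempts = 10000, p_fail = 0.2))
  ), covariates = covs)
  rec <- generate_cohort(sc, seed = 4)
  n_fail <- sum(rec$outcome == "F")
  # exact binomial 99% interval around 0.2, computed independently
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.2)
  expect_gte(n_fail, bounds[1])
  expect_lte(n_fail, bounds[2])
})

test_that("covariate effects shift failure odds through the logistic link", {
  covs <- list(
    attending_assist = list(prevalence = 0.5, effect = -1.5),
    cytopathologist = list(prevalence = 0.5, effect = 0),
    midazolam = list(shape = 8, scale = 1, unit = 0.5, threshold = 10,
                     effect = 0),
    fentanyl = list(shape = 7, scale = 20, unit = 25, threshold = 300,
                    effect = 0)
  )
  sc <- simulation_scenario(
    operators = list(list(id = "X",
                          phases = data.frame(n_attempts = 20000,
                                              p_fail = 0.3))),
    covariates = covs)
  rec <- generate_cohort(sc, seed = 6)
  p_with <- mean(rec$outcome[rec$attending_assist == 1] == "F")
  p_without <- mean(rec$outcome[rec$attending_assist == 0] == "F")
  # log-odds difference should recover the configured -1.5
  lor <- qlogis(p_with) - qlogis(p_without)
  expect_equal(lor, -1.5, tolerance = 0.15)
  expect_equal(p_without, 0.3, tolerance = 0.02)
})

test_that("invalid scenarios are rejected", {
  expect_error(simulation_scenario(operators = list(list(id = "X"))),
               "needs an 'id' and a 'phases'")
  expect_error(simulation_scenario(operators = list(
    list(id = "X", phases = data.frame(n_attempts = 0, p_fail = 0.1)))),
    "positive integers")
  expect_error(simulation_scenario(operators = list(
    list(id = "X", phases = data.frame(n_attempts = 10, p_fail = 1.2)))),
    "\\[0, 1\\]")
  expect_error(simulation_scenario(operators = list(
    list(id = "X", phases = data.frame(n_attempts = 10, p_fail = 0.1),
         n_cases = 2))),
    "cannot hold")
})

test_that("degenerate true rates give exact operating characteristics", {
  oc0 <- simulate_operating_characteristics(cusum_params(), p_true = 0,
                                            horizon = 120, n_reps = 50,
                                            seed = 1)
  expect_identical(oc0$p_flag_nonproficient, 0)
  expect_identical(oc0$p_flag_proficient, 1)  # monotone descent must signal
  oc1 <- simulate_operating_characteristics(cusum_params(), p_true = 1,
                                            horizon = 120, n_reps = 50,
                                            seed = 1)
  expect_identical(oc1$p_flag_proficient, 0)
  expect_identical(oc1$p_flag_nonproficient, 1)
})

test_that("generated cohorts recover a known covariate effect", {
  # attending log-odds effect -1.5 on failure; the environment model on the
  # sampling outcome should find a negative estimate with CI excluding 0
  covs <- list(
    attending_assist = list(prevalence = 0.5, effect = -1.5),
    cytopathologist = list(prevalence = 0.5, effect = 0),
    midazolam = list(shape = 8, scale = 1, unit = 0.5, threshold = 10,
                     effect = 0),
    fentanyl = list(shape = 7, scale = 20, unit = 25, threshold = 300,
                    effect = 0)
  )
  sc <- simulation_scenario(
    operators = list(list(id = "X",
                          phases = data.frame(n_attempts = 2000,
                                              p_fail = 0.15))),
    covariates = covs)
  n_reps <- 60
  hits <- 0
  for (r in seq_len(n_reps)) {
    rec <- generate_cohort(sc, seed = 1000 + r)
    fr <- data.frame(
      outcome_failure = as_outcomes(rec$outcome),
      attending_assist = rec$attending_assist,
      cytopathologist = rec$cytopathologist,
      high_midazolam = as.integer(rec$midazolam_mg >= 10),
      high_fentanyl = as.integer(rec$fentanyl_ug >= 300)
    )
    fit <- fit_environment(fr, response = "failure")
    row <- fit$table[fit$table$term == "attending_assist", ]
    if (row$estimate < 0 && row$ci_high < 1) hits <- hits + 1
  }
  expect_gte(hits / n_reps, 0.9)
})
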