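test_that("covariate generation matches marginal prevalences, handles n = 0, and is seed-deterministic", {
  spec <- melanoma_covariates("pooled")

  empty <- generate_covariates(0, spec, seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_setequal(names(empty),
                  c("patient_id", vapply(spec, `[[`, "", "name")))

  big <- generate_covariates(100000, spec, seed = 11)
  expect_lt(abs(mean(big$elevated_ldh) - 0.304), 0.005)
  expect_lt(abs(mean(big$brain_met) - 0.179), 0.005)
  expect_lt(abs(mean(big$anatomic_site == "trunk") - 0.304), 0.01)

  a <- generate_covariates(5000, spec, seed = 7)
  b <- generate_covariates(5000, spec, seed = 7)
  expect_identical(a, b)

  expect_error(covariate_spec("x", "binary", prevalence = 1.2), "\\[0,1\\]")
  expect_error(covariate_spec("x", "categorical", levels = c("a", "b"),
                              probs = c(0.6, 0.6)), "sum to 1")
})

test_that("strategy assignment returns exact multinomial propensities", {
  cov <- generate_covariates(4000, melanoma_covariates(), seed = 3)

  # no coefficients: uniform propensities over K = 4 strategies
  m0 <- assignment_model(c("a", "b", "c", "d"))
  asg0 <- assign_strategy(cov, m0, seed = 5)
  expect_equal(unname(asg0$propensity),
               matrix(0.25, 4000, 4), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(asg0$propensity) - 1)), 1e-12)

  # confounded: SMD of the confounder between groups exceeds 0.1
  m1 <- assignment_model(c("a", "b"),
                         coefficients = list(a = c(brain_met = 1.2),
                                             b = numeric(0)))
  asg1 <- assign_strategy(cov[1:4000, ], m1, seed = 5)
  smd <- standardized_mean_difference(cov$brain_met, asg1$strategy == "a")
  expect_gt(smd, 0.1)
  expect_lt(max(abs(rowSums(asg1$propensity) - 1)), 1e-12)

  # determinism and error handling
  asg2 <- assign_strategy(cov, m0, seed = 5)
  expect_identical(asg0$strategy, asg2$strategy)
  expect_error(assignment_model("only_one"), "at least 2")
  expect_error(assign_strategy(cov, assignment_model(
    c("a", "b"), coefficients = list(a = c(nope = 1), b = numeric(0)))),
    "unknown covariate")
})

test_that("transition simulation reproduces competing-risk closed forms", {
  n <- 10000
  cov <- generate_covariates(n, melanoma_covariates(), seed = 2)
  labels <- rep("S", n)
  no_cens <- function(r12, r13, r23 = 0.1) transition_hazards(
    "S",
    transition_dist("exponential", rate = r12),
    transition_dist("exponential", rate = r13),
    transition_dist("exponential", rate = r23),
    dropout_rate = 0, accrual_months = 1e-6, cut_month = 1e9)

  ev <- simulate_transitions(labels, cov, no_cens(0.05, 0.05),
                             horizon = 12000, seed = 9)
  # competing exponentials: P(exit to L2) = r12 / (r12 + r13) = 0.5
  expect_lt(abs(mean(ev$exit_l1_cause == "to_L2") - 0.5), 0.02)
  # mean L1 sojourn = 1 / total exit rate = 10 months
  expect_lt(abs(mean(ev$t_exit_l1) - 10), 0.3)
  # empirical KM of L1 survival vs the analytic exponential
  km <- weighted_km(ev$t_exit_l1, as.numeric(ev$exit_l1_cause != "censored"))
  for (t0 in c(5, 10, 20)) {
    s_hat <- melcea:::eval_km(km, t0)
    s_true <- exp(-0.1 * t0)
    expect_lt(abs(s_hat - s_true), 3 * sqrt(s_true * (1 - s_true) / n))
  }

  # null process: zero hazards, no drop-out: everyone censored in L1
  ev0 <- simulate_transitions(labels, cov, no_cens(0, 0, 0),
                              horizon = 120, seed = 9)
  expect_true(all(ev0$exit_l1_cause == "censored"))
  expect_true(all(ev0$t_exit_l1 == 120))

  # occupancy partitions follow-up
  soj <- ifelse(is.na(ev$t_l2_sojourn), 0, ev$t_l2_sojourn)
  expect_true(all(ev$t_exit_l1 >= 0 & soj >= 0))
  expect_true(all(is.na(ev$t_l2_sojourn) | ev$exit_l1_cause == "to_L2"))
  expect_true(all(ev$t_exit_l1 + soj <= 12000 + 1e-9))

  expect_error(transition_dist("exponential", rate = -1), ">= 0")
})

test_that("economic simulation follows occupancy and degenerates exactly at zero noise", {
  hist <- data.frame(patient_id = 1:2, strategy = "S",
                     t_exit_l1 = c(10, 4.2),
                     exit_l1_cause = c("censored", "to_death"),
                     t_l2_sojourn = c(NA, NA),
                     l2_status = c(NA, NA), stringsAsFactors = FALSE)
  par0 <- econ_gen_params(data.frame(
    strategy = "S", cost_l1_mean = 7723, cost_l1_sd = 0,
    cost_l2_mean = 11127, cost_l2_sd = 0, pall_mean = 2928, pall_sd = 0,
    utility_l1 = 0.75, utility_l2 = 0.81, utility_sd = 0))
  eco <- simulate_economics(hist, par0, seed = 1)

  l1 <- eco$costs[eco$costs$patient_id == 1 & eco$costs$line == "L1", ]
  expect_equal(nrow(l1), 10L)
  expect_equal(sum(l1$cost_eur), 77230)              # 10 x 7723 exactly
  expect_equal(nrow(eco$costs[eco$costs$line == "L2", ]), 0L)
  expect_equal(sum(eco$costs$line == "palliative"), 1L)  # one death
  expect_true(all(eco$utilities$utility_index %in% c(0.75, 0.81)))
  # utilities at month 0 and every 3 months within the line
  u1 <- eco$utilities[eco$utilities$patient_id == 1, ]
  expect_equal(u1$month_index, c(0L, 3L, 6L, 9L))

  expect_error(simulate_economics(transform(hist, strategy = "other"), par0),
               "no economic parameters")
  expect_error(econ_gen_params(data.frame(strategy = "S")), "missing")
})

test_that("cohort CSVs round-trip and a fixed master seed is fully reproducible", {
  tabs <- simulate_cohort(10, "BRAF-wt", seed = 123)
  expect_equal(nrow(tabs$cohort), 10L)

  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(tabs, d1)
  back <- read_cohort(d1)
  write_cohort(back, d2)
  for (f in c("cohort.csv", "events.csv", "costs.csv", "utilities.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_equal(back$cohort$strategy, tabs$cohort$strategy)
  expect_equal(back$events$t_exit_l1, round(tabs$events$t_exit_l1, 2))

  # empty cohort: header-only files
  d0 <- file.path(tempdir(), "coh0")
  write_cohort(simulate_cohort(0, "BRAF-wt", seed = 1), d0)
  expect_equal(nrow(read_cohort(d0)$cohort), 0L)
  expect_gt(length(readLines(file.path(d0, "events.csv"))), 0L)

  tabs2 <- simulate_cohort(10, "BRAF-wt", seed = 123)
  expect_identical(tabs, tabs2)
})

test_that("with no assignment coefficients every covariate is balanced across arms", {
  n <- 20000
  cov <- generate_covariates(n, melanoma_covariates(), seed = 31)
  asg <- assign_strategy(cov, assignment_model(c("a", "b", "c")), seed = 32)
  X <- expand_covariates(cov)
  for (cv in colnames(X)) {
    for (s in c("a", "b")) {
      expect_lt(standardized_mean_difference(X[, cv], asg$strategy == s),
                0.05)
    }
  }
})
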