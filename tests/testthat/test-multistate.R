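test_that("weighted KM reproduces the product-limit estimator and its invariances", {
  km <- weighted_km(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 0))
  expect_equal(melcea:::eval_km(km, 2), 0.75)     # 1 * (3/4)
  expect_equal(melcea:::eval_km(km, 4), 0.375)    # (3/4) * (1/2)

  # no events: flat at 1
  km0 <- weighted_km(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # doubling all weights leaves the curve unchanged
  km2 <- weighted_km(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 0), rep(2, 5))
  expect_equal(km$surv, km2$surv)
  expect_equal(km$time, km2$time)

  expect_error(weighted_km(numeric(0), numeric(0)), "no observations")
})

test_that("parametric tails are fitted by weighted ML and selected by AIC", {
  set.seed(5)
  t_exp <- rexp(5000, 0.1)
  f_exp <- fit_tail(t_exp, rep(1, 5000), family = "exponential")
  expect_lt(abs(f_exp$pars[["rate"]] - 0.1), 0.005)
  f_wb <- fit_tail(t_exp, rep(1, 5000), family = "weibull")
  # exponential wins or ties against the nested weibull on exponential data
  expect_lte(f_exp$aic, f_wb$aic + 2.1)
  sel <- select_tail(list(f_wb, f_exp))
  expect_true(sel$family == "exponential" || f_wb$aic < f_exp$aic)

  # weibull shape 2: weibull beats exponential decisively
  t_wb <- rweibull(2000, shape = 2, scale = 10)
  expect_lt(fit_tail(t_wb, rep(1, 2000), family = "weibull")$aic,
            fit_tail(t_wb, rep(1, 2000), family = "exponential")$aic)

  expect_error(fit_tail(c(1, 2, 3), c(0, 0, 0)), "censored")
  # weight-scale invariance of the selected family on real-shaped data
  cands <- melcea:::fit_all_tails(t_exp[1:500], rep(1, 500))
  expect_gte(length(cands), 2L)
})

test_that("extrapolation splices the rescaled tail continuously onto the KM", {
  km <- weighted_km(1:5, rep(1, 5))   # S = .8 .6 .4 .2 0 at t = 1..5
  tail <- exp_tail(0.05)

  # S(attach + 12) = S_km(attach) * exp(-rate * 12)
  ex <- extrapolate(km, tail, horizon = 24, attach = 3)
  expect_equal(ex$survival[ex$t_months == 3], 0.4)
  expect_equal(ex$survival[ex$t_months == 15], 0.4 * exp(-0.6),
               tolerance = 1e-12)
  expect_true(all(diff(ex$survival) <= 1e-12))
  expect_equal(unique(ex$source[ex$t_months <= 3]), "km")

  # horizon at the attachment point: pure KM restriction
  ex0 <- extrapolate(km, tail, horizon = 3, attach = 3)
  expect_equal(ex0$survival, c(1, melcea:::eval_km(km, 1:3)))
})

test_that("occupancy integration matches the analytic illness-death solution", {
  H <- 1200
  l1 <- melcea:::parametric_curve(function(t) exp(-0.1 * t), H)
  l2 <- melcea:::parametric_curve(function(t) exp(-0.1 * t), H)
  occ <- occupancy(l1, l2, 0.5, H)

  # lambda12 = lambda13 = 0.05, mu23 = 0.1: mean L1 time = 1/0.1 = 10 months,
  # mean L2 time = 0.5 / 0.1 = 5 months
  expect_lt(abs(melcea:::occupancy_auc(occ$p_l1) - 10) / 10, 0.02)
  expect_lt(abs(melcea:::occupancy_auc(occ$p_l2) - 5) / 5, 0.02)

  # conservation at every cycle and in the AUCs
  expect_lt(max(abs(occ$p_l1 + occ$p_l2 + occ$p_dead - 1)), 1e-9)
  auc_sum <- melcea:::occupancy_auc(occ$p_l1) + melcea:::occupancy_auc(occ$p_l2) +
    melcea:::occupancy_auc(occ$p_dead)
  expect_lt(abs(auc_sum - H), 1e-6)
  expect_true(all(diff(occ$p_dead) >= -1e-12))
  expect_true(all(occ$p_l2 >= 0 & occ$p_l2 <= 1))

  # zero hazards: everyone stays in L1
  flat <- melcea:::parametric_curve(function(t) rep(1, length(t)), 120)
  occ0 <- occupancy(flat, flat, 0.5, 120)
  expect_true(all(occ0$p_l1 == 1))

  # halving the cycle changes 10-year restricted means by < 1%
  l1h <- melcea:::parametric_curve(function(t) exp(-0.1 * t), 120, cycle = 0.5)
  l2h <- melcea:::parametric_curve(function(t) exp(-0.1 * t), 120, cycle = 0.5)
  o1 <- occupancy(l1, l2, 0.5, 120)
  o2 <- occupancy(l1h, l2h, 0.5, 120, cycle = 0.5)
  for (st in c("p_l1", "p_l2")) {
    a1 <- melcea:::occupancy_auc(o1[[st]])
    a2 <- melcea:::occupancy_auc(o2[[st]], cycle = 0.5)
    expect_lt(abs(a2 / a1 - 1), 0.01)
  }

  expect_error(occupancy(flat, flat, 0.5, 600), "grid mismatch")
})

test_that("per-cycle cause split integrates back to the cumulative incidence split", {
  set.seed(8)
  n <- 4000
  t12 <- rexp(n, 0.06); t13 <- rexp(n, 0.03)
  t_exit <- pmin(t12, t13, 60)
  cause <- ifelse(t_exit == 60, "censored",
                  ifelse(t12 < t13, "to_L2", "to_death"))
  share <- cause_split(t_exit, cause, horizon = 120)
  expect_true(all(share >= 0 & share <= 1))
  # overall split should be near 0.06 / 0.09 = 2/3
  expect_lt(abs(mean(share[1:30]) - 2 / 3), 0.06)
  # degenerate: everything censored falls back to an uninformative half
  expect_equal(cause_split(c(1, 2), c("censored", "censored"), horizon = 10),
               rep(0.5, 10))
})

test_that("strategy curve fitting produces horizon-covering monotone curves", {
  tabs <- simulate_cohort(800, "BRAF-wt", seed = 4)
  ev <- tabs$events
  one <- ev[ev$strategy == ev$strategy[1], ]
  cv <- fit_strategy_curves(one, horizon = 120)
  expect_equal(max(cv$l1_curve$t_months), 120)
  expect_true(all(diff(cv$l1_curve$survival) <= 1e-12))
  expect_true(all(diff(cv$l2_curve$survival) <= 1e-12))
  expect_equal(length(cv$l2_share), 120L)
  occ <- occupancy(cv$l1_curve, cv$l2_curve, cv$l2_share, 120)
  expect_lt(max(abs(occ$p_l1 + occ$p_l2 + occ$p_dead - 1)), 1e-9)
})
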