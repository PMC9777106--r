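#' Weighted Kaplan-Meier estimator
#'
#' Product-limit estimator with weighted risk sets and weighted event counts
#' (case weights in [survival::survfit()]). Unit weights reproduce the
#' classical KM; rescaling all weights by a constant leaves the curve
#' unchanged.
#'
#' @param times nonnegative event/censoring times (months)
#' @param events 1 = event, 0 = censored
#' @param weights positive case weights (default unit)
#' @return object of class `step_survival`: `time`, `surv` (starting value 1
#'   at time 0 implicit), weighted `n_risk` and `n_event`
#' @export
weighted_km <- function(times, events, weights = NULL) {
  assert_that(length(times) > 0, "no observations")
  assert_that(all(times >= 0), "times must be >= 0")
  weights <- weights %||% rep(1, length(times))
  assert_that(all(weights > 0), "weights must be > 0")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           weights = weights)
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event),
            class = "step_survival")
}

# right-continuous step evaluation of a step_survival at arbitrary times
eval_km <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1L]
}

#' Fit a parametric tail distribution by weighted maximum likelihood
#'
#' @param times,events,weights as in [weighted_km()]
#' @param family one of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`
#' @return object of class `parametric_tail`: `family`, `pars` (named, on the
#'   natural scale), `aic`, and `surv_fn(t)`
#' @export
fit_tail <- function(times, events, weights = NULL,
                     family = c("exponential", "weibull", "lognormal",
                                "loglogistic", "gompertz")) {
  family <- match.arg(family)
  weights <- weights %||% rep(1, length(times))
  n_ev <- sum(weights[events == 1])
  assert_that(sum(events) > 0, "cannot fit a tail: all observations censored")
  assert_that(n_ev >= 5, "need >= 5 weighted events to fit a tail")
  dist <- switch(family, exponential = "exp", weibull = "weibull",
                 lognormal = "lnorm", loglogistic = "llogis",
                 gompertz = "gompertz")
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(times, events) ~ 1, dist = dist,
                          weights = weights),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !is.finite(stats::AIC(fit))) {
    # moment-estimator fallback: exponential rate = weighted events / exposure
    warning(sprintf("%s tail did not converge; using exponential moment estimator",
                    family))
    rate <- n_ev / sum(weights * times)
    ll <- n_ev * log(rate) - rate * sum(weights * times)
    return(structure(list(family = "exponential", pars = c(rate = rate),
                          aic = -2 * ll + 2,
                          surv_fn = function(t) exp(-rate * t)),
                     class = "parametric_tail"))
  }
  pars <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  surv_fn <- local({
    f <- fit
    function(t) summary(f, t = t, type = "survival", ci = FALSE,
                        tidy = TRUE)$est
  })
  structure(list(family = family, pars = pars, aic = stats::AIC(fit),
                 surv_fn = surv_fn),
            class = "parametric_tail")
}

#' Select the minimum-AIC parametric tail
#'
#' Ties (within 1e-9) are broken by family order: exponential, weibull,
#' lognormal, loglogistic, gompertz.
#'
#' @param candidates list of [fit_tail()] results
#' @return the selected `parametric_tail`
#' @export
select_tail <- function(candidates) {
  assert_that(length(candidates) >= 1, "no tail candidates")
  order_pref <- c("exponential", "weibull", "lognormal", "loglogistic",
                  "gompertz")
  aic <- vapply(candidates, function(x) x$aic, numeric(1))
  pref <- match(vapply(candidates, function(x) x$family, character(1)),
                order_pref)
  best <- order(round(aic, 9), pref)[1]
  candidates[[best]]
}

# fit all five families, dropping those that fail outright
fit_all_tails <- function(times, events, weights = NULL) {
  fams <- c("exponential", "weibull", "lognormal", "loglogistic", "gompertz")
  cands <- list()
  for (f in fams) {
    fit <- tryCatch(suppressWarnings(fit_tail(times, events, weights, f)),
                    error = function(e) NULL)
    if (!is.null(fit)) cands[[length(cands) + 1L]] <- fit
  }
  assert_that(length(cands) > 0, "no tail family could be fitted")
  cands
}

# last event time at which the weighted risk set is still >= frac of the
# initial weighted risk set; extrapolation attaches here because later KM
# steps rest on too few patients
attach_time <- function(km, frac = 0.1) {
  ev <- km$n_event > 0
  if (!any(ev)) return(0)
  ok <- ev & (km$n_risk >= frac * km$n_risk[1])
  if (!any(ok)) return(km$time[which(ev)[1]])
  max(km$time[ok])
}

#' Extrapolate a KM curve with a rescaled parametric tail
#'
#' On a monthly grid `0..horizon`: the observed KM step function up to
#' `attach_time`, then the parametric tail rescaled to pass through the KM
#' value at the attachment point, S(t) = S_KM(a) * S_tail(t) / S_tail(a),
#' which makes the spliced curve continuous there.
#'
#' @param km a [weighted_km()] curve
#' @param tail a [fit_tail()]/[select_tail()] result
#' @param horizon months (>= last KM time used)
#' @param attach attachment time in months; default the last event time with
#'   weighted risk set >= 10% of the initial
#' @return data.frame of class `msm_curve`: `t_months`, `survival`, `source`
#'   (`"km"` or `"tail"`)
#' @export
extrapolate <- function(km, tail, horizon, attach = NULL) {
  attach <- attach %||% attach_time(km)
  grid <- 0:horizon
  s <- numeric(length(grid))
  obs <- grid <= attach
  s[obs] <- eval_km(km, grid[obs])
  if (any(!obs)) {
    s_attach <- eval_km(km, attach)
    tail_ref <- tail$surv_fn(attach)
    s[!obs] <- s_attach * tail$surv_fn(grid[!obs]) / tail_ref
  }
  s <- cummin(pmin(pmax(s, 0), 1))   # guard monotonicity against fp noise
  out <- data.frame(t_months = grid, survival = s,
                    source = ifelse(obs, "km", "tail"))
  class(out) <- c("msm_curve", "data.frame")
  out
}

# analytic grid curve, used for oracles and direct model input
parametric_curve <- function(surv_fn, horizon, cycle = 1) {
  grid <- seq(0, horizon, by = cycle)
  out <- data.frame(t_months = grid, survival = surv_fn(grid),
                    source = "tail")
  class(out) <- c("msm_curve", "data.frame")
  out
}

#' Per-cycle probability that an L1 exit goes to L2 rather than death
#'
#' Weighted Aalen-Johansen cumulative incidence of the two competing exit
#' causes; the per-cycle split is the ratio of CIF increments within the
#' cycle, falling back to the overall cumulative split where no exits were
#' observed (including the whole extrapolated region).
#'
#' @param times,weights L1 exit times and case weights
#' @param causes `"to_L2"`, `"to_death"` or `"censored"` per patient
#' @param horizon months
#' @return numeric vector of length `horizon` (one share per cycle), in [0,1]
#' @export
cause_split <- function(times, causes, weights = NULL, horizon = 120) {
  weights <- weights %||% rep(1, length(times))
  f <- factor(causes, levels = c("censored", "to_L2", "to_death"))
  if (all(causes == "censored")) return(rep(0.5, horizon))
  fit <- survival::survfit(survival::Surv(times, f) ~ 1, weights = weights)
  ci <- fit$pstate[, match(c("to_L2", "to_death"), fit$states), drop = FALSE]
  at <- function(t) {  # CIF values at time t (right-continuous step)
    idx <- findInterval(t, fit$time)
    rbind(c(0, 0), ci)[idx + 1L, , drop = FALSE]
  }
  lo <- at(0:(horizon - 1)); hi <- at(1:horizon)
  d2 <- hi[, 1] - lo[, 1]; dd <- hi[, 2] - lo[, 2]
  tot_end <- at(max(fit$time))
  overall <- if (sum(tot_end) > 0) tot_end[1] / sum(tot_end) else 0.5
  share <- ifelse(d2 + dd > 0, d2 / (d2 + dd), overall)
  pmin(pmax(share, 0), 1)
}

#' Integrate state occupancy over monthly cycles
#'
#' Discrete-time product integration of the three-state model on the monthly
#' grid. First-line occupancy is the extrapolated all-cause L1-exit survival;
#' per cycle, exits split into L2 entries and deaths by `l2_share`; each L2
#' entry cohort is tracked by its entry cycle with the clock-reset L2 sojourn
#' curve; death absorbs the remainder, so occupancy sums to 1 exactly.
#'
#' @param l1_curve extrapolated all-cause L1-exit curve ([extrapolate()])
#' @param l2_curve extrapolated L2 sojourn (death) curve on the same grid
#' @param l2_share per-cycle probability that an L1 exit enters L2 (scalar or
#'   one value per cycle, see [cause_split()])
#' @param horizon months
#' @param cycle cycle length in months (default 1); both curves must be
#'   defined on the `seq(0, horizon, by = cycle)` grid
#' @return data.frame of class `occupancy_curves`: `t_months`, `p_l1`,
#'   `p_l2`, `p_dead`
#' @export
occupancy <- function(l1_curve, l2_curve, l2_share, horizon = 120, cycle = 1) {
  assert_that(max(l1_curve$t_months) >= horizon &&
                max(l2_curve$t_months) >= horizon,
              "curves must cover the horizon (grid mismatch)")
  grid <- seq(0, horizon, by = cycle)
  ncyc <- length(grid) - 1L
  s1 <- l1_curve$survival[match(round(grid, 9), round(l1_curve$t_months, 9))]
  s2 <- l2_curve$survival[match(round(grid, 9), round(l2_curve$t_months, 9))]
  assert_that(!anyNA(s1) && !anyNA(s2),
              "curves must be defined on the cycle grid (grid mismatch)")
  share <- rep_len(l2_share, ncyc)
  p_l1 <- s1
  exits <- s1[1:ncyc] - s1[2:(ncyc + 1)]    # mass leaving L1 per cycle
  entrants <- exits * share                  # entering L2 mid-cycle
  # clock-reset convolution: the cohort entering during cycle s is credited
  # the L2 sojourn curve at half-cycle offsets (entry at the cycle midpoint),
  # which keeps the discretization error at O(cycle^2)
  s2h <- (s2[1:ncyc] + s2[2:(ncyc + 1)]) / 2   # S2((k - 0.5) * cycle)
  p_l2 <- numeric(ncyc + 1)
  for (s in seq_len(ncyc)) {
    t_idx <- s:ncyc
    p_l2[t_idx + 1L] <- p_l2[t_idx + 1L] + entrants[s] * s2h[t_idx - s + 1L]
  }
  p_dead <- 1 - p_l1 - p_l2
  out <- data.frame(t_months = grid, p_l1 = p_l1, p_l2 = p_l2,
                    p_dead = pmax(p_dead, 0))
  class(out) <- c("occupancy_curves", "data.frame")
  out
}

# area under an occupancy column (months): trapezoidal by default (half-cycle
# corrected), or left-step sums when half_cycle = FALSE
occupancy_auc <- function(p, half_cycle = TRUE, cycle = 1) {
  n <- length(p)
  cycle * if (half_cycle) sum((p[-n] + p[-1]) / 2) else sum(p[-n])
}

#' Fit all transition curves for one strategy
#'
#' Weighted KM for the all-cause L1 exit and the (clock-reset) L2 sojourn,
#' min-AIC parametric tails, extrapolation to the horizon, and the
#' Aalen-Johansen per-cycle cause split.
#'
#' @param events event-history data.frame for one strategy
#'   ([simulate_transitions()] schema)
#' @param weights per-patient weights aligned with `events` rows
#' @param horizon months
#' @return list: `l1_curve`, `l2_curve`, `l2_share`, `km_l1`, `km_l2`,
#'   `tail_l1`, `tail_l2`
#' @export
fit_strategy_curves <- function(events, weights = NULL, horizon = 120) {
  weights <- weights %||% rep(1, nrow(events))
  ev1 <- as.numeric(events$exit_l1_cause != "censored")
  km1 <- weighted_km(events$t_exit_l1, ev1, weights)
  tail1 <- select_tail(fit_all_tails(events$t_exit_l1, ev1, weights))
  l1_curve <- extrapolate(km1, tail1, horizon)
  in_l2 <- events$exit_l1_cause == "to_L2"
  assert_that(sum(in_l2) > 0, "no L2 entries observed for this strategy")
  ev2 <- as.numeric(events$l2_status[in_l2] == "death")
  km2 <- weighted_km(events$t_l2_sojourn[in_l2], ev2, weights[in_l2])
  tail2 <- select_tail(fit_all_tails(events$t_l2_sojourn[in_l2], ev2,
                                     weights[in_l2]))
  l2_curve <- extrapolate(km2, tail2, horizon)
  share <- cause_split(events$t_exit_l1, events$exit_l1_cause, weights,
                       horizon)
  list(l1_curve = l1_curve, l2_curve = l2_curve, l2_share = share,
       km_l1 = km1, km_l2 = km2, tail_l1 = tail1, tail_l2 = tail2)
}
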