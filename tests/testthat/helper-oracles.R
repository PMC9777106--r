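# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the frontier oracle is an exhaustive all-pairs scan, the
# occupancy oracle is a patient-level microsimulation from the same curves.

# O(n^2) dominance scan: a point is dominated if any other point is no more
# expensive and no less effective, with at least one strict inequality
brute_force_frontier <- function(points) {
  n <- nrow(points)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i &&
        points$cost[j] <= points$cost[i] &&
        points$effect[j] >= points$effect[i] &&
        (points$cost[j] < points$cost[i] || points$effect[j] > points$effect[i])
    }, logical(1)))
  }, logical(1))
  lab <- points$label[!dominated]
  # collapse exact duplicates to a single representative, as the frontier does
  keep <- !duplicated(points[!dominated, c("cost", "effect")])
  sort(lab[keep])
}

# patient-level microsimulation drawing L1 exit cycles from the L1 curve,
# cause by the per-cycle split, and L2 sojourn cycles from the L2 curve
# (events placed at cycle midpoints); returns mean months in L1 and in L2
microsim_occupancy <- function(l1_curve, l2_curve, l2_share, horizon,
                               n = 1e5, seed = 1) {
  set.seed(seed)
  s1 <- l1_curve$survival[match(0:horizon, l1_curve$t_months)]
  s2 <- l2_curve$survival[match(0:horizon, l2_curve$t_months)]
  share <- rep_len(l2_share, horizon)
  draw_cycle <- function(u, s) {
    # number of grid values of the nonincreasing s that are <= u
    m <- findInterval(u, rev(s))
    ifelse(m == 0L, Inf, length(s) - m)  # exit cycle index, Inf = survivor
  }
  u <- stats::runif(n)
  exit <- draw_cycle(u, s1)
  t_l1 <- ifelse(is.infinite(exit), horizon, exit - 0.5)
  to_l2 <- !is.infinite(exit) &
    stats::runif(n) < share[pmin(exit, horizon)]
  v <- stats::runif(n)
  soj_cycle <- draw_cycle(v, s2)
  soj <- ifelse(is.infinite(soj_cycle), horizon, soj_cycle - 0.5)
  t_l2 <- ifelse(to_l2, pmin(soj, horizon - t_l1), 0)
  list(mean_l1 = mean(t_l1), mean_l2 = mean(t_l2),
       se_l1 = stats::sd(t_l1) / sqrt(n), se_l2 = stats::sd(t_l2) / sqrt(n))
}

# two-strategy confounded null-effect cohort: assignment depends on three
# prognostic covariates that also raise the death hazards, but the hazards
# are identical across strategies (true marginal HR = 1)
make_null_confounded_cohort <- function(n, seed = 42) {
  prog <- c(brain_met = 0.7, elevated_ldh = 0.5, age_gt_65 = 0.4)
  model <- assignment_model(
    c("A", "B"),
    coefficients = list(A = c(brain_met = 0.8, elevated_ldh = 0.6,
                              age_gt_65 = 0.5),
                        B = numeric(0)))
  dist12 <- transition_dist("exponential", rate = 0.03)
  dist13 <- transition_dist("exponential", rate = 0.03, coef = prog)
  dist23 <- transition_dist("exponential", rate = 0.05, coef = prog)
  hz <- transition_hazards(c("A", "B"), dist12, dist13, dist23,
                           dropout_rate = 0.002, accrual_months = 1e-6,
                           cut_month = 1e9)
  cov <- generate_covariates(n, melanoma_covariates("BRAF-m"),
                             seed = stream_seed(seed, 1))
  asg <- assign_strategy(cov, model, seed = stream_seed(seed, 2))
  ev <- simulate_transitions(asg$strategy, cov, hz, horizon = 1200,
                             seed = stream_seed(seed, 3))
  list(cohort = cov, strategy = asg$strategy, propensity = asg$propensity,
       events = ev)
}

# all-cause overall-survival time and status from an event history
os_from_events <- function(ev) {
  soj <- ifelse(is.na(ev$t_l2_sojourn), 0, ev$t_l2_sojourn)
  time <- ev$t_exit_l1 + soj
  status <- as.numeric(ev$exit_l1_cause == "to_death" |
                         (!is.na(ev$l2_status) & ev$l2_status == "death"))
  data.frame(time = time, status = status)
}

# maximum strategy-vs-pooled SMD over all expanded covariate columns
max_smd <- function(cohort, labels, weights) {
  X <- expand_covariates(cohort)
  max(vapply(colnames(X), function(cv) {
    max(vapply(unique(labels), function(s) {
      melcea:::smd_vs_pooled(X[, cv], labels == s, weights)
    }, numeric(1)))
  }, numeric(1)))
}

# all strategy-vs-pooled SMDs across expanded covariate columns
balance_smds <- function(X, labels, weights) {
  unlist(lapply(colnames(X), function(cv) {
    vapply(unique(labels), function(s) {
      melcea:::smd_vs_pooled(X[, cv], labels == s, weights)
    }, numeric(1))
  }))
}

# manually built exponential tail, for splicing tests with known parameters
exp_tail <- function(rate) {
  structure(list(family = "exponential", pars = c(rate = rate), aic = NA_real_,
                 surv_fn = function(t) exp(-rate * t)),
            class = "parametric_tail")
}
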