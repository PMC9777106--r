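#' Discount factor at a monthly time point
#'
#' Monthly-compounded convention: `(1 + annual_rate)^(-t/12)`, so the factor
#' is 1 at t = 0 and for a zero rate.
#'
#' @param t time in months (>= 0)
#' @param annual_rate annual discount rate (default 0.04, the French
#'   reference-case rate; 0 in sensitivity analyses)
#' @return discount factor(s) in (0, 1]
#' @export
discount_factor <- function(t, annual_rate = 0.04) {
  assert_that(all(t >= 0), "t must be >= 0")
  assert_that(annual_rate >= 0, "annual_rate must be >= 0")
  (1 + annual_rate)^(-t / 12)
}

#' Per-(strategy, line) economic inputs
#'
#' @param table data.frame with columns `strategy`, `line` (`L1`/`L2`),
#'   `cost_month` (EUR), `utility`; palliative cost supplied separately
#' @param palliative named numeric vector: one-off palliative-care cost (EUR)
#'   per strategy, charged in the cycle of death
#' @return object of class `econ_inputs`
#' @export
econ_inputs <- function(table, palliative) {
  need <- c("strategy", "line", "cost_month", "utility")
  assert_that(all(need %in% names(table)),
              paste("econ_inputs table missing:",
                    paste(setdiff(need, names(table)), collapse = ", ")))
  assert_that(all(table$cost_month >= 0), "monthly costs must be >= 0")
  assert_that(all(table$utility >= -0.53 & table$utility <= 1),
              "utilities must lie in [-0.53, 1]")
  assert_that(all(unique(table$strategy) %in% names(palliative)),
              "palliative cost required for every strategy")
  structure(list(table = table, palliative = palliative),
            class = "econ_inputs")
}

#' Estimate economic inputs from cohort records
#'
#' Weighted means of monthly costs per (strategy, line) over observed
#' person-month records, weighted mean utility per (strategy, line), and
#' weighted mean palliative cost per strategy. Weights are per-patient IPTW
#' weights applied to each of the patient's records.
#'
#' @param costs cost records (`patient_id`, `line`, `month_index`, `cost_eur`)
#' @param utilities utility records (`patient_id`, `line`, `month_index`,
#'   `utility_index`)
#' @param patients data.frame with `patient_id`, `strategy` and `weight`
#' @return [econ_inputs()] (with `cost_sd` columns retained as metadata)
#' @export
estimate_econ_inputs <- function(costs, utilities, patients) {
  assert_that(all(c("patient_id", "strategy", "weight") %in% names(patients)),
              "patients needs patient_id, strategy, weight")
  join <- function(rec) {
    i <- match(rec$patient_id, patients$patient_id)
    assert_that(!anyNA(i), "records reference unknown patients")
    rec$strategy <- patients$strategy[i]
    rec$weight <- patients$weight[i]
    rec
  }
  costs <- join(costs); utilities <- join(utilities)
  strategies <- sort(unique(patients$strategy))
  cells <- expand.grid(strategy = strategies, line = c("L1", "L2"),
                       stringsAsFactors = FALSE)
  cells$cost_month <- NA_real_; cells$cost_sd <- NA_real_
  cells$utility <- NA_real_
  for (r in seq_len(nrow(cells))) {
    cc <- costs[costs$strategy == cells$strategy[r] &
                  costs$line == cells$line[r], ]
    assert_that(nrow(cc) > 0,
                sprintf("no observed person-months for (%s, %s)",
                        cells$strategy[r], cells$line[r]))
    cells$cost_month[r] <- wmean(cc$cost_eur, cc$weight)
    cells$cost_sd[r] <- wsd_pop(cc$cost_eur, cc$weight)
    uu <- utilities[utilities$strategy == cells$strategy[r] &
                      utilities$line == cells$line[r], ]
    assert_that(nrow(uu) > 0,
                sprintf("no utility observations for (%s, %s)",
                        cells$strategy[r], cells$line[r]))
    cells$utility[r] <- wmean(uu$utility_index, uu$weight)
  }
  pall <- vapply(strategies, function(s) {
    pp <- costs[costs$strategy == s & costs$line == "palliative", ]
    if (nrow(pp) == 0) 0 else wmean(pp$cost_eur, pp$weight)
  }, numeric(1))
  econ_inputs(cells, pall)
}

#' Discounted cost, QALYs and time in state for one strategy
#'
#' Accumulates over monthly cycles on the occupancy grid:
#' cost = sum over cycles of (P_L1 c_L1 + P_L2 c_L2) df(t) plus the
#' palliative cost times the per-cycle death increment; QALY = sum of
#' (P_L1 u_L1 + P_L2 u_L2) / 12 df(t); life-months use u = 1 undiscounted.
#' Cycle occupancy is the trapezoidal (half-cycle-corrected) average of the
#' endpoint values and is discounted at the cycle midpoint; `half_cycle =
#' FALSE` gives plain left-step sums.
#'
#' @param occ an [occupancy()] result
#' @param inputs an [econ_inputs()]
#' @param strategy strategy label to look up in `inputs`
#' @param annual_rate annual discount rate
#' @param half_cycle use trapezoidal cycle averaging (default TRUE)
#' @param discount_palliative discount the palliative cost at the cycle of
#'   death (default TRUE)
#' @return one-row data.frame: `strategy`, `months_l1`, `months_l2`,
#'   `months_total` (undiscounted), `qaly`, `cost_eur` (discounted)
#' @export
evaluate_strategy <- function(occ, inputs, strategy, annual_rate = 0.04,
                              half_cycle = TRUE, discount_palliative = TRUE) {
  assert_that(inherits(inputs, "econ_inputs"), "inputs must be econ_inputs")
  tab <- inputs$table
  row1 <- tab[tab$strategy == strategy & tab$line == "L1", ]
  row2 <- tab[tab$strategy == strategy & tab$line == "L2", ]
  assert_that(nrow(row1) == 1 && nrow(row2) == 1,
              sprintf("economic inputs missing for strategy '%s'", strategy))
  grid <- occ$t_months
  n <- length(grid)
  dt <- grid[2] - grid[1]
  avg <- function(p) if (half_cycle) (p[-n] + p[-1]) / 2 else p[-n]
  df <- discount_factor(grid[-n] + (if (half_cycle) dt / 2 else 0),
                        annual_rate)
  p1 <- avg(occ$p_l1); p2 <- avg(occ$p_l2)
  d_dead <- diff(occ$p_dead)
  cost <- sum((p1 * row1$cost_month + p2 * row2$cost_month) * dt * df) +
    sum(d_dead * inputs$palliative[[strategy]] *
          (if (discount_palliative) df else 1))
  qaly <- sum((p1 * row1$utility + p2 * row2$utility) * dt / 12 * df)
  m1 <- occupancy_auc(occ$p_l1, half_cycle, dt)
  m2 <- occupancy_auc(occ$p_l2, half_cycle, dt)
  data.frame(strategy = strategy, months_l1 = m1, months_l2 = m2,
             months_total = m1 + m2, qaly = qaly, cost_eur = cost)
}
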