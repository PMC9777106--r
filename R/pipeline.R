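#' Default run configuration
#'
#' Base case: 120-month (10-year) horizon, 4% annual discount rate, 1000
#' bootstrap replicates.
#'
#' @return named list of defaults
#' @export
default_config <- function() {
  list(population = "BRAF-m", n = 1000L, seed = 1L,
       horizon_months = 120L, discount_rate = 0.04,
       replicates = 1000L, truncation_quantile = NULL,
       max_trees = 600L, shrinkage = 0.05, interaction_depth = 2L,
       extended_dominance = FALSE)
}

#' Load and validate a run configuration
#'
#' YAML file with any subset of the [default_config()] keys; unknown keys are
#' rejected, defaults are echoed to the log. An empty file yields all
#' defaults.
#'
#' @param path YAML file path
#' @return validated configuration list
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  assert_that(length(unknown) == 0L,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(user)] <- user
  validate_config(cfg)
}

validate_config <- function(cfg) {
  assert_that(cfg$population %in% c("BRAF-m", "BRAF-wt"),
              "population must be 'BRAF-m' or 'BRAF-wt'")
  assert_that(is.numeric(cfg$horizon_months) && cfg$horizon_months > 0,
              "horizon_months must be > 0")
  assert_that(is.numeric(cfg$discount_rate) && cfg$discount_rate >= 0,
              "discount_rate must be >= 0")
  assert_that(cfg$n >= 0 && cfg$replicates >= 1, "invalid n or replicates")
  message(sprintf(
    "config: population=%s n=%d seed=%d horizon=%d months rate=%.3g replicates=%d",
    cfg$population, cfg$n, cfg$seed, cfg$horizon_months, cfg$discount_rate,
    cfg$replicates))
  cfg
}

#' Save a configuration to YAML
#'
#' @param cfg configuration list
#' @param path output path
#' @return `path`, invisibly
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], path)
  invisible(path)
}

log_stage <- function(stage, seed, n, t0) {
  message(sprintf("[%s] seed=%s n=%d elapsed=%.2fs", stage,
                  as.character(seed), n,
                  as.numeric(proc.time()[3]) - t0))
}

#' Fit the weighting and multistate stages on a cohort
#'
#' Estimates GBM propensity scores and IPTW weights, then the weighted
#' transition curves (KM + min-AIC parametric tails + cause split) per
#' strategy. The returned state can be evaluated at any horizon/discount rate
#' with [evaluate_pipeline()].
#'
#' @param tables cohort tables ([simulate_cohort()] / [read_cohort()] schema)
#' @param cfg configuration list ([default_config()] keys)
#' @return object of class `pipeline_state`
#' @export
fit_pipeline <- function(tables, cfg = default_config()) {
  t0 <- as.numeric(proc.time()[3])
  cov <- tables$cohort
  labels <- cov$strategy
  ps <- fit_propensity(cov, labels,
                       propensity_spec(max_trees = cfg$max_trees,
                                       shrinkage = cfg$shrinkage,
                                       interaction_depth = cfg$interaction_depth))
  w <- compute_weights(ps$propensity, labels,
                       truncation_quantile = cfg$truncation_quantile)
  w$patient_id <- cov$patient_id
  log_stage("weight", cfg$seed, nrow(cov), t0)
  t0 <- as.numeric(proc.time()[3])
  horizon <- cfg$horizon_months
  ev <- tables$events
  wi <- w$weight[match(ev$patient_id, w$patient_id)]
  curves <- lapply(split(seq_len(nrow(ev)), ev$strategy), function(i) {
    fit_strategy_curves(ev[i, ], wi[i], horizon = horizon)
  })
  patients <- data.frame(patient_id = cov$patient_id, strategy = labels,
                         weight = w$weight)
  inputs <- estimate_econ_inputs(tables$costs, tables$utilities, patients)
  log_stage("fit", cfg$seed, nrow(ev), t0)
  structure(list(cfg = cfg, tables = tables, propensity = ps, weights = w,
                 curves = curves, inputs = inputs, patients = patients),
            class = "pipeline_state")
}

#' Evaluate a fitted pipeline at a horizon and discount rate
#'
#' @param state a [fit_pipeline()] result
#' @param horizon_months analysis horizon (defaults to the fitted one; longer
#'   horizons re-extrapolate the stored KM + tail fits)
#' @param discount_rate annual discount rate
#' @return list: `outcomes` (per-strategy data.frame), `frontier`
#'   ([build_frontier()] result), `icers`
#' @export
evaluate_pipeline <- function(state, horizon_months = NULL,
                              discount_rate = NULL) {
  horizon <- horizon_months %||% state$cfg$horizon_months
  rate <- discount_rate %||% state$cfg$discount_rate
  outcomes <- do.call(rbind, lapply(names(state$curves), function(s) {
    cv <- state$curves[[s]]
    l1 <- if (horizon <= max(cv$l1_curve$t_months)) cv$l1_curve else
      extrapolate(cv$km_l1, cv$tail_l1, horizon)
    l2 <- if (horizon <= max(cv$l2_curve$t_months)) cv$l2_curve else
      extrapolate(cv$km_l2, cv$tail_l2, horizon)
    share <- cv$l2_share
    share <- if (horizon > length(share))
      c(share, rep(share[length(share)], horizon - length(share)))
    else share[seq_len(horizon)]
    occ <- occupancy(l1, l2, share, horizon)
    evaluate_strategy(occ, state$inputs, s, annual_rate = rate)
  }))
  rownames(outcomes) <- NULL
  fr <- build_frontier(data.frame(label = outcomes$strategy,
                                  cost = outcomes$cost_eur,
                                  effect = outcomes$qaly),
                       extended_dominance = isTRUE(state$cfg$extended_dominance))
  list(outcomes = outcomes, frontier = fr, icers = sequential_icers(fr))
}

#' Run the full pipeline and write all outputs
#'
#' simulate (unless tables are given) -> weight -> fit -> evaluate ->
#' frontier, writing `cohort.csv`, `events.csv`, `costs.csv`,
#' `utilities.csv`, `weights.csv`, `balance.csv`, `curves.csv`,
#' `occupancy.csv`, `outcomes.csv` and `frontier.csv` under `out_dir`.
#' All logging goes to stderr; results only to files.
#'
#' @param cfg configuration ([load_config()] / [default_config()])
#' @param out_dir output directory
#' @param tables optional pre-built cohort tables (skips simulation)
#' @return the `pipeline_state`, with `evaluation` attached, invisibly
#' @export
run_pipeline <- function(cfg = default_config(), out_dir, tables = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- as.numeric(proc.time()[3])
  if (is.null(tables)) {
    tables <- simulate_cohort(cfg$n, cfg$population, seed = cfg$seed,
                              horizon = cfg$horizon_months)
    log_stage("simulate", cfg$seed, cfg$n, t0)
  }
  write_cohort(tables, out_dir)
  state <- fit_pipeline(tables, cfg)
  evaln <- evaluate_pipeline(state)
  wcsv <- function(d, f) utils::write.csv(format_sig(d), file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(state$weights[, c("patient_id", "strategy", "propensity_assigned",
                         "weight", "weight_untruncated")], "weights.csv")
  wcsv(state$propensity$balance, "balance.csv")
  curves <- do.call(rbind, lapply(names(state$curves), function(s) {
    cv <- state$curves[[s]]
    rbind(cbind(strategy = s, transition = "L1_exit", cv$l1_curve),
          cbind(strategy = s, transition = "L2_death", cv$l2_curve))
  }))
  wcsv(curves, "curves.csv")
  occ <- do.call(rbind, lapply(names(state$curves), function(s) {
    cv <- state$curves[[s]]
    cbind(strategy = s,
          occupancy(cv$l1_curve, cv$l2_curve, cv$l2_share,
                    cfg$horizon_months))
  }))
  wcsv(occ, "occupancy.csv")
  out <- evaln$outcomes
  out$cost_eur <- round(out$cost_eur, 2)
  wcsv(out, "outcomes.csv")
  fr <- evaln$frontier$points
  ic <- evaln$icers
  fr$icer_vs_previous <- ic$icer[match(fr$label, ic$to)]
  names(fr)[names(fr) == "label"] <- "strategy"
  fr$cost <- round(fr$cost, 2)
  wcsv(fr, "frontier.csv")
  state$evaluation <- evaln
  invisible(state)
}

# 6 significant digits for interchange files (EUR totals rounded upstream)
format_sig <- function(d) {
  for (nm in names(d)) if (is.numeric(d[[nm]])) d[[nm]] <- signif(d[[nm]], 6)
  d
}

#' Sensitivity scenarios over horizon and discount rate
#'
#' Re-evaluates a fitted pipeline for each scenario (base case 120 months x
#' 4%; sensitivity horizons 60 and 180 months and rate 0) and reports
#' outcomes plus frontier membership per scenario.
#'
#' @param state a [fit_pipeline()] result
#' @param scenarios data.frame with `horizon_months` and `discount_rate`
#'   (default: the {60, 120, 180} x {0, 0.04} grid)
#' @return data.frame: scenario columns + per-strategy outcomes + `status`
#' @export
run_sensitivity <- function(state,
                            scenarios = expand.grid(
                              horizon_months = c(60L, 120L, 180L),
                              discount_rate = c(0, 0.04))) {
  out <- lapply(seq_len(nrow(scenarios)), function(i) {
    ev <- evaluate_pipeline(state, scenarios$horizon_months[i],
                            scenarios$discount_rate[i])
    d <- ev$outcomes
    d$status <- ev$frontier$points$status[match(d$strategy,
                                                ev$frontier$points$label)]
    cbind(scenarios[i, , drop = FALSE], d, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Published per-strategy reference outcomes
#'
#' Ten-year discounted mean time in state, survival, QALYs and total cost per
#' sequence for the French advanced-melanoma populations (BRAF-mutated and
#' BRAF-wild-type), at printed precision (months and QALYs to one decimal,
#' EUR to the unit). Used as worked-example inputs for the frontier/ICER
#' operations and as calibration anchors for the synthetic generator.
#'
#' @param population `"BRAF-m"`, `"BRAF-wt"` or `"all"`
#' @return data.frame: `population`, `strategy`, `months_l1`, `months_l2`,
#'   `months_total`, `qaly`, `cost_eur`
#' @export
reference_outcomes <- function(population = c("all", "BRAF-m", "BRAF-wt")) {
  population <- match.arg(population)
  f <- system.file("extdata", "strategy_outcomes_reference.csv",
                   package = "melcea", mustWork = TRUE)
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  if (population != "all") d <- d[d$population == population, ]
  rownames(d) <- NULL
  d
}
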