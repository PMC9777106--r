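#' Covariate specification for the synthetic cohort generator
#'
#' @param name column name (identifier)
#' @param kind `"binary"` or `"categorical"`
#' @param prevalence for binary covariates, probability of a 1
#' @param levels,probs for categorical covariates, level labels and their
#'   probabilities (must sum to 1)
#' @return an object of class `covariate_spec`
#' @export
covariate_spec <- function(name, kind = c("binary", "categorical"),
                           prevalence = NULL, levels = NULL, probs = NULL) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    assert_that(is.numeric(prevalence) && length(prevalence) == 1L &&
                  prevalence >= 0 && prevalence <= 1,
                sprintf("covariate '%s': prevalence must be in [0,1]", name))
    probs <- c(prevalence)
  } else {
    assert_that(!is.null(levels) && length(levels) >= 2L &&
                  length(levels) == length(probs),
                sprintf("covariate '%s': need >= 2 levels with matching probs", name))
    assert_that(all(probs >= 0 & probs <= 1) && abs(sum(probs) - 1) < 1e-9,
                sprintf("covariate '%s': probs must lie in [0,1] and sum to 1", name))
  }
  structure(list(name = name, kind = kind, levels = levels, probs = probs),
            class = "covariate_spec")
}

#' Default prognostic covariate set for advanced melanoma
#'
#' The ten baseline prognostic variables used throughout the analysis (brain
#' and liver metastases, elevated LDH, ECOG performance status, metastatic
#' stage, elevated neutrophil/lymphocyte ratio, BRAF V600E, age > 65 years,
#' anatomic site, BMI > 30), with default prevalences taken from the observed
#' distribution of the MelBase advanced-melanoma cohort by BRAF status.
#'
#' @param population `"BRAF-m"`, `"BRAF-wt"` or `"pooled"`
#' @return list of [covariate_spec()] objects
#' @export
melanoma_covariates <- function(population = c("BRAF-m", "BRAF-wt", "pooled")) {
  population <- match.arg(population)
  p <- switch(population,
    "BRAF-m" = list(brain = .229, liver = .285, ldh = .309, nlr = .307,
                    v600e = .783, age65 = .365, bmi30 = .185,
                    ecog = c(.814, .077, .109),
                    stage = c(.072, .100, .117, .660, .051),
                    site = c(.268, .432, .133, .022, .014, .131)),
    "BRAF-wt" = list(brain = .143, liver = .263, ldh = .301, nlr = .271,
                     v600e = 0, age65 = .644, bmi30 = .210,
                     ecog = c(.828, .076, .096),
                     stage = c(.123, .092, .200, .534, .051),
                     site = c(.306, .210, .142, .101, .104, .137)),
    "pooled" = list(brain = .179, liver = .272, ldh = .304, nlr = .283,
                    v600e = .328, age65 = .526, bmi30 = .200,
                    ecog = c(.822, .076, .102),
                    stage = c(.101, .096, .165, .587, .051),
                    site = c(.290, .304, .138, .068, .066, .134))
  )
  norm1 <- function(x) x / sum(x)
  list(
    covariate_spec("brain_met",   "binary", prevalence = p$brain),
    covariate_spec("liver_met",   "binary", prevalence = p$liver),
    covariate_spec("elevated_ldh","binary", prevalence = p$ldh),
    covariate_spec("ecog", "categorical",
                   levels = c("0-1", "2-4", "unknown"), probs = norm1(p$ecog)),
    covariate_spec("metastatic_stage", "categorical",
                   levels = c("IIIC", "M1a", "M1b", "M1c", "unknown"),
                   probs = norm1(p$stage)),
    covariate_spec("high_nlr",    "binary", prevalence = p$nlr),
    covariate_spec("braf_v600e",  "binary", prevalence = p$v600e),
    covariate_spec("age_gt_65",   "binary", prevalence = p$age65),
    covariate_spec("anatomic_site", "categorical",
                   levels = c("extremities", "trunk", "head_neck",
                              "acral", "mucosa", "unknown"),
                   probs = norm1(p$site)),
    covariate_spec("bmi_gt_30",   "binary", prevalence = p$bmi30)
  )
}

#' Generate baseline covariates
#'
#' Draws `n` independent patients from the marginal covariate distributions in
#' `spec`. Binary covariates are 0/1 integers, categorical covariates are
#' character labels.
#'
#' @param n number of patients (0 allowed: returns a header-only table)
#' @param spec list of [covariate_spec()]
#' @param seed integer seed (one independent stream)
#' @return data.frame with `patient_id` plus one column per covariate
#' @export
generate_covariates <- function(n, spec = melanoma_covariates(), seed = 1L) {
  assert_that(is.numeric(n) && n >= 0, "n must be a nonnegative count")
  assert_that(is.list(spec) && all(vapply(spec, inherits, TRUE, "covariate_spec")),
              "spec must be a list of covariate_spec objects")
  set.seed(seed)
  out <- data.frame(patient_id = seq_len(n))
  for (cv in spec) {
    out[[cv$name]] <- if (cv$kind == "binary") {
      if (n == 0L) integer(0) else stats::rbinom(n, 1L, cv$probs)
    } else {
      if (n == 0L) character(0) else sample(cv$levels, n, TRUE, prob = cv$probs)
    }
  }
  out
}

#' Expand a covariate table to a numeric design matrix
#'
#' Binary 0/1 columns are kept as-is; categorical (character/factor) columns
#' are expanded to one indicator per non-reference level (`<name>.<level>`,
#' first level as reference). `patient_id`, `strategy`, `weight` and
#' `true_p_*` columns are dropped.
#'
#' @param covariates baseline covariate data.frame
#' @return numeric matrix, one row per patient
#' @export
expand_covariates <- function(covariates) {
  drop <- c("patient_id", "strategy", "weight")
  keep <- setdiff(names(covariates), drop)
  keep <- keep[!startsWith(keep, "true_p_")]
  cols <- list()
  for (nm in keep) {
    x <- covariates[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      lev <- sort(unique(x))
      for (lv in lev[-1]) cols[[paste(nm, lv, sep = ".")]] <- as.numeric(x == lv)
    }
  }
  m <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(covariates), ncol = 0)
  rownames(m) <- NULL
  m
}

#' Multinomial-logit treatment assignment model
#'
#' Describes nonrandom treatment allocation: patient i receives strategy k
#' with probability softmax(alpha_k + x_i' beta_k). Used by the generator to
#' build in the confounding that the weighting module must correct.
#'
#' @param strategies character vector of >= 2 strategy labels
#' @param intercepts numeric, one per strategy (default 0)
#' @param coefficients named list, one element per strategy: a named numeric
#'   vector of log-odds coefficients on expanded covariate columns
#' @return object of class `assignment_model`
#' @export
assignment_model <- function(strategies, intercepts = NULL, coefficients = NULL) {
  assert_that(length(strategies) >= 2L, "need at least 2 strategies")
  intercepts <- intercepts %||% rep(0, length(strategies))
  assert_that(length(intercepts) == length(strategies),
              "one intercept per strategy required")
  coefficients <- coefficients %||%
    stats::setNames(rep(list(numeric(0)), length(strategies)), strategies)
  assert_that(all(strategies %in% names(coefficients)),
              "coefficients must be named by strategy")
  structure(list(strategies = strategies,
                 intercepts = stats::setNames(intercepts, strategies),
                 coefficients = coefficients[strategies]),
            class = "assignment_model")
}

#' Default confounded assignment model
#'
#' Moderate confounding on brain metastases, elevated LDH and age > 65:
#' coefficients spread symmetrically across strategies so each strategy
#' attracts a different prognostic mix (standardized mean differences around
#' 0.1-0.4 before weighting).
#'
#' @param strategies strategy labels
#' @return [assignment_model()]
#' @export
default_assignment_model <- function(strategies) {
  K <- length(strategies)
  lean <- seq(-1, 1, length.out = K)
  coefs <- lapply(seq_len(K), function(k) {
    c(brain_met = 0.9 * lean[k],
      elevated_ldh = -0.7 * lean[k],
      age_gt_65 = 0.5 * lean[k %% K + 1L])
  })
  names(coefs) <- strategies
  assignment_model(strategies, coefficients = coefs)
}

#' Assign treatment strategies with known (true) propensities
#'
#' Samples a strategy per patient from the multinomial-logit model and also
#' returns the exact assignment probabilities used — the oracle against which
#' estimated propensity scores and weights can be tested.
#'
#' @param covariates baseline table from [generate_covariates()]
#' @param model an [assignment_model()]
#' @param seed integer seed
#' @return list with `strategy` (character vector) and `propensity`
#'   (n x K matrix, rows summing to 1, columns named by strategy)
#' @export
assign_strategy <- function(covariates, model, seed = 1L) {
  assert_that(inherits(model, "assignment_model"), "model must be an assignment_model")
  X <- expand_covariates(covariates)
  n <- nrow(covariates)
  K <- length(model$strategies)
  if (n == 0L) {
    return(list(strategy = character(0),
                propensity = matrix(numeric(0), 0, K,
                                    dimnames = list(NULL, model$strategies))))
  }
  eta <- matrix(rep(model$intercepts, each = n), n, K,
                dimnames = list(NULL, model$strategies))
  for (k in model$strategies) {
    b <- model$coefficients[[k]]
    if (length(b)) {
      missing <- setdiff(names(b), colnames(X))
      assert_that(length(missing) == 0L,
                  paste("assignment coefficients reference unknown covariate columns:",
                        paste(missing, collapse = ", ")))
      eta[, k] <- eta[, k] + X[, names(b), drop = FALSE] %*% b
    }
  }
  eta <- eta - apply(eta, 1, max)            # softmax, overflow-safe
  p <- exp(eta) / rowSums(exp(eta))
  set.seed(seed)
  u <- stats::runif(n)
  cum <- t(apply(p, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  list(strategy = model$strategies[idx], propensity = p)
}

#' Per-transition event-time hazards for one strategy
#'
#' Each of the three transitions (L1 to L2, L1 to death, L2 to death) gets a
#' parametric sojourn distribution on the months scale. `family` is
#' `"exponential"` (rate, events/month) or `"weibull"` (shape, scale as in
#' [stats::rweibull()]). Optional `coef` gives proportional-hazards log-hazard
#' ratios on expanded covariate columns. Rates/shapes must be finite and
#' nonnegative; a zero rate means the transition never fires.
#'
#' @param family distribution family
#' @param rate exponential rate (events/month)
#' @param shape,scale Weibull parameters
#' @param coef optional named numeric vector of log-hazard ratios
#' @return object of class `transition_dist`
#' @export
transition_dist <- function(family = c("exponential", "weibull"),
                            rate = NULL, shape = NULL, scale = NULL,
                            coef = NULL) {
  family <- match.arg(family)
  if (family == "exponential") {
    assert_that(is.numeric(rate) && length(rate) == 1L && is.finite(rate) && rate >= 0,
                "exponential rate must be finite and >= 0")
  } else {
    assert_that(is.numeric(shape) && shape > 0 && is.numeric(scale) && scale > 0,
                "weibull shape and scale must be > 0")
  }
  structure(list(family = family, rate = rate, shape = shape, scale = scale,
                 coef = coef), class = "transition_dist")
}

#' Transition hazards for a set of strategies
#'
#' @param strategies strategy labels
#' @param l1_to_l2,l1_to_death,l2_to_death named lists (one
#'   [transition_dist()] per strategy), or a single `transition_dist` recycled
#' @param dropout_rate exponential loss-to-follow-up rate (events/month)
#' @param accrual_months patients enter uniformly over this accrual window
#' @param cut_month administrative data cut (months after start of accrual)
#' @return object of class `transition_hazards`
#' @export
transition_hazards <- function(strategies, l1_to_l2, l1_to_death, l2_to_death,
                               dropout_rate = 0.005, accrual_months = 66,
                               cut_month = 66) {
  recycle <- function(x) {
    if (inherits(x, "transition_dist"))
      x <- stats::setNames(rep(list(x), length(strategies)), strategies)
    assert_that(all(strategies %in% names(x)),
                "each strategy needs a transition_dist")
    x
  }
  assert_that(dropout_rate >= 0 && accrual_months > 0 && cut_month > 0,
              "censoring parameters must be nonnegative")
  structure(list(strategies = strategies,
                 l1_to_l2 = recycle(l1_to_l2),
                 l1_to_death = recycle(l1_to_death),
                 l2_to_death = recycle(l2_to_death),
                 dropout_rate = dropout_rate,
                 accrual_months = accrual_months,
                 cut_month = cut_month),
            class = "transition_hazards")
}

# mean L1 / L2+ occupancy (months, 10-year model) used to calibrate the
# generator's exponential sojourn rates, plus monthly cost / utility / one-off
# palliative-care parameters per sequence, from the observed MelBase tables
melanoma_strategy_defaults <- function(population = c("BRAF-m", "BRAF-wt")) {
  population <- match.arg(population)
  if (population == "BRAF-m") {
    data.frame(
      strategy = c("Anti-PD1 -> Bi-TT", "Bi-TT -> Anti-PD1",
                   "IPI+NIVO -> Bi-TT", "MONO-TT -> Bi-TT",
                   "MONO-TT -> Anti-PD1"),
      mean_l1 = c(15.6, 21.4, 9.7, 12.1, 21.4),
      mean_l2 = c(32.3, 17.0, 25.7, 29.4, 18.9),
      p_l2 = 0.60,
      cost_l1_mean = c(7723, 13050, 26966, 11932, 8165),
      cost_l1_sd   = c(3701, 6867, 32824, 11962, 5077),
      cost_l2_mean = c(11127, 8685, 10733, 9566, 9481),
      cost_l2_sd   = c(3361, 5525, 3917, 3731, 13063),
      pall_mean    = c(2928, 2477, 1247, 2652, 2652),
      pall_sd      = c(5349, 4329, 2864, 4922, 4922),
      utility_l1   = c(0.75, 0.77, 0.68, 0.66, 0.76),
      utility_l2   = c(0.81, 0.73, 0.70, 0.70, 0.72)
    )
  } else {
    data.frame(
      strategy = c("Anti-PD1", "IPI+NIVO", "Ipilimumab", "Chemotherapy"),
      mean_l1 = c(14.7, 21.3, 5.6, 4.1),
      mean_l2 = c(8.0, 5.3, 18.5, 16.3),
      p_l2 = 0.45,
      cost_l1_mean = c(6769, 11412, 15858, 3381),
      cost_l1_sd   = c(4433, 11994, 29563, 6996),
      cost_l2_mean = c(7932, 14956, 4942, 7551),
      cost_l2_sd   = c(5796, 40275, 2688, 5256),
      pall_mean    = c(1713, 1407, 2900, 2240),
      pall_sd      = c(3037, 3944, 5562, 3411),
      utility_l1   = c(0.74, 0.75, 0.73, 0.67),
      utility_l2   = c(0.64, 0.65, 0.70, 0.65)
    )
  }
}

#' Default transition hazards per population
#'
#' Exponential sojourn distributions calibrated loosely to the mean 10-year
#' state-occupancy times per sequence (L1 exit rate = 1/mean L1 time, split
#' to L2 vs death by the observed share of patients reaching a second line;
#' L2 death rate = 1/mean L2+ time), with uniform accrual over 66 months and
#' an administrative cut at month 66.
#'
#' @param population `"BRAF-m"` or `"BRAF-wt"`
#' @param prognostic_coef optional named log-hazard-ratio vector applied to
#'   both death transitions (e.g. `c(brain_met = 0.5)`); default none
#' @return [transition_hazards()]
#' @export
melanoma_hazards <- function(population = c("BRAF-m", "BRAF-wt"),
                             prognostic_coef = NULL) {
  d <- melanoma_strategy_defaults(match.arg(population))
  mk <- function(rates, coef = NULL) {
    x <- lapply(rates, function(r) transition_dist("exponential", rate = r, coef = coef))
    stats::setNames(x, d$strategy)
  }
  exit_rate <- 1 / d$mean_l1
  transition_hazards(
    strategies = d$strategy,
    l1_to_l2 = mk(d$p_l2 * exit_rate),
    l1_to_death = mk((1 - d$p_l2) * exit_rate, prognostic_coef),
    l2_to_death = mk(1 / d$mean_l2, prognostic_coef)
  )
}

# inverse-CDF event-time draw under proportional hazards: S(t) = S0(t)^exp(lp)
draw_event_time <- function(n, dist, lp = 0) {
  if (dist$family == "exponential") {
    r <- dist$rate * exp(lp)
    t <- rep(Inf, n)
    pos <- r > 0
    if (any(pos)) t[pos] <- stats::rexp(sum(pos)) / r[pos]
    t
  } else {
    # baseline cumulative hazard (t/scale)^shape
    dist$scale * (stats::rexp(n) / exp(lp))^(1 / dist$shape)
  }
}

#' Simulate three-state transition histories
#'
#' Competing risks out of first line (L1) are simulated as the minimum of
#' independent latent times to L2, to death, and to censoring (exponential
#' drop-out plus administrative censoring at the data cut given uniform
#' accrual, plus the analysis horizon). The L2-to-death sojourn clock resets
#' at L2 entry (semi-Markov convention).
#'
#' @param labels strategy label per patient
#' @param covariates baseline table (used by proportional-hazards coefficients)
#' @param hazards a [transition_hazards()]
#' @param horizon months of maximum follow-up (> 0)
#' @param seed integer seed
#' @return data.frame of event histories: `patient_id`, `strategy`,
#'   `t_exit_l1` (months), `exit_l1_cause` (`to_L2`/`to_death`/`censored`),
#'   `t_l2_sojourn` (months since L2 entry, NA unless cause is `to_L2`),
#'   `l2_status` (`death`/`censored`/NA)
#' @export
simulate_transitions <- function(labels, covariates, hazards, horizon = 120,
                                 seed = 1L) {
  assert_that(inherits(hazards, "transition_hazards"),
              "hazards must be a transition_hazards object")
  assert_that(horizon > 0, "horizon must be > 0")
  n <- length(labels)
  assert_that(n == nrow(covariates), "labels and covariates must align")
  if (n == 0L) {
    return(data.frame(patient_id = integer(0), strategy = character(0),
                      t_exit_l1 = numeric(0), exit_l1_cause = character(0),
                      t_l2_sojourn = numeric(0), l2_status = character(0),
                      stringsAsFactors = FALSE))
  }
  X <- expand_covariates(covariates)
  lp_of <- function(dist) {
    if (is.null(dist$coef) || !length(dist$coef)) return(rep(0, n))
    as.numeric(X[, names(dist$coef), drop = FALSE] %*% dist$coef)
  }
  set.seed(seed)
  entry <- stats::runif(n, 0, hazards$accrual_months)
  admin <- pmin(pmax(hazards$cut_month - entry, 0), horizon)
  tdrop <- if (hazards$dropout_rate > 0)
    stats::rexp(n, hazards$dropout_rate) else rep(Inf, n)
  cens <- pmin(tdrop, admin)

  t12 <- t13 <- rep(Inf, n)
  t23 <- rep(Inf, n)
  for (s in unique(labels)) {
    i <- which(labels == s)
    assert_that(s %in% hazards$strategies,
                sprintf("no hazards configured for strategy '%s'", s))
    d12 <- hazards$l1_to_l2[[s]]; d13 <- hazards$l1_to_death[[s]]
    d23 <- hazards$l2_to_death[[s]]
    t12[i] <- draw_event_time(length(i), d12, lp_of(d12)[i])
    t13[i] <- draw_event_time(length(i), d13, lp_of(d13)[i])
    t23[i] <- draw_event_time(length(i), d23, lp_of(d23)[i])
  }
  t_exit <- pmin(t12, t13, cens)
  cause <- ifelse(t_exit == cens, "censored",
                  ifelse(t12 <= t13, "to_L2", "to_death"))
  # clock reset in L2: sojourn censored by remaining follow-up
  remain <- cens - t_exit
  in_l2 <- cause == "to_L2"
  soj <- ifelse(in_l2, pmin(t23, remain), NA_real_)
  l2_status <- ifelse(in_l2, ifelse(t23 <= remain, "death", "censored"),
                      NA_character_)
  data.frame(patient_id = covariates$patient_id %||% seq_len(n),
             strategy = labels,
             t_exit_l1 = t_exit, exit_l1_cause = cause,
             t_l2_sojourn = soj, l2_status = l2_status,
             stringsAsFactors = FALSE)
}

#' Per-(strategy, line) cost and utility generating parameters
#'
#' @param table data.frame with columns `strategy`, `cost_l1_mean`,
#'   `cost_l1_sd`, `cost_l2_mean`, `cost_l2_sd`, `pall_mean`, `pall_sd`,
#'   `utility_l1`, `utility_l2` and optionally `utility_sd`
#' @return object of class `econ_gen_params`
#' @export
econ_gen_params <- function(table) {
  need <- c("strategy", "cost_l1_mean", "cost_l1_sd", "cost_l2_mean",
            "cost_l2_sd", "pall_mean", "pall_sd", "utility_l1", "utility_l2")
  assert_that(all(need %in% names(table)),
              paste("econ_gen_params table missing:",
                    paste(setdiff(need, names(table)), collapse = ", ")))
  assert_that(all(table$cost_l1_mean >= 0) && all(table$cost_l2_mean >= 0) &&
                all(table$pall_mean >= 0), "cost means must be >= 0")
  assert_that(all(table$utility_l1 >= -0.53 & table$utility_l1 <= 1) &&
                all(table$utility_l2 >= -0.53 & table$utility_l2 <= 1),
              "utility means must lie in [-0.53, 1]")
  if (is.null(table$utility_sd)) table$utility_sd <- 0.2
  structure(list(table = table), class = "econ_gen_params")
}

#' Default economic generating parameters per population
#'
#' Monthly per-line management costs (mean and SD, EUR), one-off palliative
#' care cost at death, and mean per-line EQ-5D utility indices per sequence,
#' as observed in the MelBase cohort. Utility SD defaults to 0.2 (typical
#' EQ-5D-3L index dispersion; only means and CIs are reported per line).
#'
#' @inheritParams melanoma_hazards
#' @param utility_sd between-observation utility SD
#' @return [econ_gen_params()]
#' @export
melanoma_econ_params <- function(population = c("BRAF-m", "BRAF-wt"),
                                 utility_sd = 0.2) {
  d <- melanoma_strategy_defaults(match.arg(population))
  d$utility_sd <- utility_sd
  econ_gen_params(d)
}

#' Simulate monthly cost records and utility observations
#'
#' One cost record per occupied patient-month per line (truncated-normal draw,
#' floored at 0); utility observations at line entry (month 0), every 3 months
#' within the line, and at line change (normal truncated to the French EQ-5D
#' index range `[-0.53, 1]`); one palliative-care cost record at death.
#'
#' @param histories event histories from [simulate_transitions()]
#' @param params an [econ_gen_params()]
#' @param seed integer seed
#' @return list of two data.frames: `costs` (`patient_id`, `line`,
#'   `month_index`, `cost_eur`) and `utilities` (`patient_id`, `line`,
#'   `month_index`, `utility_index`)
#' @export
simulate_economics <- function(histories, params, seed = 1L) {
  assert_that(inherits(params, "econ_gen_params"), "params must be econ_gen_params")
  tab <- params$table
  missing <- setdiff(unique(histories$strategy), tab$strategy)
  assert_that(length(missing) == 0L,
              paste("no economic parameters for strategy:",
                    paste(missing, collapse = ", ")))
  set.seed(seed)
  row_of <- tab[match(histories$strategy, tab$strategy), ]
  pid <- histories$patient_id
  n_l1 <- as.integer(ifelse(histories$t_exit_l1 > 0,
                            ceiling(histories$t_exit_l1), 0))
  soj <- ifelse(is.na(histories$t_l2_sojourn), 0, histories$t_l2_sojourn)
  n_l2 <- as.integer(ifelse(soj > 0, ceiling(soj), 0))
  died <- histories$exit_l1_cause == "to_death" |
    (!is.na(histories$l2_status) & histories$l2_status == "death")
  # one cost record per occupied patient-month per line
  line_costs <- function(nm, mu, sig, label) {
    data.frame(patient_id = rep(pid, nm), line = rep(label, sum(nm)),
               month_index = sequence(nm) - 1L,
               cost_eur = rtruncnorm(sum(nm), rep(mu, nm), rep(sig, nm), lo = 0))
  }
  costs <- rbind(
    line_costs(n_l1, row_of$cost_l1_mean, row_of$cost_l1_sd, "L1"),
    line_costs(n_l2, row_of$cost_l2_mean, row_of$cost_l2_sd, "L2"),
    data.frame(patient_id = pid[died], line = rep("palliative", sum(died)),
               month_index = as.integer(floor(histories$t_exit_l1 + soj))[died],
               cost_eur = rtruncnorm(sum(died), row_of$pall_mean[died],
                                     row_of$pall_sd[died], lo = 0))
  )
  # utility observations at line entry and every 3 months within the line;
  # the L2 month-0 observation is the line-change assessment
  u_l1 <- as.integer(floor(pmax(histories$t_exit_l1 - 1e-9, 0) / 3)) + 1L
  in_l2 <- histories$exit_l1_cause == "to_L2"
  u_l2 <- ifelse(in_l2, as.integer(floor(pmax(soj - 1e-9, 0) / 3)) + 1L, 0L)
  utilities <- rbind(
    data.frame(patient_id = rep(pid, u_l1), line = rep("L1", sum(u_l1)),
               month_index = (sequence(u_l1) - 1L) * 3L,
               utility_index = rtruncnorm(sum(u_l1), rep(row_of$utility_l1, u_l1),
                                          rep(row_of$utility_sd, u_l1),
                                          lo = -0.53, hi = 1)),
    data.frame(patient_id = rep(pid, u_l2), line = rep("L2", sum(u_l2)),
               month_index = (sequence(u_l2) - 1L) * 3L,
               utility_index = rtruncnorm(sum(u_l2), rep(row_of$utility_l2, u_l2),
                                          rep(row_of$utility_sd, u_l2),
                                          lo = -0.53, hi = 1))
  )
  rownames(costs) <- rownames(utilities) <- NULL
  list(costs = costs, utilities = utilities)
}

#' Simulate a complete synthetic cohort
#'
#' Runs covariate generation, confounded strategy assignment, transition
#' simulation and cost/utility simulation with independent seed streams
#' derived from one master seed (see [stream_seed()]).
#'
#' @param n cohort size
#' @param population `"BRAF-m"` or `"BRAF-wt"` (sets all defaults)
#' @param seed master integer seed
#' @param spec,model,hazards,econ optional overrides of the population defaults
#' @param horizon months of follow-up simulation
#' @return list of data.frames `cohort` (covariates + strategy + true
#'   propensities), `events`, `costs`, `utilities`
#' @export
simulate_cohort <- function(n, population = c("BRAF-m", "BRAF-wt"), seed = 1L,
                            spec = NULL, model = NULL, hazards = NULL,
                            econ = NULL, horizon = 120) {
  population <- match.arg(population)
  spec <- spec %||% melanoma_covariates(population)
  hazards <- hazards %||% melanoma_hazards(population)
  model <- model %||% default_assignment_model(hazards$strategies)
  econ <- econ %||% melanoma_econ_params(population)
  cov <- generate_covariates(n, spec, seed = stream_seed(seed, 1))
  asg <- assign_strategy(cov, model, seed = stream_seed(seed, 2))
  events <- simulate_transitions(asg$strategy, cov, hazards, horizon = horizon,
                                 seed = stream_seed(seed, 3))
  eco <- simulate_economics(events, econ, seed = stream_seed(seed, 4))
  cohort <- cov
  cohort$strategy <- asg$strategy
  p <- as.data.frame(asg$propensity)
  names(p) <- paste0("true_p_", names(p))
  cohort <- cbind(cohort, p)
  list(cohort = cohort, events = events,
       costs = eco$costs, utilities = eco$utilities)
}

#' Write / read a cohort as CSV files
#'
#' Fixed schemas: `cohort.csv`, `events.csv` (times rounded to 2 decimals),
#' `costs.csv`, `utilities.csv`. [read_cohort()] round-trips what
#' [write_cohort()] wrote.
#'
#' @param tables list as returned by [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- tables$events
  ev$t_exit_l1 <- round(ev$t_exit_l1, 2)
  ev$t_l2_sojourn <- round(ev$t_l2_sojourn, 2)
  utils::write.csv(tables$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(tables$costs, file.path(dir, "costs.csv"), row.names = FALSE)
  utils::write.csv(tables$utilities, file.path(dir, "utilities.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f, col = NA) utils::read.csv(file.path(dir, f),
                                              stringsAsFactors = FALSE,
                                              colClasses = col,
                                              check.names = FALSE)
  list(cohort = rd("cohort.csv"),
       events = rd("events.csv",
                   c(t_exit_l1 = "numeric", t_l2_sojourn = "numeric",
                     exit_l1_cause = "character", l2_status = "character")),
       costs = rd("costs.csv", c(line = "character")),
       utilities = rd("utilities.csv", c(line = "character")))
}
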