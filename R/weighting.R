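#' Propensity model specification
#'
#' Tuning parameters for the gradient-boosted multinomial propensity model.
#' The boosting iteration count is not fixed in advance: candidate counts on a
#' grid (every `grid_step` trees up to `max_trees`) are scored by the balance
#' stop-metric (mean absolute standardized mean difference across covariates
#' and strategy-vs-pooled comparisons under the implied ATE weights) and the
#' minimizer is kept.
#'
#' @param max_trees maximum boosting iterations (>= 1)
#' @param shrinkage learning rate in (0, 1]
#' @param interaction_depth tree depth
#' @param grid_step iteration-grid spacing for the stop metric
#' @return object of class `propensity_spec`
#' @export
propensity_spec <- function(max_trees = 600L, shrinkage = 0.01,
                            interaction_depth = 2L, grid_step = 100L) {
  assert_that(max_trees >= 1, "max_trees must be >= 1")
  assert_that(shrinkage > 0 && shrinkage <= 1, "shrinkage must be in (0,1]")
  assert_that(interaction_depth >= 1 && grid_step >= 1,
              "interaction_depth and grid_step must be >= 1")
  structure(list(max_trees = as.integer(max_trees), shrinkage = shrinkage,
                 interaction_depth = as.integer(interaction_depth),
                 grid_step = as.integer(grid_step), estimand = "ATE"),
            class = "propensity_spec")
}

#' Standardized mean difference between two groups
#'
#' |difference in (weighted) group means| divided by the unweighted
#' full-sample standard deviation (population form, so for a 0/1 covariate the
#' denominator is sqrt(p(1-p)) of the full-sample proportion). The stable,
#' weight-free denominator makes SMDs comparable across boosting iterations.
#'
#' @param x numeric covariate vector
#' @param group_mask logical; TRUE = first group, FALSE = second group
#' @param weights optional nonnegative weights (default unit)
#' @return nonnegative SMD; `Inf` when the pooled SD is zero but the means
#'   differ; 0 when both are degenerate and equal
#' @export
standardized_mean_difference <- function(x, group_mask, weights = NULL) {
  weights <- weights %||% rep(1, length(x))
  assert_that(any(group_mask) && any(!group_mask), "both groups must be non-empty")
  m1 <- wmean(x[group_mask], weights[group_mask])
  m2 <- wmean(x[!group_mask], weights[!group_mask])
  s <- wsd_pop(x, rep(1, length(x)))
  d <- abs(m1 - m2)
  if (s == 0) return(if (d == 0) 0 else Inf)
  d / s
}

# strategy-vs-pooled SMD used by balance reports: weighted strategy-group mean
# against the unweighted full-sample mean (the ATE target population), over
# the unweighted full-sample SD
smd_vs_pooled <- function(x, in_group, weights) {
  s <- wsd_pop(x, rep(1, length(x)))
  d <- abs(wmean(x[in_group], weights[in_group]) - mean(x))
  if (s == 0) return(if (d == 0) 0 else Inf)
  d / s
}

# balance table across all expanded covariates and strategies
balance_table <- function(X, labels, weights) {
  strategies <- sort(unique(labels))
  out <- expand.grid(covariate = colnames(X), comparison = strategies,
                     stringsAsFactors = FALSE)
  out$smd <- mapply(function(cv, s) {
    smd_vs_pooled(X[, cv], labels == s, weights)
  }, out$covariate, out$comparison)
  out
}

#' Fit a gradient-boosted multinomial propensity model
#'
#' The multinomial model is realized as K one-vs-rest boosted logistic
#' classifiers (gradient-boosted trees) whose predicted probabilities are
#' renormalized per patient. The common iteration count is chosen on a grid to
#' minimize the mean absolute strategy-vs-pooled SMD of the implied inverse
#' probability weights — balance, not likelihood, is the stopping criterion.
#' If every expanded covariate is constant the propensities are the empirical
#' group shares (there is no information to boost on).
#'
#' @param covariates baseline covariate data.frame (no missing values)
#' @param labels strategy label per patient (>= 2 strategies, >= 2 patients each)
#' @param spec a [propensity_spec()]
#' @return object of class `propensity_fit`: `propensity` (row-stochastic
#'   n x K matrix), `balance` (per covariate x strategy: `smd_before`,
#'   `smd_after`), `selected_trees`, `grid` (iteration grid with its stop
#'   metric), `strategies`
#' @export
fit_propensity <- function(covariates, labels, spec = propensity_spec()) {
  assert_that(inherits(spec, "propensity_spec"), "spec must be a propensity_spec")
  strategies <- sort(unique(labels))
  assert_that(length(strategies) >= 2L, "need >= 2 strategies to estimate propensities")
  assert_that(all(table(labels) >= 2L), "each strategy needs >= 2 patients")
  X <- expand_covariates(covariates)
  assert_that(all(is.finite(X)), "covariates must be finite (no missing values)")
  n <- nrow(X); K <- length(strategies)
  shares <- as.numeric(table(factor(labels, strategies)) / n)

  bal_before <- balance_table(X, labels, rep(1, n))
  constant <- ncol(X) == 0L || all(apply(X, 2, stats::sd) == 0)
  if (constant) {
    p <- matrix(shares, n, K, byrow = TRUE, dimnames = list(NULL, strategies))
    bal_after <- balance_table(X, labels, compute_weights(p, labels)$weight)
    return(structure(list(propensity = p,
                          balance = merge_balance(bal_before, bal_after),
                          selected_trees = 0L,
                          grid = data.frame(trees = 0L,
                                            mean_abs_smd = mean(bal_after$smd)),
                          strategies = strategies),
                     class = "propensity_fit"))
  }

  fits <- lapply(strategies, function(s) {
    dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(labels == s))
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = spec$shrinkage,
                    max_depth = spec$interaction_depth, nthread = 1),
      data = dtrain, nrounds = spec$max_trees, verbose = 0)
  })
  # the grid includes 0 trees (intercept-only: empirical group shares), so
  # that under null confounding the balance criterion can refuse to boost
  grid <- unique(c(0L, seq(spec$grid_step, spec$max_trees, by = spec$grid_step),
                   spec$max_trees))
  prob_at <- function(ntree) {
    if (ntree == 0L) {
      p <- matrix(shares, n, K, byrow = TRUE, dimnames = list(NULL, strategies))
      return(p)
    }
    raw <- vapply(fits, function(f)
      stats::predict(f, X, iterationrange = c(1, ntree)), numeric(n))
    raw <- pmin(pmax(raw, 1e-6), 1 - 1e-6)
    p <- raw / rowSums(raw)
    colnames(p) <- strategies
    p
  }
  metric <- vapply(grid, function(nt) {
    p <- prob_at(nt)
    w <- compute_weights(p, labels)$weight
    mean(balance_table(X, labels, w)$smd)
  }, numeric(1))
  best <- grid[which.min(metric)]
  p <- prob_at(best)
  bal_after <- balance_table(X, labels, compute_weights(p, labels)$weight)
  structure(list(propensity = p,
                 balance = merge_balance(bal_before, bal_after),
                 selected_trees = best,
                 grid = data.frame(trees = grid, mean_abs_smd = metric),
                 strategies = strategies),
            class = "propensity_fit")
}

merge_balance <- function(before, after) {
  out <- before
  names(out)[names(out) == "smd"] <- "smd_before"
  out$smd_after <- after$smd
  out
}

#' Inverse probability of treatment weights
#'
#' ATE weights: each patient is weighted by the reciprocal of the estimated
#' probability of the strategy actually received, so that every strategy group
#' is reweighted to the pooled population. Optional symmetric truncation caps
#' weights at an empirical quantile; the untruncated weights are always
#' reported alongside.
#'
#' @param p row-stochastic propensity matrix, columns named by strategy
#' @param labels assigned strategy per patient (aligned with rows of `p`)
#' @param truncation_quantile optional quantile in (0, 1), e.g. 0.99
#' @return data.frame: `strategy`, `propensity_assigned`, `weight`
#'   (possibly truncated), `weight_untruncated`
#' @export
compute_weights <- function(p, labels, truncation_quantile = NULL) {
  assert_that(nrow(p) == length(labels), "labels must align with propensity rows")
  j <- match(labels, colnames(p))
  assert_that(!anyNA(j), "labels contain strategies absent from the propensity matrix")
  pa <- p[cbind(seq_along(labels), j)]
  bad <- which(pa <= 0)
  assert_that(length(bad) == 0L,
              paste("zero assigned propensity for patient(s):",
                    paste(utils::head(bad, 5), collapse = ", ")))
  w <- 1 / pa
  wt <- w
  if (!is.null(truncation_quantile)) {
    cap <- stats::quantile(w, truncation_quantile, names = FALSE)
    wt <- pmin(w, cap)
    message(sprintf("weights truncated at the %.3g quantile (cap %.3g)",
                    truncation_quantile, cap))
  }
  data.frame(strategy = labels, propensity_assigned = pa,
             weight = wt, weight_untruncated = w)
}
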