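#' Efficiency frontier by dominance analysis
#'
#' Points are sorted by cost (ties: higher effect first, then label). A
#' strategy is (strictly) dominated when another costs no more and yields no
#' less effect, with at least one strict inequality. With
#' `extended_dominance = TRUE`, strategies producing non-increasing sequential
#' ICERs along the cost-ordered frontier are additionally removed (extended
#' dominance). The default is strict dominance only.
#'
#' @param points data.frame with `label`, `cost` (EUR), `effect` (QALYs)
#' @param extended_dominance apply extended dominance (default FALSE)
#' @return object of class `frontier_result`: `points` (all points with a
#'   `status` column: `frontier`, `dominated` or `extendedly_dominated`) and
#'   `frontier` (the cost-ordered frontier members)
#' @export
build_frontier <- function(points, extended_dominance = FALSE) {
  assert_that(nrow(points) >= 1, "need at least one strategy point")
  assert_that(all(c("label", "cost", "effect") %in% names(points)),
              "points needs label, cost, effect")
  assert_that(all(is.finite(points$cost)) && all(is.finite(points$effect)),
              "costs and effects must be finite")
  pts <- points[order(points$cost, -points$effect, points$label), ]
  n <- nrow(pts)
  status <- rep("frontier", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dom <- pts$cost[j] <= pts$cost[i] && pts$effect[j] >= pts$effect[i] &&
        (pts$cost[j] < pts$cost[i] || pts$effect[j] > pts$effect[i])
      if (dom) { status[i] <- "dominated"; break }
    }
  }
  # duplicated points: identical (cost, effect) pairs are ties; keep the
  # first label on the frontier
  dup <- duplicated(pts[, c("cost", "effect")]) & status == "frontier"
  status[dup] <- "dominated"
  if (extended_dominance) {
    repeat {
      on <- which(status == "frontier")
      if (length(on) < 3) break
      dc <- diff(pts$cost[on]); de <- diff(pts$effect[on])
      icer <- dc / de
      bad <- which(diff(icer) <= 0)   # upstream ICER >= downstream
      if (!length(bad)) break
      status[on[bad[1] + 1L]] <- "extendedly_dominated"
    }
  }
  pts$status <- status
  structure(list(points = pts, frontier = pts[status == "frontier", ]),
            class = "frontier_result")
}

#' Sequential ICERs along a frontier
#'
#' Incremental cost-effectiveness ratios between consecutive cost-ordered
#' frontier members: delta cost / delta effect, reported rounded
#' half-away-from-zero to integer EUR/QALY. Deltas are computed at the
#' precision of the inputs (feed one-decimal QALYs and integer EUR to
#' reproduce published worked examples; full-precision pipeline outputs are
#' used as-is). A zero effect delta yields a tie (no ratio).
#'
#' @param frontier a [build_frontier()] result (or its `frontier` data.frame)
#' @return data.frame: `from`, `to`, `delta_cost`, `delta_effect`, `icer`
#'   (integer EUR/QALY, NA for ties), `note`
#' @export
sequential_icers <- function(frontier) {
  fr <- if (inherits(frontier, "frontier_result")) frontier$frontier else frontier
  if (nrow(fr) < 2) {
    return(data.frame(from = character(0), to = character(0),
                      delta_cost = numeric(0), delta_effect = numeric(0),
                      icer = numeric(0), note = character(0)))
  }
  dc <- diff(fr$cost)
  de <- round(diff(fr$effect), 10)   # kill fp noise in printed-precision deltas
  tie <- de == 0
  data.frame(from = fr$label[-nrow(fr)], to = fr$label[-1],
             delta_cost = dc, delta_effect = de,
             icer = ifelse(tie, NA_real_, round_half_away(dc / de)),
             note = ifelse(tie, "dominated-tie", ""))
}

#' Bootstrap specification
#'
#' @param replicates number of bootstrap replicates (default 1000)
#' @param seed integer seed for the replicate stream
#' @param level percentile confidence level (default 0.95)
#' @return object of class `bootstrap_spec`
#' @export
bootstrap_spec <- function(replicates = 1000L, seed = 1L, level = 0.95) {
  assert_that(replicates >= 1, "replicates must be >= 1")
  assert_that(level > 0 && level < 1, "level must be in (0,1)")
  structure(list(replicates = as.integer(replicates), seed = seed,
                 level = level), class = "bootstrap_spec")
}

#' Non-parametric bootstrap of cost-effectiveness outcomes
#'
#' Patients are resampled with replacement within strategy (preserving arm
#' sizes); `handle` re-runs the analysis pipeline on each resampled cohort
#' and returns a data.frame with `strategy`, `cost`, `qaly`. Replicate seeds
#' come from one stream, so doubling the replicate count reproduces the first
#' half. Failed replicates are skipped and logged; more than 10% failures
#' aborts.
#'
#' @param patients data.frame with `patient_id` and `strategy`
#' @param handle function(patient_ids, replicate_seed) -> data.frame with
#'   `strategy`, `cost`, `qaly`
#' @param spec a [bootstrap_spec()]
#' @return object of class `bootstrap_result`: `replicates` (long data.frame:
#'   `replicate`, `strategy`, `cost`, `qaly`), `ci` (per strategy percentile
#'   intervals), `n_failed`
#' @export
bootstrap_ce <- function(patients, handle, spec = bootstrap_spec()) {
  assert_that(inherits(spec, "bootstrap_spec"), "spec must be a bootstrap_spec")
  by_strat <- split(seq_len(nrow(patients)), patients$strategy)
  reps <- vector("list", spec$replicates)
  n_failed <- 0L
  for (b in seq_len(spec$replicates)) {
    set.seed(stream_seed(spec$seed, 5) + b)
    idx <- unlist(lapply(by_strat, function(i) sample(i, length(i), TRUE)),
                  use.names = FALSE)
    res <- tryCatch(handle(patients$patient_id[idx], stream_seed(spec$seed, 5) + b),
                    error = function(e) {
                      message(sprintf("replicate %d failed: %s", b,
                                      conditionMessage(e)))
                      NULL
                    })
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    res$replicate <- b
    reps[[b]] <- res
  }
  assert_that(n_failed <= 0.10 * spec$replicates,
              sprintf("bootstrap aborted: %d/%d replicates failed",
                      n_failed, spec$replicates))
  reps <- do.call(rbind, reps)
  alpha <- (1 - spec$level) / 2
  ci <- do.call(rbind, lapply(split(reps, reps$strategy), function(d) {
    data.frame(strategy = d$strategy[1],
               cost = mean(d$cost),
               cost_lo = stats::quantile(d$cost, alpha, names = FALSE),
               cost_hi = stats::quantile(d$cost, 1 - alpha, names = FALSE),
               qaly = mean(d$qaly),
               qaly_lo = stats::quantile(d$qaly, alpha, names = FALSE),
               qaly_hi = stats::quantile(d$qaly, 1 - alpha, names = FALSE))
  }))
  rownames(ci) <- NULL
  structure(list(replicates = reps[, c("replicate", "strategy", "cost", "qaly")],
                 ci = ci, n_failed = n_failed, level = spec$level),
            class = "bootstrap_result")
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability (across bootstrap
#' replicates) that each strategy maximizes net monetary benefit
#' NMB = lambda * effect - cost. Within-replicate ties are split equally.
#'
#' @param replicates long data.frame `replicate`, `strategy`, `cost`, `qaly`
#'   (e.g. `bootstrap_ce(...)$replicates`)
#' @param wtp_grid willingness-to-pay grid, EUR/QALY (default 0 to 1e6 in
#'   10,000-EUR steps)
#' @return data.frame: `wtp`, `strategy`, `probability` (summing to 1 per wtp)
#' @export
ceac <- function(replicates, wtp_grid = seq(0, 1e6, by = 1e4)) {
  strategies <- sort(unique(replicates$strategy))
  reps <- split(replicates, replicates$replicate)
  assert_that(all(vapply(reps, nrow, 1L) == length(strategies)),
              "each replicate must contain every strategy exactly once")
  cost <- vapply(reps, function(d) d$cost[match(strategies, d$strategy)],
                 numeric(length(strategies)))
  qaly <- vapply(reps, function(d) d$qaly[match(strategies, d$strategy)],
                 numeric(length(strategies)))
  out <- lapply(wtp_grid, function(l) {
    nmb <- l * qaly - cost                 # strategies x replicates
    best <- nmb == rep(apply(nmb, 2, max), each = length(strategies))
    p <- rowMeans(best / rep(colSums(best), each = length(strategies)))
    data.frame(wtp = l, strategy = strategies, probability = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
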