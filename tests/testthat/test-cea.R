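test_that("frontier matches an exhaustive dominance scan and is order-invariant", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(3:50, 1)
    pts <- data.frame(label = sprintf("s%02d", 1:n),
                      cost = round(runif(n, 1e5, 6e5)),
                      effect = round(runif(n, 0.5, 4), 1))
    fr <- build_frontier(pts)
    expect_identical(sort(fr$frontier$label), brute_force_frontier(pts))
    # permutation invariance
    perm <- pts[sample(n), ]
    fr2 <- build_frontier(perm)
    expect_identical(fr$frontier$label, fr2$frontier$label)
    # frontier costs and effects strictly increase
    expect_true(all(diff(fr$frontier$cost) > 0))
    expect_true(all(diff(fr$frontier$effect) > 0))
  }

  one <- build_frontier(data.frame(label = "only", cost = 1, effect = 1))
  expect_equal(nrow(one$frontier), 1L)
  expect_equal(nrow(sequential_icers(one)), 0L)
})

test_that("extended dominance removes strategies with non-increasing sequential ICERs", {
  wt <- data.frame(label = c("Anti-PD1", "Ipi+Nivo", "Ipilimumab", "Chemo"),
                   cost = c(178726, 351590, 190322, 151475),
                   effect = c(1.3, 1.6, 1.4, 1.1))
  off <- build_frontier(wt, extended_dominance = FALSE)
  expect_true(all(off$points$status == "frontier"))
  on <- build_frontier(wt, extended_dominance = TRUE)
  expect_equal(on$points$status[on$points$label == "Anti-PD1"],
               "extendedly_dominated")
  expect_equal(sum(on$points$status == "frontier"), 3L)
  # with extended dominance the remaining ICERs strictly increase
  ic <- sequential_icers(on)
  expect_true(all(diff(ic$icer) > 0))
})

test_that("sequential ICERs divide printed-precision deltas and round half away from zero", {
  fr <- data.frame(label = c("cheap", "dear"),
                   cost = c(375736, 502045), effect = c(2.5, 3.2))
  ic <- sequential_icers(fr)
  expect_equal(ic$delta_cost, 126309)
  expect_equal(ic$delta_effect, 0.7)
  expect_equal(ic$icer, 180441)

  # identical points: tie, no ratio
  tie <- sequential_icers(data.frame(label = c("x", "y"),
                                     cost = c(10, 20), effect = c(1, 1)))
  expect_true(is.na(tie$icer))
  expect_equal(tie$note, "dominated-tie")

  expect_equal(round_half_away(c(0.5, 1.5, -0.5, 2.4)), c(1, 2, -1, 2))
})

test_that("bootstrap replicates are seed-reproducible and extendable", {
  set.seed(1)
  pats <- data.frame(patient_id = 1:120,
                     strategy = rep(c("A", "B"), each = 60))
  vals <- stats::rnorm(120, mean = ifelse(pats$strategy == "A", 10, 20))
  handle <- function(ids, seed) {
    d <- data.frame(strategy = pats$strategy[match(ids, pats$patient_id)],
                    v = vals[match(ids, pats$patient_id)])
    out <- aggregate(v ~ strategy, d, mean)
    data.frame(strategy = out$strategy, cost = out$v, qaly = out$v / 10)
  }
  b1 <- bootstrap_ce(pats, handle, bootstrap_spec(40, seed = 3))
  b2 <- bootstrap_ce(pats, handle, bootstrap_spec(40, seed = 3))
  expect_identical(b1$replicates, b2$replicates)

  # doubling replicates reproduces the first half
  b3 <- bootstrap_ce(pats, handle, bootstrap_spec(80, seed = 3))
  expect_equal(b3$replicates[b3$replicates$replicate <= 40, ],
               b1$replicates)

  # single replicate: the CI collapses onto it
  b4 <- bootstrap_ce(pats, handle, bootstrap_spec(1, seed = 3))
  expect_equal(b4$ci$cost_lo, b4$ci$cost_hi)
  expect_equal(b4$ci$cost, b4$ci$cost_lo)

  # systematic failure aborts
  bad <- function(ids, seed) stop("boom")
  expect_error(suppressMessages(
    bootstrap_ce(pats, bad, bootstrap_spec(10, seed = 3))), "aborted")
})

test_that("acceptability curves are NMB probabilities that sum to one", {
  reps <- expand.grid(replicate = 1:50, strategy = c("A", "B"))
  # A strictly dominates B in every replicate
  reps$cost <- ifelse(reps$strategy == "A", 100, 200)
  reps$qaly <- ifelse(reps$strategy == "A", 2, 1)
  cc <- ceac(reps, wtp_grid = c(0, 5e4, 1e5))
  expect_true(all(cc$probability[cc$strategy == "A"] == 1))
  agg <- aggregate(probability ~ wtp, cc, sum)
  expect_lt(max(abs(agg$probability - 1)), 1e-9)

  # lambda = 0 ranks by lowest cost
  reps2 <- expand.grid(replicate = 1:50, strategy = c("A", "B"))
  reps2$cost <- ifelse(reps2$strategy == "A", 200, 100)
  reps2$qaly <- ifelse(reps2$strategy == "A", 2, 1)
  cc2 <- ceac(reps2, wtp_grid = 0)
  expect_equal(cc2$probability[cc2$strategy == "B"], 1)

  # symmetric cloud around equal NMB at lambda* = 100: probability ~ 0.5
  set.seed(12)
  eps <- rnorm(400)
  reps3 <- rbind(
    data.frame(replicate = 1:400, strategy = "A", cost = 0, qaly = 0),
    data.frame(replicate = 1:400, strategy = "B", cost = 100 + eps, qaly = 1))
  cc3 <- ceac(reps3, wtp_grid = 100)
  expect_lt(abs(cc3$probability[cc3$strategy == "B"] - 0.5), 0.07)

  # NMB ranking is invariant to adding a constant to all costs
  reps4 <- reps3
  reps4$cost <- reps4$cost + 500
  expect_equal(ceac(reps4, wtp_grid = 100)$probability,
               cc3$probability)
})
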