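#' Derive an independent per-stage random seed from a master seed
#'
#' All randomness in the package is driven by one integer master seed that is
#' expanded into per-operation streams with a fixed multiplicative mix, so that
#' changing e.g. the economics draws never perturbs the transition draws.
#' Stream order: 1 = covariates, 2 = assignment, 3 = transitions,
#' 4 = economics, 5 = bootstrap, 6 = microsimulation.
#'
#' @param seed master integer seed
#' @param stream positive integer stream index
#' @return an integer seed in `[0, 2^31 - 1)`
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 1)
  # Lehmer-style mix kept inside 32-bit integer range
  as.integer((abs(seed) * 48271 + stream * 7919) %% 2147483629)
}

#' Round half away from zero
#'
#' Reporting rule for ICERs: ratios are rounded to integer EUR/QALY with ties
#' going away from zero (so 0.5 -> 1, -0.5 -> -1), unlike base `round()`'s
#' round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal digits to keep (default 0)
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# weighted mean / SD helpers; SD uses the population (divide-by-n) form so
# that for a 0/1 covariate the full-sample SD equals sqrt(p * (1 - p))
wmean <- function(x, w) sum(x * w) / sum(w)

wsd_pop <- function(x, w) {
  m <- wmean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

# truncated-normal draw on [lo, hi] by inverse-CDF; vectorized over mean/sd;
# sd = 0 degenerates to the mean exactly
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0L) return(numeric(0))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    a <- stats::pnorm(lo, mean[pos], sd[pos])
    b <- stats::pnorm(hi, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), a, b)
    out[pos] <- pmin(pmax(stats::qnorm(u, mean[pos], sd[pos]), lo), hi)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
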