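#' Observed Hill number of order q
#'
#' `qD = (sum p_i^q)^(1/(1-q))`, with the q = 1 limit
#' `exp(-sum p_i log p_i)`. Order 0 is species richness, order 1 the
#' exponential of Shannon entropy, order 2 the inverse Simpson
#' concentration.
#'
#' @param p Relative abundances summing to 1 (zeros allowed and dropped).
#' @param q Diversity order, q >= 0.
#' @return The Hill number.
#' @export
hill_observed <- function(p, q) {
  if (q < 0) stop("q must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1")
  p <- p[p > 0]
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

# Abundance summaries used by the asymptotic estimators.
abund_stats <- function(counts) {
  counts <- counts[counts > 0]
  list(x = counts, n = sum(counts), s_obs = length(counts),
       f1 = sum(counts == 1), f2 = sum(counts == 2))
}

#' Asymptotic Hill number of order q (Chao-type estimators)
#'
#' q = 0: Chao1 (`S_obs + ((n-1)/n) f1^2 / (2 f2)`, bias-corrected form
#' `f1 (f1 - 1) / 2` when `f2 = 0`). q = 1: the entropy estimator with
#' rare-species correction `A = 2 f2 / ((n-1) f1 + 2 f2)` (continuation
#' `A = 2 / ((n-1)(f1-1) + 2)` when `f2 = 0, f1 > 0`; `A = 1` when
#' `f1 = 0`), exponentiated. q = 2: the minimum-variance unbiased inverse
#' Simpson `1 / sum(x_i (x_i - 1) / (n (n - 1)))`.
#'
#' @param counts Positive integer abundances per taxon.
#' @param q Order, one of 0, 1, 2.
#' @return The asymptotic diversity estimate (NaN with a warning when all
#'   taxa are singletons at q = 2).
#' @export
hill_asymptotic <- function(counts, q) {
  st <- abund_stats(counts)
  n <- st$n
  if (n < 2) stop("need total count >= 2")
  if (q == 0) {
    if (st$f2 > 0) return(st$s_obs + (n - 1) / n * st$f1^2 / (2 * st$f2))
    return(st$s_obs + (n - 1) / n * st$f1 * (st$f1 - 1) / 2)
  }
  if (q == 1) {
    x <- st$x
    h <- sum(x / n * (digamma(n) - digamma(x)))
    if (st$f1 > 0) {
      A <- if (st$f2 > 0) 2 * st$f2 / ((n - 1) * st$f1 + 2 * st$f2)
           else 2 / ((n - 1) * (st$f1 - 1) + 2)
      r <- seq_len(n - 1)
      h <- h + st$f1 / n * (1 - A)^(1 - n) * (-log(A) - sum((1 - A)^r / r))
    }
    return(exp(h))
  }
  if (q == 2) {
    denom <- sum(st$x * (st$x - 1)) / (n * (n - 1))
    if (denom == 0) {
      warning("all taxa are singletons; asymptotic order-2 diversity undefined")
      return(NaN)
    }
    return(1 / denom)
  }
  stop("q must be 0, 1 or 2 for asymptotic estimation")
}

#' Estimated sample coverage
#'
#' `C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`: the estimated
#' probability that the next sampled individual belongs to an already-seen
#' taxon.
#'
#' @param counts Positive integer abundances.
#' @return Coverage in \[0, 1\].
#' @export
sample_coverage <- function(counts) {
  st <- abund_stats(counts)
  n <- st$n
  if (n < 1) stop("need at least one count")
  if (st$f1 == 0) return(1)
  denom <- (n - 1) * st$f1 + 2 * st$f2
  if (denom == 0) return(1 - st$f1 / n)
  1 - st$f1 / n * ((n - 1) * st$f1 / denom)
}

#' Percentile bootstrap confidence interval for an asymptotic Hill number
#'
#' Resamples `n` individuals from the coverage-adjusted abundance model
#' (observed taxa down-weighted to the estimated coverage, plus the
#' estimated number of unseen taxa sharing the remaining probability),
#' recomputes the estimator per replicate and returns the 2.5/97.5
#' percentiles. Deterministic under `seed`.
#'
#' @param counts Positive integer abundances.
#' @param q Order (0, 1 or 2).
#' @param n_boot Number of replicates (warning below 20).
#' @param seed Integer seed.
#' @return Named vector `c(ci_low, ci_high)`.
#' @export
hill_bootstrap_ci <- function(counts, q, n_boot = 200L, seed = 1L) {
  st <- abund_stats(counts)
  n <- st$n
  if (n < 2) stop("need total count >= 2")
  if (n_boot < 20L) warning("fewer than 20 bootstrap replicates")
  if (st$s_obs == 1L) {
    v <- hill_asymptotic(counts, q)
    return(c(ci_low = v, ci_high = v))
  }
  chat <- sample_coverage(counts)
  f0 <- max(0, round(hill_asymptotic(counts, 0) - st$s_obs))
  p_obs <- st$x / n
  lambda <- if (any(p_obs < 1)) {
    (1 - chat) / sum(p_obs * (1 - p_obs)^n)
  } else 0
  p_adj <- p_obs * (1 - lambda * (1 - p_obs)^n)
  p_unseen <- if (f0 > 0) rep((1 - sum(p_adj)) / f0, f0) else numeric(0)
  model_p <- c(p_adj, p_unseen)
  model_p <- pmax(model_p, 0)
  model_p <- model_p / sum(model_p)

  set.seed(seed)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    xb <- stats::rmultinom(1L, n, model_p)[, 1]
    xb <- xb[xb > 0]
    reps[b] <- if (sum(xb) >= 2) suppressWarnings(hill_asymptotic(xb, q)) else NA
  }
  qs <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  c(ci_low = qs[1], ci_high = qs[2])
}

#' Full Hill-number profile for one assemblage
#'
#' @param counts Positive integer abundances.
#' @param orders Diversity orders (default 0, 1, 2).
#' @param n_boot Bootstrap replicates for the CIs (0 skips CIs).
#' @param seed Seed for the bootstrap.
#' @return Data frame: q, observed, asymptotic, ci_low, ci_high, coverage.
#' @export
hill_profile <- function(counts, orders = c(0, 1, 2), n_boot = 200L, seed = 1L) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  rows <- lapply(orders, function(q) {
    ci <- if (n_boot > 0L) hill_bootstrap_ci(counts, q, n_boot, derive_seed(seed, q + 1))
          else c(ci_low = NA_real_, ci_high = NA_real_)
    data.frame(q = q,
               observed = hill_observed(p, q),
               asymptotic = suppressWarnings(hill_asymptotic(counts, q)),
               ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
               coverage = sample_coverage(counts))
  })
  do.call(rbind, rows)
}
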