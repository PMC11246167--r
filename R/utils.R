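# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a user seed and a counter, so that
# replicate j (or sample j) is reproducible independently of j - 1.
# Kept below 2^31 - 1; constants are the MINSTD multiplier and the Knuth
# multiplicative hash. Exact in double precision for counters < ~2^42.
derive_seed <- function(seed, counter) {
  if (is.null(seed)) return(NULL)
  s <- as.double(seed) %% 2147483647
  as.integer((s * 48271 + 2654435761 * as.double(counter)) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; with a NULL
# seed the expression just consumes the current RNG stream (so callers already
# running inside a seeded context stay fully reproducible).
with_rng <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(as.double(seed) %% 2147483647), code)
  }
}

# Closed-form univariate OLS of y on x: slope, its standard error/variance and
# the two-sided t-test of slope = 0. Equivalent to lm(y ~ x) but ~50x faster,
# which matters inside the simulation loops; equivalence is covered by tests.
ols_assoc <- function(y, x) {
  keep <- stats::complete.cases(y, x)
  y <- as.numeric(y)[keep]
  x <- as.numeric(x)[keep]
  n <- length(y)
  if (n < 3) {
    stop("association test needs at least 3 complete (alpha, covariate) pairs")
  }
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) {
    stop("covariate is constant; the association is undefined")
  }
  my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sxx
  res <- y - my - slope * (x - mx)
  df <- n - 2
  v <- sum(res^2) / df / sxx
  if (v > 0) {
    tval <- slope / sqrt(v)
    p <- 2 * stats::pt(-abs(tval), df)
  } else {
    tval <- NA_real_
    p <- NA_real_
  }
  list(estimate = slope, se = sqrt(v), V = v, statistic = tval,
       p_value = p, n = n, df = df, degenerate = !(v > 0))
}

# Recode a covariate as numeric: numeric/logical pass through; a two-level
# factor/character is coded 0/1 by sorted level order (second level = 1).
covariate_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.logical(x)) return(as.numeric(x))
  lv <- sort(unique(as.character(x[!is.na(x)])))
  if (length(lv) != 2) {
    stop("categorical covariates must have exactly two levels, got ",
         length(lv))
  }
  out <- as.numeric(as.character(x) == lv[2])
  out[is.na(x)] <- NA_real_
  out
}
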