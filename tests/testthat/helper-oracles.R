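# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's closed-form code paths.

# 1-D trapezoid integration of the fixed-precision marginal over a flat
# intercept (p = 1 design).
oracle_lml_flat_intercept <- function(y, tau, lo = -10, hi = 12, step = 1e-3) {
  b0 <- seq(lo, hi, by = step)
  n <- length(y)
  ll <- vapply(b0, function(b) {
    sum(dnorm(y, mean = b, sd = 1 / sqrt(tau), log = TRUE))
  }, numeric(1))
  m <- max(ll)
  m + log(sum(exp(ll - m)) * step)
}

# 2-D grid integration: flat intercept + one N(0, v) slope coefficient.
oracle_lml_two_coef <- function(y, x, tau, v = 1000, n_grid = 801) {
  # centre the grid on the OLS solution, +- 10 noise SDs per coefficient
  fit <- lm.fit(cbind(1, x), y)
  sd0 <- 10 * max(1 / sqrt(tau), 1)
  b0 <- seq(fit$coefficients[1] - sd0, fit$coefficients[1] + sd0,
    length.out = n_grid
  )
  b1 <- seq(fit$coefficients[2] - sd0, fit$coefficients[2] + sd0,
    length.out = n_grid
  )
  n <- length(y)
  ll <- outer(b0, b1, function(a, b) {
    res2 <- vapply(seq_along(a), function(i) {
      sum((y - a[i] - b[i] * x)^2)
    }, numeric(1))
    -n / 2 * log(2 * pi) + n / 2 * log(tau) - tau / 2 * res2 -
      0.5 * log(2 * pi * v) - b^2 / (2 * v)
  })
  m <- max(ll)
  m + log(sum(exp(ll - m))) +
    log(b0[2] - b0[1]) + log(b1[2] - b1[1])
}

# Posterior mean of (intercept, slope) by the same 2-D grid.
oracle_post_mean_two_coef <- function(y, x, tau, v = 1000, n_grid = 801) {
  fit <- lm.fit(cbind(1, x), y)
  sd0 <- 10 * max(1 / sqrt(tau), 1)
  b0 <- seq(fit$coefficients[1] - sd0, fit$coefficients[1] + sd0,
    length.out = n_grid
  )
  b1 <- seq(fit$coefficients[2] - sd0, fit$coefficients[2] + sd0,
    length.out = n_grid
  )
  n <- length(y)
  ll <- outer(b0, b1, function(a, b) {
    res2 <- vapply(seq_along(a), function(i) {
      sum((y - a[i] - b[i] * x)^2)
    }, numeric(1))
    n / 2 * log(tau) - tau / 2 * res2 - b^2 / (2 * v)
  })
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  c(
    intercept = sum(rowSums(w) * b0),
    slope = sum(colSums(w) * b1)
  )
}

# Grid inversion of a dose-response curve at 1 mg/kg resolution.
oracle_dose_at_score <- function(curve, score, resolution = 1) {
  d <- seq(min(curve$dose), max(curve$dose), by = resolution)
  s <- score_at_dose(curve, d)
  d[which.min(abs(s - score))]
}
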