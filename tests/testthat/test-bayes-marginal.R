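intercept_only <- function(n) {
  matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
}

test_that("flat-intercept marginal matches its closed form and 1-D oracle", {
  pr <- bms_prior()
  # n = 1: the density integrates to exactly 1 over the flat intercept
  expect_equal(
    log_marginal_fixed_precision(0.7, intercept_only(1), pr, tau = 3), 0
  )
  expect_equal(
    log_marginal_fixed_precision(-4, intercept_only(1), pr, tau = 1e-4), 0
  )

  # y = (0,1,2), tau = 1: closed form log[(2pi)^-1 3^-1/2 e^-1]
  y <- c(0, 1, 2)
  val <- log_marginal_fixed_precision(y, intercept_only(3), pr, tau = 1)
  expect_equal(val, -log(2 * pi) - log(3) / 2 - 1)
  expect_equal(val, oracle_lml_flat_intercept(y, tau = 1), tolerance = 1e-8)
})

test_that("closed form agrees with brute-force quadrature for n <= 8, p <= 2", {
  pr <- bms_prior()
  set.seed(41)
  for (case in 1:4) {
    n <- sample(3:8, 1)
    y <- round(rnorm(n, 2, 1.5), 3)
    tau <- c(0.5, 1, 2, 0.8)[case]
    # p = 1, flat intercept
    cf1 <- log_marginal_fixed_precision(y, intercept_only(n), pr, tau)
    or1 <- oracle_lml_flat_intercept(y, tau, lo = -30, hi = 30, step = 2e-3)
    expect_equal(cf1, or1, tolerance = 1e-5)
    # p = 2, flat intercept + Gaussian slope
    x <- seq(0, n - 1)
    X <- cbind(intercept_only(n), rapeseed_oil = x)
    cf2 <- log_marginal_fixed_precision(y, X, pr, tau)
    or2 <- oracle_lml_two_coef(y, x, tau)
    expect_equal(cf2, or2, tolerance = 1e-5)
  }
})

test_that("flat intercept is the large-variance limit of a Gaussian one", {
  y <- c(2.6, 2.9, 2.6, 2.8, 2.7, 2.9)
  X <- cbind(intercept_only(6), rapeseed_oil = c(0, 5, 9, 14, 19, 24))
  flat <- log_marginal_fixed_precision(y, X, bms_prior(), tau = 2)
  wide <- log_marginal_fixed_precision(
    y, X, bms_prior(intercept = "gaussian", intercept_variance = 1e8),
    tau = 2
  )
  # the improper limit drops the intercept's prior mass term log(2*pi*v)/2,
  # a constant shared by every candidate model ...
  expect_equal(flat, wide + log(2 * pi * 1e8) / 2, tolerance = 1e-4)

  # ... so posterior model probabilities agree between the two conventions
  tab <- trial_fixture("organ_lipid")
  p_flat <- bms(tab, "OSIPI")$probabilities
  p_wide <- bms(tab, "OSIPI",
    prior = bms_prior(intercept = "gaussian", intercept_variance = 1e8)
  )$probabilities
  expect_equal(p_flat, p_wide, tolerance = 1e-4)
})

test_that("precision quadrature self-converges and matches Monte Carlo", {
  tab <- trial_fixture("organ_lipid")
  dm <- design_matrix(tab, "OSIPI", "m3")
  q51 <- log_marginal(dm$y, dm$X, nodes = 51)
  q201 <- log_marginal(dm$y, dm$X, nodes = 201)
  expect_lt(abs(q51 - q201), 1e-6)

  # Monte Carlo over the gamma precision prior, intercept-only model,
  # small-scale response so a usable share of prior draws contributes
  y <- c(0.11, 0.25, 0.31)
  pr <- bms_prior()
  quad <- log_marginal(y, intercept_only(3), pr)
  set.seed(2024)
  taus <- rgamma(1e6, shape = pr$precision_shape, rate = pr$precision_rate)
  # vectorized closed form of the flat-intercept fixed-tau marginal
  n <- 3
  S <- sum((y - mean(y))^2)
  lm_tau <- -(n - 1) / 2 * log(2 * pi) + (n - 1) / 2 * log(taus) -
    log(n) / 2 - taus * S / 2
  vals <- exp(lm_tau)
  mc <- mean(vals)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(exp(quad) - mc), 3 * se)
})

test_that("marginal likelihood is exchangeable in observation order", {
  tab <- trial_fixture("organ_lipid")
  dm <- design_matrix(tab, "PI_lipid", "m5")
  base <- log_marginal(dm$y, dm$X)
  set.seed(5)
  for (i in 1:5) {
    perm <- sample(12)
    expect_equal(log_marginal(dm$y[perm], dm$X[perm, , drop = FALSE]), base,
      tolerance = 1e-12
    )
  }
})

test_that("degenerate integrations raise errors rather than NaN", {
  # fewer observations than coefficients
  expect_error(
    log_marginal_fixed_precision(1, cbind(intercept_only(1), x = 2),
      bms_prior(),
      tau = 1
    ),
    "rows"
  )
  # flat prior on a column of zeros: infinite flat direction
  X <- cbind(matrix(0, 3, 1, dimnames = list(NULL, "(Intercept)")))
  expect_error(
    log_marginal_fixed_precision(c(1, 2, 3), X, bms_prior(), tau = 1),
    "degenera"
  )
})

test_that("design_matrix builds the stated covariate sets and units", {
  tab <- trial_fixture("organ_lipid")
  dm5 <- design_matrix(tab, "OSIPI", "m5")
  expect_equal(dim(dm5$X), c(12, 4))
  expect_equal(
    colnames(dm5$X),
    c("(Intercept)", "size", "rapeseed_oil", "size:rapeseed_oil")
  )
  expect_equal(
    dm5$X[, "size:rapeseed_oil"],
    dm5$X[, "size"] * dm5$X[, "rapeseed_oil"]
  )
  # raw units: oil column carries the percent values as-is
  expect_setequal(unique(dm5$X[, "rapeseed_oil"]), c(0, 5, 9, 14, 19, 24))

  dm1 <- design_matrix(tab, "OSIPI", "m1")
  expect_equal(dm1$X, matrix(1, 12, 1, dimnames = list(NULL, "(Intercept)")))

  single <- sim_pen_responses("m1", beta = c(intercept = 1), sigma = 0.2,
    sizes = 0, seed = 1
  )
  expect_error(design_matrix(single, "y", "m3"), "degenerate")
})
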