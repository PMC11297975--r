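#' Prior specification for Bayesian linear-model selection
#'
#' Priors follow the convention of weakly informative Gaussian regression:
#' fixed effects get independent \eqn{N(0, v)} priors (default \eqn{v = 1000}),
#' the intercept gets a completely flat (improper) prior by default, the
#' residual precision \eqn{\tau = 1/\sigma^2} gets a gamma prior (default
#' shape 1, rate 5e-5), and the five candidate models get a uniform prior.
#'
#' @param fixed_effect_variance Prior variance of the non-intercept
#'   coefficients. Default 1000.
#' @param intercept Either \code{"flat"} (improper, integrated against
#'   Lebesgue measure) or \code{"gaussian"}.
#' @param intercept_variance Prior variance of the intercept when
#'   \code{intercept = "gaussian"}; ignored otherwise.
#' @param precision_shape,precision_rate Shape and rate of the gamma prior on
#'   the residual precision \eqn{\tau}.
#' @param model_prior Probability vector over the five models m1..m5; must sum
#'   to 1. Default uniform.
#' @param nodes Number of quadrature nodes for the deterministic integration
#'   over \eqn{\log\tau}. Default 51.
#' @return An object of class \code{"bms_prior"}.
#' @export
#' @examples
#' bms_prior()
#' bms_prior(precision_rate = 5e-4)
bms_prior <- function(fixed_effect_variance = 1000,
                      intercept = c("flat", "gaussian"),
                      intercept_variance = 1000,
                      precision_shape = 1,
                      precision_rate = 5e-5,
                      model_prior = rep(1 / 5, 5),
                      nodes = 51L) {
  intercept <- match.arg(intercept)
  stopifnot(
    is.numeric(fixed_effect_variance), fixed_effect_variance > 0,
    is.numeric(intercept_variance), intercept_variance > 0,
    precision_shape > 0, precision_rate > 0,
    length(model_prior) == 5, all(model_prior >= 0),
    nodes >= 5
  )
  if (abs(sum(model_prior) - 1) > 1e-8) {
    stop("`model_prior` must sum to 1", call. = FALSE)
  }
  structure(
    list(
      fixed_effect_variance = fixed_effect_variance,
      intercept = intercept,
      intercept_variance = intercept_variance,
      precision_shape = precision_shape,
      precision_rate = precision_rate,
      model_prior = model_prior / sum(model_prior),
      nodes = as.integer(nodes)
    ),
    class = "bms_prior"
  )
}

# Covariate sets of the five nested hypotheses.
.bms_models <- c("m1", "m2", "m3", "m4", "m5")

.model_terms <- function(model) {
  switch(model,
    m1 = character(0),
    m2 = "rapeseed_oil",
    m3 = "size",
    m4 = c("size", "rapeseed_oil"),
    m5 = c("size", "rapeseed_oil", "size:rapeseed_oil"),
    stop("unknown model '", model, "' (expected m1..m5)", call. = FALSE)
  )
}

#' Design matrix for one of the five model hypotheses
#'
#' Builds the response vector and covariate matrix for a candidate model.
#' Columns are ordered intercept, size, rapeseed oil, size-by-oil interaction
#' (restricted to the model's covariate set); size is coded 0/1 (small/large)
#' and rapeseed oil is kept in raw percent units, with no standardization.
#'
#' @param data A pen table (see [pen_table()]) or plain data frame with
#'   columns \code{size}, \code{rapeseed_oil}, and the response.
#' @param response Name of the response column.
#' @param model One of \code{"m1"}..\code{"m5"}: intercept only; + oil;
#'   + size; + size + oil; + size + oil + interaction.
#' @return List with \code{y} (response vector) and \code{X} (model matrix).
#' @export
#' @examples
#' tab <- trial_fixture("organ_lipid")
#' dm <- design_matrix(tab, "OSIPI", "m5")
#' dim(dm$X)
design_matrix <- function(data, response, model = "m5") {
  data <- as.data.frame(data)
  if (!response %in% names(data)) {
    stop("response '", response, "' not found in data", call. = FALSE)
  }
  y <- data[[response]]
  if (!is.numeric(y) || anyNA(y)) {
    stop("response '", response, "' must be numeric and complete",
      call. = FALSE
    )
  }
  terms <- .model_terms(model)
  n <- length(y)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (tm in terms) {
    col <- if (tm == "size:rapeseed_oil") {
      data$size * data$rapeseed_oil
    } else {
      data[[tm]]
    }
    if (is.null(col)) stop("column '", tm, "' missing", call. = FALSE)
    if (stats::sd(col) == 0) {
      stop("degenerate design: covariate '", tm, "' is constant, required by ",
        model,
        call. = FALSE
      )
    }
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- tm
  }
  list(y = as.numeric(y), X = X)
}

# Prior precision contributions per column: 0 for a flat intercept, 1/v else.
.prior_diag <- function(X, prior) {
  p <- ncol(X)
  d <- rep(1 / prior$fixed_effect_variance, p)
  if (colnames(X)[1] == "(Intercept)") {
    d[1] <- if (prior$intercept == "flat") 0 else 1 / prior$intercept_variance
  }
  d
}

#' Log marginal likelihood at fixed residual precision
#'
#' Closed form of \eqn{\log \int N(y \mid X\beta, \tau^{-1} I)\, p(\beta)\,
#' d\beta} for Gaussian coefficient priors; a flat intercept is handled as
#' integration against Lebesgue measure (the infinite-variance limit).
#'
#' @param y Response vector.
#' @param X Covariate matrix (first column the intercept).
#' @param prior A [bms_prior()].
#' @param tau Residual precision, \eqn{\tau > 0}.
#' @return The log marginal likelihood (a scalar).
#' @export
#' @examples
#' # A flat intercept integrates the n = 1 density to exactly 1:
#' log_marginal_fixed_precision(0.7, matrix(1, 1, 1,
#'   dimnames = list(NULL, "(Intercept)")), bms_prior(), tau = 3)
log_marginal_fixed_precision <- function(y, X, prior = bms_prior(), tau) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || n < p) {
    stop("need rows(X) == length(y) >= ncol(X)", call. = FALSE)
  }
  d <- .prior_diag(X, prior)
  A <- tau * crossprod(X) + diag(d, p)
  R <- tryCatch(chol(A), error = function(e) {
    stop("numerical degeneracy: posterior precision matrix is singular",
      call. = FALSE
    )
  })
  b <- tau * crossprod(X, y)
  z <- backsolve(R, b, transpose = TRUE)
  logdetA <- 2 * sum(log(diag(R)))
  n_gauss <- sum(d > 0)
  -n / 2 * log(2 * pi) + n / 2 * log(tau) -
    sum(log(2 * pi / d[d > 0])) / 2 +
    p / 2 * log(2 * pi) - logdetA / 2 +
    sum(z^2) / 2 - tau * sum(y^2) / 2
}

# Conditional posterior moments of beta given tau: mean (A^-1 b) and
# covariance (A^-1), plus the fixed-tau log marginal, in one pass.
.posterior_moments_fixed_tau <- function(y, X, prior, tau) {
  n <- length(y)
  p <- ncol(X)
  d <- .prior_diag(X, prior)
  A <- tau * crossprod(X) + diag(d, p)
  R <- chol(A)
  b <- tau * crossprod(X, y)
  z <- backsolve(R, b, transpose = TRUE)
  mu <- backsolve(R, z)
  Sigma <- chol2inv(R)
  lml <- -n / 2 * log(2 * pi) + n / 2 * log(tau) -
    sum(log(2 * pi / d[d > 0])) / 2 +
    p / 2 * log(2 * pi) - 2 * sum(log(diag(R))) / 2 +
    sum(z^2) / 2 - tau * sum(y^2) / 2
  list(mu = drop(mu), Sigma = Sigma, lml = lml)
}

# Fast evaluator of h(u) = log p(y | tau = e^u) + log p(tau) + u, with the
# sufficient statistics precomputed once.
.make_log_integrand <- function(y, X, prior) {
  n <- length(y)
  p <- ncol(X)
  SXX <- crossprod(X)
  SXy <- crossprod(X, y)
  Syy <- sum(y^2)
  d <- .prior_diag(X, prior)
  D <- diag(d, p)
  prior_const <- -sum(log(2 * pi / d[d > 0])) / 2 + p / 2 * log(2 * pi) -
    n / 2 * log(2 * pi)
  a <- prior$precision_shape
  r <- prior$precision_rate
  gam_const <- a * log(r) - lgamma(a)
  function(u) {
    vapply(u, function(ui) {
      tau <- exp(ui)
      R <- tryCatch(chol(tau * SXX + D), error = function(e) NULL)
      if (is.null(R)) return(-Inf)
      z <- backsolve(R, tau * SXy, transpose = TRUE)
      prior_const + n / 2 * ui - sum(log(diag(R))) +
        sum(z^2) / 2 - tau * Syy / 2 +
        gam_const + (a - 1) * ui - r * tau + ui
    }, numeric(1))
  }
}

# Deterministic quadrature over log tau. Returns the overall log marginal,
# the node locations (tau), and normalized log mixture weights for the
# conditional posteriors at each node.
.tau_quadrature <- function(y, X, prior, nodes = prior$nodes) {
  h <- .make_log_integrand(y, X, prior)
  # coarse bracket of the mode over a very wide precision range
  u0 <- seq(log(1e-12), log(1e12), length.out = 161)
  h0 <- h(u0)
  if (!any(is.finite(h0))) {
    stop("quadrature non-finite: integrand range [",
      min(h0), ", ", max(h0), "]",
      call. = FALSE
    )
  }
  i <- which.max(h0)
  lo <- u0[max(1, i - 1)]
  hi <- u0[min(length(u0), i + 1)]
  opt <- stats::optimize(h, c(lo, hi), maximum = TRUE, tol = 1e-10)
  u_hat <- opt$maximum
  # curvature-based width of the integrand in log-precision space
  eps <- 1e-3
  d2 <- (h(u_hat + eps) - 2 * opt$objective + h(u_hat - eps)) / eps^2
  s <- if (is.finite(d2) && d2 < 0) 1 / sqrt(-d2) else 1
  half <- 12 * s
  for (k in 1:6) { # widen until both tails are negligible
    if (max(h(u_hat - half), h(u_hat + half)) < opt$objective - 30) break
    half <- 2 * half
  }
  u <- seq(u_hat - half, u_hat + half, length.out = nodes)
  hu <- h(u)
  step <- u[2] - u[1]
  logw <- hu + log(step)
  logw[c(1, nodes)] <- logw[c(1, nodes)] + log(0.5)
  lml <- logsumexp(logw)
  if (!is.finite(lml)) {
    stop("quadrature non-finite: integrand range [",
      min(hu), ", ", max(hu), "]",
      call. = FALSE
    )
  }
  list(log_marginal = lml, u = u, tau = exp(u), logw = logw - lml)
}

#' Log marginal likelihood with the residual precision integrated out
#'
#' Integrates the fixed-precision marginal likelihood over the gamma prior on
#' \eqn{\tau} by deterministic trapezoid quadrature on a mode-centred,
#' curvature-scaled grid in \eqn{\log\tau}. Reproducible bit-for-bit for
#' fixed inputs.
#'
#' @inheritParams log_marginal_fixed_precision
#' @param nodes Number of quadrature nodes (default from the prior).
#' @return The log marginal likelihood (a scalar).
#' @export
#' @examples
#' dm <- design_matrix(trial_fixture("organ_lipid"), "OSIPI", "m3")
#' log_marginal(dm$y, dm$X)
log_marginal <- function(y, X, prior = bms_prior(), nodes = prior$nodes) {
  .tau_quadrature(y, X, prior, nodes)$log_marginal
}

#' Posterior model probabilities from log marginal likelihoods
#'
#' Renormalizes \eqn{p(y \mid m)\, p(m)} over the candidate models with
#' max-subtraction for numerical stability.
#'
#' @param lml Vector of log marginal likelihoods.
#' @param model_prior Prior probability vector over the same models
#'   (default uniform).
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' posterior_model_probs(c(0, -log(2)))
posterior_model_probs <- function(lml,
                                  model_prior = rep(1 / length(lml),
                                    length(lml)
                                  )) {
  if (any(!is.finite(lml))) {
    stop("non-finite log marginal likelihood", call. = FALSE)
  }
  stopifnot(length(model_prior) == length(lml), all(model_prior >= 0))
  lp <- lml + log(model_prior)
  w <- exp(lp - max(lp))
  p <- w / sum(w)
  names(p) <- names(lml)
  p
}

#' Bayes factor between two models
#'
#' @param lml_a,lml_b Log marginal likelihoods of the two models.
#' @return \eqn{\exp(\mathrm{lml}_a - \mathrm{lml}_b)} on the natural scale.
#' @export
#' @examples
#' bayes_factor(0, -log(10))
bayes_factor <- function(lml_a, lml_b) exp(lml_a - lml_b)

#' Kass-Raftery evidence category of a Bayes factor
#'
#' Half-open bins on the natural scale: \[1, 3.2) Negligible, \[3.2, 10)
#' Substantial, \[10, 100) Strong, \[100, Inf) Decisive. A Bayes factor
#' below 1 is mapped through its reciprocal, with the \code{"direction"}
#' attribute flagging the reversal.
#'
#' @param bf Non-negative Bayes factor(s).
#' @return Character vector of categories with a \code{"direction"} attribute
#'   (\code{"forward"} or \code{"reverse"} per element).
#' @export
#' @examples
#' evidence_category(c(1, 5, 50, 919))
evidence_category <- function(bf) {
  stopifnot(all(bf >= 0))
  direction <- ifelse(bf < 1, "reverse", "forward")
  b <- ifelse(bf < 1 & bf > 0, 1 / bf, bf)
  lab <- cut(b,
    breaks = c(1, 3.2, 10, 100, Inf),
    labels = c("Negligible", "Substantial", "Strong", "Decisive"),
    right = FALSE, include.lowest = TRUE
  )
  out <- as.character(lab)
  attr(out, "direction") <- direction
  out
}

#' Kolmogorov-Smirnov check of standardized residuals
#'
#' One-sample KS test of the supplied standardized residuals against the
#' standard normal distribution, with the p-value taken from the asymptotic
#' Kolmogorov distribution. The check passes when \eqn{p > 0.05}.
#'
#' @param z Numeric vector of standardized residuals.
#' @return List of class \code{"ks_check"}: \code{residuals},
#'   \code{ks_statistic}, \code{ks_p}, \code{pass}.
#' @export
#' @examples
#' ks_normal_check(qnorm((1:20 - 0.5) / 20))
ks_normal_check <- function(z) {
  if (length(z) < 1 || anyNA(z)) {
    stop("residuals must be non-empty and complete", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(z, "pnorm", exact = FALSE))
  structure(
    list(
      residuals = z,
      ks_statistic = unname(kt$statistic),
      ks_p = kt$p.value,
      pass = kt$p.value > 0.05
    ),
    class = "ks_check"
  )
}

# Full single-model posterior: quadrature cache plus conditional moments at
# every precision node. Used by bms(), posterior_line(), predict, residuals.
.fit_single_model <- function(y, X, prior, nodes = prior$nodes) {
  quad <- .tau_quadrature(y, X, prior, nodes)
  mom <- lapply(quad$tau, function(tau) {
    .posterior_moments_fixed_tau(y, X, prior, tau)
  })
  w <- exp(quad$logw)
  p <- ncol(X)
  mu_mat <- vapply(mom, `[[`, numeric(p), "mu")
  mu_mat <- matrix(mu_mat, nrow = p) # p x nodes
  beta_mean <- drop(mu_mat %*% w)
  names(beta_mean) <- colnames(X)
  sigma_mean <- sum(w / sqrt(quad$tau)) # posterior mean residual SD
  list(
    y = y, X = X, prior = prior, quad = quad, weights = w,
    moments = mom, beta_mean = beta_mean, sigma_mean = sigma_mean
  )
}

# Quantile of a finite mixture of normals, by root finding on the CDF.
.mix_norm_q <- function(prob, means, sds, weights) {
  cdf <- function(x) sum(weights * stats::pnorm(x, means, sds))
  lo <- min(means - 12 * sds)
  hi <- max(means + 12 * sds)
  vapply(prob, function(pp) {
    stats::uniroot(function(x) cdf(x) - pp, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

# Coefficient posterior summary (mixture over the precision grid).
.coef_table <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  p <- length(fit$beta_mean)
  out <- matrix(NA_real_, p, 1 + length(probs),
    dimnames = list(
      names(fit$beta_mean),
      c("mean", paste0("q", probs * 100))
    )
  )
  for (j in seq_len(p)) {
    means <- vapply(fit$moments, function(m) m$mu[j], numeric(1))
    sds <- vapply(fit$moments, function(m) sqrt(m$Sigma[j, j]), numeric(1))
    out[j, 1] <- fit$beta_mean[j]
    out[j, -1] <- .mix_norm_q(probs, means, sds, fit$weights)
  }
  out
}

# Rows of the prediction design for new (size, rapeseed_oil) points under the
# covariate set of `model`.
.newdata_matrix <- function(newdata, model) {
  newdata <- as.data.frame(newdata)
  if (is.null(newdata$size) || is.null(newdata$rapeseed_oil)) {
    stop("newdata needs columns 'size' and 'rapeseed_oil'", call. = FALSE)
  }
  if (!all(newdata$size %in% c(0, 1))) {
    stop("size must be coded 0 (small) or 1 (large)", call. = FALSE)
  }
  if (any(newdata$rapeseed_oil < 0 | newdata$rapeseed_oil > 100)) {
    stop("rapeseed_oil must be a percentage in [0, 100]", call. = FALSE)
  }
  terms <- .model_terms(model)
  X <- matrix(1, nrow(newdata), 1, dimnames = list(NULL, "(Intercept)"))
  for (tm in terms) {
    col <- if (tm == "size:rapeseed_oil") {
      newdata$size * newdata$rapeseed_oil
    } else {
      newdata[[tm]]
    }
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- tm
  }
  X
}

.predict_fit <- function(fit, Xnew, level = 0.95) {
  a <- (1 - level) / 2
  probs <- c(a, 0.5, 1 - a)
  n <- nrow(Xnew)
  out <- data.frame(
    fit = numeric(n), lwr = numeric(n), med = numeric(n), upr = numeric(n)
  )
  for (i in seq_len(n)) {
    x <- Xnew[i, ]
    means <- vapply(fit$moments, function(m) sum(x * m$mu), numeric(1))
    sds <- vapply(
      fit$moments,
      function(m) sqrt(drop(x %*% m$Sigma %*% x)), numeric(1)
    )
    q <- .mix_norm_q(probs, means, sds, fit$weights)
    out$fit[i] <- sum(fit$weights * means)
    out$lwr[i] <- q[1]
    out$med[i] <- q[2]
    out$upr[i] <- q[3]
  }
  out
}

#' Bayesian selection among the five pen-trial model hypotheses
#'
#' Fits the five nested Gaussian linear hypotheses (intercept only; + rapeseed
#' oil; + fish size; + both; + both with interaction) to one pen-level
#' response, computes exact marginal likelihoods (precision integrated by
#' deterministic quadrature), posterior model probabilities under the model
#' prior, the Bayes factor BF12 between the two most probable models with its
#' Kass-Raftery evidence category, and a Kolmogorov-Smirnov residual
#' diagnostic for the selected model.
#'
#' @param data A pen table or data frame with columns \code{size} (0/1),
#'   \code{rapeseed_oil} (percent) and the response.
#' @param response Name of the response column to analyse.
#' @param prior A [bms_prior()].
#' @param models Candidate models (default all of \code{"m1"}..\code{"m5"}).
#' @return Object of class \code{"bms"} with components \code{lml},
#'   \code{probabilities}, \code{best_model}, \code{second_model},
#'   \code{bf12}, \code{evidence}, \code{diagnostics}, and the cached
#'   posterior of the best model.
#' @seealso [posterior_line()], [predict.bms()], [residuals.bms()]
#' @export
#' @examples
#' fit <- bms(trial_fixture("organ_lipid"), "OSIPI")
#' fit
#' coef(fit)
bms <- function(data, response, prior = bms_prior(), models = .bms_models) {
  stopifnot(all(models %in% .bms_models))
  model_prior <- prior$model_prior[match(models, .bms_models)]
  model_prior <- model_prior / sum(model_prior)
  lml <- vapply(models, function(m) {
    dm <- tryCatch(design_matrix(data, response, m), error = function(e) {
      stop("variable '", response, "', model ", m, ": ", conditionMessage(e),
        call. = FALSE
      )
    })
    log_marginal(dm$y, dm$X, prior)
  }, numeric(1))
  probs <- posterior_model_probs(lml, model_prior)
  ord <- order(probs, seq_along(probs), decreasing = TRUE)
  # parsimony tie-break: on a tie within 1e-12 prefer the lower-index model
  if (length(ord) > 1 && abs(probs[ord[1]] - probs[ord[2]]) <= 1e-12) {
    ord[1:2] <- sort(ord[1:2])
  }
  best <- models[ord[1]]
  second <- if (length(models) > 1) models[ord[2]] else NA_character_
  bf12 <- if (is.na(second)) NA_real_ else bayes_factor(lml[best], lml[second])
  fit_best <- {
    dm <- design_matrix(data, response, best)
    .fit_single_model(dm$y, dm$X, prior)
  }
  z <- (fit_best$y - drop(fit_best$X %*% fit_best$beta_mean)) /
    fit_best$sigma_mean
  structure(
    list(
      response = response,
      data = as.data.frame(data),
      prior = prior,
      models = models,
      lml = lml,
      probabilities = probs,
      best_model = best,
      second_model = second,
      bf12 = unname(bf12),
      evidence = if (is.na(second)) NA_character_ else
        as.character(evidence_category(max(bf12, 1))),
      fit = fit_best,
      diagnostics = ks_normal_check(z)
    ),
    class = "bms"
  )
}

#' Posterior regression line for a single model hypothesis
#'
#' Coefficient posterior summaries and 95 percent credible bands for the
#' posterior mean at requested (size, rapeseed oil) points, for one fixed
#' model. The coefficient posterior is the mixture of the fixed-precision
#' Gaussian conditionals over the precision-quadrature weights.
#'
#' @inheritParams bms
#' @param model One of \code{"m1"}..\code{"m5"}.
#' @param newdata Data frame of query points with columns \code{size} and
#'   \code{rapeseed_oil}.
#' @param level Credible level for the bands (default 0.95).
#' @return List of class \code{"posterior_line"} with \code{model},
#'   \code{coefficients} (mean and 2.5/50/97.5 percent quantiles) and
#'   \code{predictions} (\code{fit}, \code{lwr}, \code{med}, \code{upr} per
#'   query point).
#' @export
#' @examples
#' pl <- posterior_line(trial_fixture("organ_lipid"), "OSIPI", "m3",
#'   newdata = data.frame(size = c(0, 1), rapeseed_oil = c(0, 0)))
#' pl$coefficients
posterior_line <- function(data, response, model, prior = bms_prior(),
                           newdata = NULL, level = 0.95) {
  dm <- design_matrix(data, response, model)
  fit <- .fit_single_model(dm$y, dm$X, prior)
  preds <- NULL
  if (!is.null(newdata)) {
    Xnew <- .newdata_matrix(newdata, model)
    preds <- cbind(as.data.frame(newdata), .predict_fit(fit, Xnew, level))
  }
  structure(
    list(
      model = model,
      response = response,
      level = level,
      coefficients = .coef_table(fit),
      predictions = preds,
      fit = fit
    ),
    class = "posterior_line"
  )
}

#' Are two credible intervals separated?
#'
#' Comparison rule used for pairwise contrasts: two estimates are treated as
#' clearly different when their credible intervals do not overlap.
#'
#' @param lwr1,upr1,lwr2,upr2 Interval bounds (vectorized).
#' @return Logical: \code{TRUE} where the intervals do not overlap.
#' @export
#' @examples
#' intervals_separated(0, 1, 2, 3)
intervals_separated <- function(lwr1, upr1, lwr2, upr2) {
  upr1 < lwr2 | upr2 < lwr1
}

#' KS residual diagnostic for one model hypothesis
#'
#' Fits the single model, standardizes residuals by the posterior-mean
#' coefficients and posterior-mean residual SD, and runs the one-sample
#' Kolmogorov-Smirnov check against the standard normal.
#'
#' @inheritParams posterior_line
#' @return A \code{"ks_check"} object (see [ks_normal_check()]).
#' @export
ks_residual_check <- function(data, response, model, prior = bms_prior()) {
  dm <- design_matrix(data, response, model)
  if (length(dm$y) < 3) {
    stop("insufficient data: need at least 3 observations", call. = FALSE)
  }
  fit <- .fit_single_model(dm$y, dm$X, prior)
  z <- (fit$y - drop(fit$X %*% fit$beta_mean)) / fit$sigma_mean
  ks_normal_check(z)
}

#' @export
print.bms <- function(x, digits = 3, ...) {
  cat("Bayesian model selection for '", x$response, "' (",
    length(x$fit$y), " pens)\n",
    sep = ""
  )
  tab <- data.frame(
    log_marginal = round(x$lml, digits),
    probability = round(x$probabilities, digits)
  )
  print(tab)
  cat(
    "Best model: ", x$best_model,
    " (p = ", format(x$probabilities[x$best_model], digits = digits), ")",
    "; BF12 = ", format(x$bf12, digits = digits),
    " [", x$evidence, "]\n",
    sep = ""
  )
  cat("KS residual check: D = ",
    format(x$diagnostics$ks_statistic, digits = digits),
    ", p = ", format(x$diagnostics$ks_p, digits = digits),
    if (x$diagnostics$pass) " (pass)" else " (FAIL)", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
summary.bms <- function(object, ...) {
  structure(
    list(
      response = object$response,
      lml = object$lml,
      probabilities = object$probabilities,
      best_model = object$best_model,
      second_model = object$second_model,
      bf12 = object$bf12,
      evidence = object$evidence,
      coefficients = .coef_table(object$fit),
      sigma = object$fit$sigma_mean,
      diagnostics = object$diagnostics
    ),
    class = "summary.bms"
  )
}

#' @export
print.summary.bms <- function(x, digits = 3, ...) {
  cat("Response:", x$response, "\n\nModel comparison:\n")
  print(data.frame(
    log_marginal = round(x$lml, digits),
    probability = round(x$probabilities, digits)
  ))
  cat(
    "\nBest model ", x$best_model, ", BF12 = ",
    format(x$bf12, digits = digits), " [", x$evidence, "]\n",
    sep = ""
  )
  cat("\nCoefficient posterior (best model):\n")
  print(round(x$coefficients, digits))
  cat("\nPosterior mean residual SD:", format(x$sigma, digits = digits), "\n")
  cat(
    "KS: D = ", format(x$diagnostics$ks_statistic, digits = digits),
    ", p = ", format(x$diagnostics$ks_p, digits = digits), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
coef.bms <- function(object, ...) object$fit$beta_mean

#' Predicted posterior mean with credible bands
#'
#' @param object A fitted [bms()] object.
#' @param newdata Data frame with columns \code{size} and
#'   \code{rapeseed_oil}; defaults to the training design.
#' @param level Credible level (default 0.95).
#' @param model Model hypothesis to predict from; defaults to the selected
#'   best model.
#' @param ... Unused.
#' @return Data frame of query points with \code{fit}, \code{lwr},
#'   \code{med}, \code{upr}.
#' @export
predict.bms <- function(object, newdata = NULL, level = 0.95,
                        model = object$best_model, ...) {
  if (is.null(newdata)) {
    newdata <- object$data[c("size", "rapeseed_oil")]
  }
  fit <- if (identical(model, object$best_model)) {
    object$fit
  } else {
    dm <- design_matrix(object$data, object$response, model)
    .fit_single_model(dm$y, dm$X, object$prior)
  }
  Xnew <- .newdata_matrix(newdata, model)
  cbind(as.data.frame(newdata), .predict_fit(fit, Xnew, level))
}

#' @export
residuals.bms <- function(object, ...) object$diagnostics$residuals

#' @export
fitted.bms <- function(object, ...) {
  drop(object$fit$X %*% object$fit$beta_mean)
}

#' Simulate pen responses from the posterior of the selected model
#'
#' Draws a precision node from the quadrature weights, a coefficient vector
#' from its conditional Gaussian, and Gaussian noise, for each replicate.
#'
#' @param object A fitted [bms()] object.
#' @param nsim Number of replicate response vectors.
#' @param seed Integer seed (the caller's RNG stream is preserved).
#' @param ... Unused.
#' @return Matrix with one column per replicate.
#' @export
simulate.bms <- function(object, nsim = 1, seed = NULL, ...) {
  fit <- object$fit
  n <- length(fit$y)
  p <- ncol(fit$X)
  with_preserved_seed(seed, {
    out <- matrix(NA_real_, n, nsim)
    for (s in seq_len(nsim)) {
      j <- sample.int(length(fit$weights), 1, prob = fit$weights)
      m <- fit$moments[[j]]
      beta <- drop(m$mu + t(chol(m$Sigma)) %*% stats::rnorm(p))
      out[, s] <- drop(fit$X %*% beta) +
        stats::rnorm(n, sd = 1 / sqrt(fit$quad$tau[j]))
    }
    out
  })
}

#' Plot the selected regression against rapeseed-oil level
#'
#' Observed pen values with the posterior-mean line and credible band of the
#' selected model, drawn separately for the two size classes.
#'
#' @param x A fitted [bms()] object.
#' @param level Credible level for the bands.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data frame of plotted predictions.
#' @export
plot.bms <- function(x, level = 0.95, ...) {
  dat <- x$data
  oil <- seq(min(dat$rapeseed_oil), max(dat$rapeseed_oil), length.out = 41)
  grid <- expand.grid(rapeseed_oil = oil, size = sort(unique(dat$size)))
  pred <- predict(x, grid, level = level)
  graphics::plot(dat$rapeseed_oil, dat[[x$response]],
    pch = ifelse(dat$size == 0, 1, 17),
    xlab = "Rapeseed oil (% of diet)", ylab = x$response, ...
  )
  cols <- c("0" = "steelblue", "1" = "tomato")
  for (sz in sort(unique(dat$size))) {
    sub <- pred[pred$size == sz, ]
    graphics::lines(sub$rapeseed_oil, sub$fit, col = cols[as.character(sz)])
    graphics::lines(sub$rapeseed_oil, sub$lwr,
      lty = 2, col = cols[as.character(sz)]
    )
    graphics::lines(sub$rapeseed_oil, sub$upr,
      lty = 2, col = cols[as.character(sz)]
    )
  }
  graphics::legend("topleft",
    legend = c("small (0)", "large (1)"),
    pch = c(1, 17), col = cols, bty = "n"
  )
  invisible(pred)
}

#' @export
print.ks_check <- function(x, digits = 3, ...) {
  cat("One-sample KS check against N(0, 1): D = ",
    format(x$ks_statistic, digits = digits),
    ", p = ", format(x$ks_p, digits = digits),
    if (x$pass) " (pass)" else " (reject)", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.posterior_line <- function(x, digits = 3, ...) {
  cat("Posterior line, model ", x$model, " for '", x$response, "'\n",
    sep = ""
  )
  print(round(x$coefficients, digits))
  if (!is.null(x$predictions)) {
    cat("\nPredictions (", x$level * 100, "% credible):\n", sep = "")
    print(x$predictions, digits = digits)
  }
  invisible(x)
}
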