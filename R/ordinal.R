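#' Score table for ordinal histology outcomes
#'
#' Validates a long-format table of histology score counts: one row per
#' (size, rapeseed_oil, score) combination with the number of fish observed
#' at that score. Scores are ordinal categories 0..K (0 = normal, then mild,
#' moderate, marked, severe).
#'
#' @param data Data frame with columns \code{size}, \code{rapeseed_oil},
#'   \code{score}, \code{count}.
#' @param endpoint Optional endpoint tag, e.g. \code{"steatosis_PI"} or
#'   \code{"enteritis_DI"}.
#' @return The validated data frame with class \code{"score_table"}.
#' @export
score_table <- function(data, endpoint = NULL) {
  data <- as.data.frame(data)
  for (col in c("size", "rapeseed_oil", "score", "count")) {
    if (is.null(data[[col]])) {
      stop("score table is missing column '", col, "'", call. = FALSE)
    }
  }
  if (any(data$count < 0)) stop("counts must be >= 0", call. = FALSE)
  populated <- sort(unique(data$score[data$count > 0]))
  if (length(populated) < 2) {
    stop("degenerate score table: fewer than 2 populated categories",
      call. = FALSE
    )
  }
  structure(data, endpoint = endpoint, class = c("score_table", "data.frame"))
}

# Cumulative-logit log-likelihood and analytic gradient for the
# proportional-odds model logit P(Y <= k) = zeta_k - eta, eta = x'beta.
# theta = (zeta_1..zeta_{K-1}, beta); counts w per (row, category).
.po_loglik <- function(theta, eta_X, w, K) {
  nz <- K - 1
  zeta <- theta[seq_len(nz)]
  if (nz > 1 && any(diff(zeta) <= 0)) return(list(value = -Inf))
  beta <- theta[-seq_len(nz)]
  eta <- drop(eta_X %*% beta)
  # cumulative probabilities per row x category boundary
  cum <- stats::plogis(outer(-eta, zeta, `+`)) # n x (K-1)
  P <- cbind(cum, 1) - cbind(0, cum) # n x K category probs
  if (any(P[w > 0] <= 0)) return(list(value = -Inf))
  list(value = sum(w * log(pmax(P, 1e-300))), P = P, cum = cum, eta = eta)
}

.po_gradient <- function(theta, eta_X, w, K) {
  nz <- K - 1
  zeta <- theta[seq_len(nz)]
  beta <- theta[-seq_len(nz)]
  eta <- drop(eta_X %*% beta)
  cum <- stats::plogis(outer(-eta, zeta, `+`))
  dens <- cum * (1 - cum) # logistic density at each boundary
  P <- cbind(cum, 1) - cbind(0, cum)
  P <- pmax(P, 1e-300)
  # d loglik / d zeta_k: + f_k/P_k for category k, - f_k/P_{k+1} for k+1
  gz <- numeric(nz)
  for (k in seq_len(nz)) {
    gz[k] <- sum(w[, k] * dens[, k] / P[, k]) -
      sum(w[, k + 1] * dens[, k] / P[, k + 1])
  }
  # d loglik / d beta_j: -x_j * (f_k - f_{k-1}) / P_k summed over categories
  f_full <- cbind(0, dens, 0)
  gb <- numeric(ncol(eta_X))
  for (k in seq_len(K)) {
    coefk <- (f_full[, k + 1] - f_full[, k]) / P[, k]
    gb <- gb - colSums(eta_X * (w[, k] * coefk))
  }
  c(gz, gb)
}

# Numerically differenced Hessian of the analytic gradient.
.po_hessian <- function(theta, eta_X, w, K, eps = 1e-6) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + eps
    tm[j] <- tm[j] - eps
    H[, j] <- (.po_gradient(tp, eta_X, w, K) -
      .po_gradient(tm, eta_X, w, K)) / (2 * eps)
  }
  (H + t(H)) / 2
}

#' Proportional-odds ordinal regression of histology scores
#'
#' Maximum-likelihood fit of the cumulative-logit model
#' \deqn{\mathrm{logit}\, P(Y \le k) = \zeta_k - \beta_{size}\,Size -
#' \beta_{oil}\,RapeOil} by Newton iteration with step-halving, so a positive
#' coefficient shifts mass toward higher (worse) scores. Interior score
#' categories with zero total count are merged into their neighbours with a
#' warning.
#'
#' @param scores A [score_table()] or data frame with columns \code{size},
#'   \code{rapeseed_oil}, \code{score}, \code{count}.
#' @param terms Covariates to include; default both \code{"size"} and
#'   \code{"rapeseed_oil"}; a reduced set may be requested.
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class \code{"po_fit"} with components
#'   \code{coefficients} (named \code{beta}), \code{zeta} (increasing
#'   cutpoints), \code{se}, \code{vcov}, \code{logLik}, \code{converged},
#'   \code{categories}, and the iteration trace of log-likelihoods.
#' @export
#' @examples
#' tab <- sim_histology_scores(
#'   cutpoints = c(-1, 0.5, 2), beta_size = 1, beta_oil = 0.08,
#'   fish_per_pen = 200, seed = 1
#' )
#' fit <- fit_proportional_odds(tab)
#' coef(fit)
fit_proportional_odds <- function(scores,
                                  terms = c("size", "rapeseed_oil"),
                                  max_iter = 100, tol = 1e-10) {
  scores <- as.data.frame(scores)
  stopifnot(
    all(c("size", "rapeseed_oil", "score", "count") %in% names(scores)),
    length(terms) >= 1, all(terms %in% c("size", "rapeseed_oil"))
  )
  cats <- sort(unique(scores$score))
  tot <- vapply(cats, function(k) sum(scores$count[scores$score == k]),
    numeric(1)
  )
  if (sum(tot > 0) < 2) {
    stop("degenerate score table: fewer than 2 populated categories",
      call. = FALSE
    )
  }
  if (any(tot == 0)) {
    warning("empty score categories merged: ",
      paste(cats[tot == 0], collapse = ", "),
      call. = FALSE
    )
    cats <- cats[tot > 0]
  }
  for (tm in terms) {
    if (stats::sd(rep(scores[[tm]], scores$count)) == 0) {
      stop("covariate '", tm, "' does not vary", call. = FALSE)
    }
  }
  # wide count matrix: one row per covariate pattern
  pat <- unique(scores[terms])
  eta_X <- as.matrix(pat)
  K <- length(cats)
  w <- matrix(0, nrow(pat), K)
  for (i in seq_len(nrow(pat))) {
    sel <- rep(TRUE, nrow(scores))
    for (tm in terms) sel <- sel & scores[[tm]] == pat[[tm]][i]
    for (k in seq_len(K)) {
      w[i, k] <- sum(scores$count[sel & scores$score == cats[k]])
    }
  }
  # start: cutpoints at empirical cumulative logits, beta = 0
  marg <- colSums(w) / sum(w)
  zeta0 <- stats::qlogis(pmin(pmax(cumsum(marg)[-K], 1e-6), 1 - 1e-6))
  theta <- c(zeta0, rep(0, length(terms)))
  ll <- .po_loglik(theta, eta_X, w, K)$value
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- .po_gradient(theta, eta_X, w, K)
    H <- .po_hessian(theta, eta_X, w, K)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      stop("non-convergence: singular Hessian at iteration ", it,
        " (possible complete separation; |grad| = ",
        format(max(abs(g)), digits = 3), ")",
        call. = FALSE
      )
    }
    # step-halving: accept only steps that do not decrease the likelihood
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      ll_new <- .po_loglik(cand, eta_X, w, K)$value
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        stop("non-convergence: step-halving failed (complete separation?)",
          call. = FALSE
        )
      }
    }
    theta <- cand
    trace <- c(trace, ll_new)
    done <- abs(ll_new - ll) < tol * (abs(ll) + 1) && max(abs(g)) < 1e-6
    ll <- ll_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    g <- .po_gradient(theta, eta_X, w, K)
    stop("non-convergence after ", max_iter,
      " Newton iterations (|grad| = ", format(max(abs(g)), digits = 3),
      "; possible complete separation)",
      call. = FALSE
    )
  }
  H <- .po_hessian(theta, eta_X, w, K)
  vc <- tryCatch(solve(-H), error = function(e) {
    matrix(NA_real_, length(theta), length(theta))
  })
  nz <- K - 1
  nm <- c(paste0("zeta_", seq_len(nz)), terms)
  dimnames(vc) <- list(nm, nm)
  beta <- theta[-seq_len(nz)]
  names(beta) <- terms
  se <- sqrt(diag(vc))
  structure(
    list(
      coefficients = beta,
      zeta = stats::setNames(theta[seq_len(nz)], nm[seq_len(nz)]),
      se = se,
      vcov = vc,
      logLik = ll,
      converged = converged,
      iterations = length(trace) - 1,
      trace = trace,
      categories = cats,
      terms = terms
    ),
    class = "po_fit"
  )
}

#' @export
print.po_fit <- function(x, digits = 4, ...) {
  cat("Proportional-odds fit (", length(x$categories), " categories, ",
    x$iterations, " Newton iterations",
    if (!x$converged) ", NOT converged", ")\n",
    sep = ""
  )
  tab <- data.frame(
    estimate = c(x$zeta, x$coefficients),
    se = x$se
  )
  print(round(tab, digits))
  cat("log-likelihood:", format(x$logLik, digits = digits + 2), "\n")
  invisible(x)
}

#' @export
coef.po_fit <- function(object, ...) object$coefficients

#' @export
vcov.po_fit <- function(object, ...) object$vcov

#' @export
logLik.po_fit <- function(object, ...) {
  structure(object$logLik,
    df = length(object$zeta) + length(object$coefficients),
    class = "logLik"
  )
}

#' @export
summary.po_fit <- function(object, ...) {
  z <- object$coefficients / object$se[object$terms]
  tab <- cbind(
    estimate = object$coefficients,
    se = object$se[object$terms],
    odds_ratio = exp(object$coefficients),
    z = z,
    p = 2 * stats::pnorm(-abs(z))
  )
  structure(
    list(coefficients = tab, zeta = object$zeta, fit = object),
    class = "summary.po_fit"
  )
}

#' @export
print.summary.po_fit <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nWald tests and odds ratios:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Two-sided Wald p-value for a proportional-odds coefficient
#'
#' Normal-approximation p-value from coefficient over standard error, the
#' standard error taken from the inverse observed information.
#'
#' @param fit A converged [fit_proportional_odds()] object.
#' @param term Coefficient name (\code{"size"} or \code{"rapeseed_oil"}).
#' @return The two-sided p-value.
#' @export
wald_p <- function(fit, term) {
  stopifnot(inherits(fit, "po_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (!term %in% fit$terms) {
    stop("unknown term '", term, "'", call. = FALSE)
  }
  z <- fit$coefficients[term] / fit$se[term]
  unname(2 * stats::pnorm(-abs(z)))
}

#' Predicted score-category probabilities
#'
#' Differences of inverse-logit cumulative probabilities at the requested
#' covariate values; each row sums to 1.
#'
#' @param fit A converged [fit_proportional_odds()] object.
#' @param size,rapeseed_oil Covariate values (recycled to equal length).
#' @return Matrix of category probabilities, one row per query point,
#'   columns named by score category.
#' @export
predicted_category_probs <- function(fit, size, rapeseed_oil) {
  stopifnot(inherits(fit, "po_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  q <- data.frame(size = size, rapeseed_oil = rapeseed_oil)
  eta <- as.matrix(q[fit$terms]) %*% fit$coefficients
  cum <- stats::plogis(outer(-drop(eta), unname(fit$zeta), `+`))
  cum <- matrix(cum, nrow = nrow(q))
  P <- cbind(cum, 1) - cbind(0, cum)
  colnames(P) <- as.character(fit$categories)
  P
}

#' Read a score table from CSV
#'
#' CSV schema: columns \code{size}, \code{rapeseed_oil}, \code{score},
#' \code{count} (comma-separated, dot decimal, header required).
#'
#' @param path Path to the CSV file.
#' @param endpoint Optional endpoint tag.
#' @return A [score_table()].
#' @export
read_score_table <- function(path, endpoint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, fileEncoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  score_table(raw, endpoint = endpoint)
}
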