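#' Simulate pen-level responses under one of the five model hypotheses
#'
#' Generates one Gaussian pen response per (size, oil) cell of the
#' unreplicated two-factor design,
#' \eqn{y = \mu_m(x) + \sigma z} with \eqn{z} standard normal. With
#' \code{sigma = 0} the responses are the exact model means. The generator
#' is a pure function of its arguments and seed: identical calls give
#' identical tables and the caller's RNG stream is left untouched.
#'
#' @param model One of \code{"m1"}..\code{"m5"}.
#' @param beta Named coefficients: \code{intercept}, and (as used by the
#'   model) \code{size}, \code{oil}, \code{interaction}.
#' @param sigma Residual SD (>= 0).
#' @param oil_levels Dietary rapeseed-oil percentages; default the trial's
#'   six levels.
#' @param sizes Size classes; default both 0 and 1.
#' @param response Name for the response column.
#' @param seed Integer seed.
#' @return A [pen_table()] with one row per (size, oil) cell.
#' @export
#' @examples
#' sim_pen_responses("m3", beta = c(intercept = 2.5, size = -0.6),
#'   sigma = 0.1, seed = 42)
sim_pen_responses <- function(model,
                              beta = c(
                                intercept = 0, size = 0, oil = 0,
                                interaction = 0
                              ),
                              sigma = 1,
                              oil_levels = c(0, 5, 9, 14, 19, 24),
                              sizes = c(0, 1),
                              response = "y",
                              seed = NULL) {
  stopifnot(sigma >= 0, !anyDuplicated(oil_levels))
  b <- c(intercept = 0, size = 0, oil = 0, interaction = 0)
  b[names(beta)] <- beta
  grid <- expand.grid(rapeseed_oil = oil_levels, size = sizes)
  used <- .model_terms(model)
  mu <- rep(b["intercept"], nrow(grid))
  if ("size" %in% used) mu <- mu + b["size"] * grid$size
  if ("rapeseed_oil" %in% used) mu <- mu + b["oil"] * grid$rapeseed_oil
  if ("size:rapeseed_oil" %in% used) {
    mu <- mu + b["interaction"] * grid$size * grid$rapeseed_oil
  }
  y <- with_preserved_seed(seed, mu + sigma * stats::rnorm(nrow(grid)))
  out <- data.frame(
    pen_id = sprintf("S%d_%02d", grid$size, grid$rapeseed_oil),
    size = grid$size,
    rapeseed_oil = grid$rapeseed_oil
  )
  out[[response]] <- unname(y)
  suppressWarnings(pen_table(out))
}

#' Simulate fish-level histology scores under a proportional-odds model
#'
#' Draws multinomial score counts per (size, oil) cell from the cumulative
#' logit model \eqn{\mathrm{logit} P(Y \le k) = \zeta_k - \beta_{size} Size
#' - \beta_{oil} RapeOil}, emulating a fixed number of fish scored per pen.
#'
#' @param cutpoints Increasing cutpoints \eqn{\zeta_1 < \ldots <
#'   \zeta_{K-1}} defining K score categories 0..K-1.
#' @param beta_size,beta_oil Covariate effects (positive = worse scores).
#' @param fish_per_pen Number of fish scored per cell (>= 1).
#' @param oil_levels,sizes Design cells, as in [sim_pen_responses()].
#' @param seed Integer seed.
#' @return A [score_table()] in long format.
#' @export
#' @examples
#' sim_histology_scores(c(-1, 0, 1, 2), beta_size = 0.9, beta_oil = 0.05,
#'   fish_per_pen = 12, seed = 7)
sim_histology_scores <- function(cutpoints, beta_size = 0, beta_oil = 0,
                                 fish_per_pen = 12,
                                 oil_levels = c(0, 5, 9, 14, 19, 24),
                                 sizes = c(0, 1),
                                 seed = NULL) {
  stopifnot(
    length(cutpoints) >= 1, !is.unsorted(cutpoints, strictly = TRUE),
    fish_per_pen >= 1
  )
  grid <- expand.grid(rapeseed_oil = oil_levels, size = sizes)
  K <- length(cutpoints) + 1
  counts <- with_preserved_seed(seed, {
    t(vapply(seq_len(nrow(grid)), function(i) {
      eta <- beta_size * grid$size[i] + beta_oil * grid$rapeseed_oil[i]
      cum <- stats::plogis(cutpoints - eta)
      p <- diff(c(0, cum, 1))
      drop(stats::rmultinom(1, fish_per_pen, p))
    }, numeric(K)))
  })
  out <- data.frame(
    size = rep(grid$size, each = K),
    rapeseed_oil = rep(grid$rapeseed_oil, each = K),
    score = rep(0:(K - 1), nrow(grid)),
    count = as.vector(t(counts))
  )
  score_table(out)
}

#' Simulate a marker digestibility trial with known true digestibilities
#'
#' Constructs feed/faeces marker and nutrient fractions exactly consistent
#' with chosen true apparent digestibilities: the inert marker concentrates
#' in faeces by \code{concentration_factor}, and the faeces nutrient
#' fraction is solved from the digestibility formula, optionally perturbed
#' by multiplicative lognormal noise. With \code{noise_sd = 0},
#' [apparent_digestibility()] recovers \code{true_ad} exactly.
#'
#' @param true_ad Named vector of true digestibilities, percent (<= 100).
#' @param marker_feed Marker percentage in feed (> 0).
#' @param concentration_factor Faeces/feed marker concentration ratio
#'   (> 0; > 1 for a physically sensible trial).
#' @param nutrient_feed Nutrient percentages in feed, recycled against
#'   \code{true_ad}.
#' @param noise_sd SD of lognormal multiplicative noise on the faeces
#'   nutrient fraction (0 = none).
#' @param seed Integer seed.
#' @return Data frame with one row per nutrient: \code{nutrient},
#'   \code{true_ad}, \code{marker_feed}, \code{marker_faeces},
#'   \code{nutrient_feed}, \code{nutrient_faeces}.
#' @export
#' @examples
#' tr <- sim_digestibility_trial(c(fat = 85, protein = 90), seed = 1)
#' with(tr, apparent_digestibility(marker_feed, marker_faeces,
#'   nutrient_feed, nutrient_faeces))
sim_digestibility_trial <- function(true_ad,
                                    marker_feed = 0.1,
                                    concentration_factor = 5,
                                    nutrient_feed = 30,
                                    noise_sd = 0,
                                    seed = NULL) {
  stopifnot(marker_feed > 0, concentration_factor > 0, noise_sd >= 0)
  if (any(true_ad > 100)) {
    stop("config error: true_ad above 100% implies negative faeces nutrient",
      call. = FALSE
    )
  }
  k <- length(true_ad)
  nutrient_feed <- rep_len(nutrient_feed, k)
  marker_faeces <- marker_feed * concentration_factor
  nutrient_faeces <- nutrient_feed * (1 - true_ad / 100) *
    concentration_factor
  if (noise_sd > 0) {
    nutrient_faeces <- with_preserved_seed(
      seed,
      nutrient_faeces * exp(stats::rnorm(k, 0, noise_sd))
    )
  }
  data.frame(
    nutrient = if (is.null(names(true_ad))) {
      paste0("n", seq_len(k))
    } else {
      names(true_ad)
    },
    true_ad = unname(true_ad),
    marker_feed = marker_feed,
    marker_faeces = marker_faeces,
    nutrient_feed = nutrient_feed,
    nutrient_faeces = unname(nutrient_faeces)
  )
}

#' Generate a synthetic dose-response curve
#'
#' Parametric stand-ins for an external choline/steatosis dose-response
#' relationship, for testing the requirement-shift mapping: a decreasing
#' linear ramp or a decreasing logistic.
#'
#' @param family \code{"linear"}: \code{score = intercept + slope * dose}
#'   (slope < 0); \code{"logistic"}: \code{score = s_min + (s_max - s_min) /
#'   (1 + exp((dose - d50) / scale))} (scale > 0).
#' @param params Named numeric parameters of the chosen family:
#'   \code{intercept}, \code{slope} for linear; \code{s_min}, \code{s_max},
#'   \code{d50}, \code{scale} for logistic.
#' @param dose_range Dose range, mg/kg.
#' @param n Number of table nodes.
#' @return A [dose_response_curve()].
#' @export
#' @examples
#' sim_dose_response("linear", c(intercept = 4.5, slope = -1 / 1000))
sim_dose_response <- function(family = c("linear", "logistic"),
                              params = c(intercept = 4.5, slope = -1 / 1000),
                              dose_range = c(0, 4000),
                              n = 401) {
  family <- match.arg(family)
  dose <- seq(dose_range[1], dose_range[2], length.out = n)
  score <- switch(family,
    linear = {
      if (params[["slope"]] >= 0) {
        stop("config error: linear family needs slope < 0 for a ",
          "non-increasing curve",
          call. = FALSE
        )
      }
      params[["intercept"]] + params[["slope"]] * dose
    },
    logistic = {
      if (params[["scale"]] <= 0 || params[["s_max"]] <= params[["s_min"]]) {
        stop("config error: logistic family needs scale > 0 and ",
          "s_max > s_min",
          call. = FALSE
        )
      }
      params[["s_min"]] + (params[["s_max"]] - params[["s_min"]]) /
        (1 + exp((dose - params[["d50"]]) / params[["scale"]]))
    }
  )
  dose_response_curve(dose, score)
}
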