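#' First-degree regression of mean steatosis score on rapeseed-oil level
#'
#' Ordinary least squares of group-mean histology scores on dietary
#' rapeseed-oil percentage, fitted separately per size class as in the
#' published score-vs-oil lines.
#'
#' @param oil_levels Rapeseed-oil percentages (at least 2 distinct values).
#' @param mean_scores Mean scores at those levels.
#' @param size Optional size-class tag (0 or 1) carried in the result.
#' @return Object of class \code{"score_line"} with \code{slope} (score
#'   units per percent oil) and \code{intercept} (score units).
#' @export
#' @examples
#' fit_score_line(c(0, 5, 9, 14, 19, 24), c(3.1, 3.4, 3.6, 3.9, 4.1, 4.4))
fit_score_line <- function(oil_levels, mean_scores, size = NA) {
  stopifnot(length(oil_levels) == length(mean_scores))
  if (length(unique(oil_levels)) < 2) {
    stop("degenerate: need at least 2 distinct oil levels", call. = FALSE)
  }
  x <- oil_levels - mean(oil_levels)
  slope <- sum(x * (mean_scores - mean(mean_scores))) / sum(x^2)
  intercept <- mean(mean_scores) - slope * mean(oil_levels)
  structure(
    list(size = size, slope = slope, intercept = intercept),
    class = "score_line"
  )
}

#' @export
print.score_line <- function(x, digits = 4, ...) {
  cat("Score line",
    if (!is.na(x$size)) paste0(" (size ", x$size, ")"), ": y = ",
    format(x$slope, digits = digits), " x + ",
    format(x$intercept, digits = digits), "\n",
    sep = ""
  )
  invisible(x)
}

#' Evaluate a score line at an oil level
#'
#' @param line A [fit_score_line()] result, or any list with \code{slope}
#'   and \code{intercept}.
#' @param oil Rapeseed-oil percentage(s).
#' @param rounded Round to 1 decimal (half away from zero), the presentation
#'   convention of the published scores.
#' @return Predicted mean score(s).
#' @export
#' @examples
#' line <- list(slope = 0.0532, intercept = 3.1111)
#' score_at(line, 0, rounded = TRUE)
score_at <- function(line, oil, rounded = FALSE) {
  out <- line$intercept + line$slope * oil
  if (rounded) round_half_up(out, 1) else out
}

#' Score shift between two oil levels
#'
#' @inheritParams score_at
#' @param oil0,oil1 Oil percentages delimiting the shift.
#' @return \code{slope * (oil1 - oil0)}, optionally rounded to 1 decimal.
#' @export
#' @examples
#' score_shift(list(slope = 0.0699, intercept = 2.3452), 0, 24,
#'   rounded = TRUE)
score_shift <- function(line, oil0, oil1, rounded = FALSE) {
  out <- line$slope * (oil1 - oil0)
  if (rounded) round_half_up(out, 1) else out
}

#' Dose-response curve from choline dose to expected steatosis score
#'
#' Wraps a user-supplied table of (dose, score) pairs as a monotone
#' non-increasing curve, invertible by linear interpolation between nodes.
#' The external published curve is not distributed with this package; it
#' must be supplied by the user (e.g. digitized to CSV).
#'
#' @param dose Choline doses, mg/kg, strictly increasing after sorting.
#' @param score Expected steatosis scores, non-increasing in dose.
#' @return Object of class \code{"dose_response_curve"}.
#' @export
#' @examples
#' crv <- dose_response_curve(seq(0, 4000, 100), 4.5 - seq(0, 4000, 100) / 1000)
#' dose_at_score(crv, 2.3)
dose_response_curve <- function(dose, score) {
  stopifnot(length(dose) == length(score), length(dose) >= 2)
  ord <- order(dose)
  dose <- dose[ord]
  score <- score[ord]
  if (anyDuplicated(dose)) stop("doses must be distinct", call. = FALSE)
  if (any(diff(score) > 1e-12)) {
    stop("scores must be non-increasing in dose", call. = FALSE)
  }
  structure(
    list(dose = dose, score = score),
    class = "dose_response_curve"
  )
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat("Dose-response curve: ", length(x$dose), " nodes, dose [",
    min(x$dose), ", ", max(x$dose), "] mg/kg, score [",
    min(x$score), ", ", max(x$score), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Expected score at a choline dose
#'
#' @param curve A [dose_response_curve()].
#' @param dose Dose(s) within the curve's dose range, mg/kg.
#' @return Interpolated score(s).
#' @export
score_at_dose <- function(curve, dose) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (any(dose < min(curve$dose) | dose > max(curve$dose))) {
    stop("dose outside curve range [", min(curve$dose), ", ",
      max(curve$dose), "] mg/kg (no extrapolation)",
      call. = FALSE
    )
  }
  stats::approx(curve$dose, curve$score, xout = dose, ties = "ordered")$y
}

#' Choline dose at an expected score (monotone inverse)
#'
#' @param curve A [dose_response_curve()].
#' @param score Score(s) within the curve's score range.
#' @return Interpolated dose(s), mg/kg.
#' @export
dose_at_score <- function(curve, score) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (any(score < min(curve$score) | score > max(curve$score))) {
    stop("score outside curve range [", min(curve$score), ", ",
      max(curve$score), "] (no extrapolation)",
      call. = FALSE
    )
  }
  # scores decrease with dose; invert on the reversed (increasing) axis
  stats::approx(rev(curve$score), rev(curve$dose),
    xout = score, ties = "ordered"
  )$y
}

#' Indicative choline-requirement shift for a steatosis-score shift
#'
#' Maps two steatosis scores through the inverse of a dose-response curve
#' and returns the difference in choline dose,
#' \eqn{dose(score_b) - dose(score_a)} in mg/kg. The sign indicates the
#' direction of the requirement shift. The result is an \emph{indication}
#' of magnitude, not a requirement estimate; the returned value carries an
#' \code{"indication"} attribute set to \code{TRUE} to make that explicit.
#'
#' @param curve A [dose_response_curve()].
#' @param score_a,score_b The two observed scores (both within the curve's
#'   score range; no silent extrapolation).
#' @return Requirement shift in mg/kg, with attribute
#'   \code{indication = TRUE}.
#' @export
#' @examples
#' crv <- dose_response_curve(seq(0, 4000, 10), 4.5 - seq(0, 4000, 10) / 1000)
#' indicate_requirement_shift(crv, 2.3, 4.0)
indicate_requirement_shift <- function(curve, score_a, score_b) {
  shift <- dose_at_score(curve, score_b) - dose_at_score(curve, score_a)
  attr(shift, "indication") <- TRUE
  shift
}

#' Read a dose-response curve from CSV
#'
#' CSV schema: columns \code{dose_mg_per_kg} and \code{score}.
#'
#' @param path Path to the CSV file.
#' @return A [dose_response_curve()].
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, fileEncoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  for (col in c("dose_mg_per_kg", "score")) {
    if (is.null(raw[[col]])) {
      stop("schema error: missing column '", col, "'", call. = FALSE)
    }
  }
  dose_response_curve(raw$dose_mg_per_kg, raw$score)
}
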