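#' Thermal growth coefficient
#'
#' \eqn{TGC = 1000\,(BW_1^{1/3} - BW_0^{1/3}) / ddg}, where \eqn{ddg}
#' (degree-days) is feeding days times mean water temperature.
#'
#' @param bw0,bw1 Initial and final body weight, g (> 0).
#' @param days Feeding days.
#' @param mean_temp Mean water temperature, degrees C.
#' @param ddg Degree-days; defaults to \code{days * mean_temp}.
#' @return TGC (vectorized).
#' @export
#' @examples
#' thermal_growth_coefficient(1000, 2000, days = 50, mean_temp = 10)
thermal_growth_coefficient <- function(bw0, bw1, days = NULL,
                                       mean_temp = NULL,
                                       ddg = days * mean_temp) {
  if (any(bw0 <= 0) || any(bw1 <= 0)) {
    stop("body weights must be positive", call. = FALSE)
  }
  if (is.null(ddg) || any(ddg <= 0)) {
    stop("degree-days must be positive", call. = FALSE)
  }
  1000 * (bw1^(1 / 3) - bw0^(1 / 3)) / ddg
}

#' Specific growth rate, percent per day
#'
#' The standard log-difference form
#' \eqn{SGR = 100\,(\ln BW_1 - \ln BW_0)/D}. A published typographic variant
#' divides the logarithms instead
#' (\eqn{100\,(\ln BW_1 / \ln BW_0)/D}); it is available behind
#' \code{printed_variant = TRUE} for comparison with legacy tables only.
#'
#' @param bw0,bw1 Initial and final body weight, g (> 0).
#' @param days Feeding days (>= 1).
#' @param printed_variant Use the log-ratio typographic variant.
#' @return SGR in percent per day (vectorized).
#' @export
#' @examples
#' specific_growth_rate(1000, 2000, days = 55)
specific_growth_rate <- function(bw0, bw1, days, printed_variant = FALSE) {
  if (any(bw0 <= 0) || any(bw1 <= 0)) {
    stop("body weights must be positive", call. = FALSE)
  }
  if (any(days <= 0)) stop("days must be positive", call. = FALSE)
  if (printed_variant) {
    100 * (log(bw1) / log(bw0)) / days
  } else {
    100 * (log(bw1) - log(bw0)) / days
  }
}

#' Fulton's condition factor
#'
#' \eqn{K = 100\, FBW / FL^3} with body weight in g and fork length in cm.
#'
#' @param fbw Final body weight, g.
#' @param fl Fork length, cm.
#' @return Condition factor (vectorized).
#' @export
#' @examples
#' fulton_condition(1000, 10)
fulton_condition <- function(fbw, fl) {
  if (any(fbw <= 0)) stop("body weight must be positive", call. = FALSE)
  if (any(fl <= 0)) stop("fork length must be positive", call. = FALSE)
  100 * fbw / fl^3
}

#' Organosomatic index, percent of body weight
#'
#' \eqn{OSI = 100\,\mathrm{organ}/\mathrm{body}}.
#'
#' @param organ Organ weight, g (>= 0).
#' @param body Body weight, g (> 0).
#' @return OSI in percent (vectorized).
#' @export
#' @examples
#' organosomatic_index(2.6, 100)
organosomatic_index <- function(organ, body) {
  if (any(organ < 0)) stop("organ weight must be >= 0", call. = FALSE)
  if (any(body <= 0)) stop("body weight must be positive", call. = FALSE)
  100 * organ / body
}

#' Apparent digestibility from an inert marker
#'
#' Standard inert-marker form
#' \deqn{AD = 100 - 100\,\frac{M_{feed}}{M_{faeces}}\cdot
#' \frac{N_{faeces}}{N_{feed}}}
#' with \eqn{M} the marker (yttrium oxide) percentage and \eqn{N} the
#' nutrient percentage in feed and faeces. (A common typographic variant
#' prints the nutrient ratio inverted, which would give negative
#' digestibilities for typical inputs; the standard form is used.) A
#' faeces marker level below the feed level triggers a warning, since the
#' indigestible marker should concentrate in faeces.
#'
#' @param marker_feed,marker_faeces Marker percentage in feed and faeces
#'   (> 0).
#' @param nutrient_feed Nutrient percentage in feed (> 0).
#' @param nutrient_faeces Nutrient percentage in faeces (>= 0).
#' @return Apparent digestibility, percent (vectorized).
#' @export
#' @examples
#' apparent_digestibility(0.1, 0.5, 30, 7.5)
apparent_digestibility <- function(marker_feed, marker_faeces,
                                   nutrient_feed, nutrient_faeces) {
  if (any(marker_feed <= 0) || any(marker_faeces <= 0) ||
    any(nutrient_feed <= 0)) {
    stop("marker and feed-nutrient values must be positive", call. = FALSE)
  }
  if (any(nutrient_faeces < 0)) {
    stop("faeces nutrient must be >= 0", call. = FALSE)
  }
  if (any(marker_faeces < marker_feed)) {
    warning("marker is less concentrated in faeces than in feed",
      call. = FALSE
    )
  }
  100 - 100 * (marker_feed / marker_faeces) *
    (nutrient_faeces / nutrient_feed)
}

#' Fatty-acid mass from chromatographic peak areas
#'
#' Internal-standard quantification:
#' \eqn{FA\,(mg) = (A_{FA}/A_{13:0}) \times RF \times m_{13:0}}, with
#' tridecanoic acid (13:0) as internal standard and RF the response factor.
#'
#' @param area_fa Peak area of the fatty acid (>= 0).
#' @param area_is Peak area of the internal standard (> 0).
#' @param rf Response factor (> 0).
#' @param is_mass Internal standard mass, mg (> 0).
#' @return Fatty-acid mass, mg (vectorized).
#' @export
#' @examples
#' fa_mass(1200, 1000, rf = 1.05, is_mass = 0.25)
fa_mass <- function(area_fa, area_is, rf, is_mass) {
  if (any(area_fa < 0)) stop("peak area must be >= 0", call. = FALSE)
  if (any(area_is <= 0)) {
    stop("internal-standard peak area must be positive", call. = FALSE)
  }
  if (any(rf <= 0) || any(is_mass <= 0)) {
    stop("response factor and internal-standard mass must be positive",
      call. = FALSE
    )
  }
  (area_fa / area_is) * rf * is_mass
}

#' Fatty-acid concentration, mg per g of sample
#'
#' \eqn{FA\,(mg/g) = FA\,(mg) / m_{sample}\,(g)}.
#'
#' @inheritParams fa_mass
#' @param sample_mass Weighed sample mass, g (> 0).
#' @return Fatty-acid concentration, mg/g (vectorized).
#' @export
#' @examples
#' fa_concentration(1000, 1000, rf = 1, is_mass = 0.25, sample_mass = 0.5)
fa_concentration <- function(area_fa, area_is, rf, is_mass, sample_mass) {
  if (any(sample_mass <= 0)) {
    stop("sample mass must be positive", call. = FALSE)
  }
  fa_mass(area_fa, area_is, rf, is_mass) / sample_mass
}

#' Digestible nutrient content of a diet
#'
#' \eqn{\mathrm{digestible} = \mathrm{diet\ concentration} \times AD / 100}.
#'
#' @param diet_conc Dietary concentration, g/kg (>= 0).
#' @param ad Apparent digestibility, percent (<= 100).
#' @return Digestible content, g/kg (vectorized).
#' @export
#' @examples
#' digestible_content(263, 81)
digestible_content <- function(diet_conc, ad) {
  if (any(diet_conc < 0)) {
    stop("diet concentration must be >= 0", call. = FALSE)
  }
  if (any(ad > 100)) stop("digestibility cannot exceed 100%", call. = FALSE)
  diet_conc * ad / 100
}
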