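# Denominator units for per-unit monies. Each unit is "per <scale> persons"
# (or drinks/drivers); scale is the number of base entities one unit of the
# denominator represents, so value / scale is the per-entity money.

.denominator_scales <- c(
  "driver"               = 1,
  "youth"                = 1,
  "adult"                = 1,
  "drinker-year"         = 1,
  "license-revoked"      = 1,
  "vehicle-equipped"     = 1,
  "impoundment"          = 1,
  "house-arrest"         = 1,
  "probation"            = 1,
  "client"               = 1,
  "participating-worker" = 1,
  "person-treated"       = 1,
  "student"              = 1,
  "per-1e4-drinks"       = 1e4,
  "per-1e3-population"   = 1e3,
  "per-1e4-drivers"      = 1e4,
  "per-1e6-population"   = 1e6
)

#' Known denominator units
#'
#' Per-unit monies in the league tables are expressed on mixed bases (per
#' driver, per student, per million population, per 10,000 drinks, ...).
#' `denominator_scale()` returns the number of base entities one denominator
#' unit represents.
#'
#' @param unit Character vector of denominator unit names.
#' @return Named numeric vector of scales.
#' @export
#' @examples
#' denominator_scale("per-1e6-population")  # 1e6
denominator_scale <- function(unit) {
  bad <- setdiff(unit, names(.denominator_scales))
  if (length(bad) > 0L) {
    stop("unknown_unit: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  .denominator_scales[unit]
}

#' Rescale a per-denominator money to another basis
#'
#' Linearly rescales a money expressed per denominator unit (e.g. per million
#' population) to a target basis (default: per single base entity). The
#' operation is exactly invertible: rescaling to a basis and back reproduces
#' the input.
#'
#' @param value Money per denominator unit.
#' @param unit Denominator unit the value is currently expressed in.
#' @param target_scale Number of base entities in the target basis (default 1,
#'   i.e. per person / per drink / per driver).
#' @return Rescaled money, with attributes `original_unit` and `target_scale`
#'   recording provenance.
#' @export
#' @examples
#' rescale_denominator(16036, "per-1e6-population")  # 0.016036 per person
rescale_denominator <- function(value, unit, target_scale = 1) {
  stopifnot(is.numeric(value), is.numeric(target_scale), target_scale > 0)
  scale <- unname(denominator_scale(unit))
  out <- value * target_scale / scale
  attr(out, "original_unit") <- unit
  attr(out, "target_scale") <- target_scale
  out
}

#' @rdname rescale_denominator
#' @export
denominator_units <- function() names(.denominator_scales)

.intervention_categories <- c(
  "availability", "marketing", "pricing", "drink_driving",
  "workplace", "health_sector", "youth_development", "school_based"
)

#' @rdname rescale_denominator
#' @export
intervention_categories <- function() .intervention_categories

.adjustment_flags <- c(
  "uniform_benefits", "other_modifications", "costs_computed",
  "demonstration_discount"
)

#' @rdname rescale_denominator
#' @export
adjustment_flags <- function() .adjustment_flags
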