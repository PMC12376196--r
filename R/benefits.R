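#' Benefit components of a harm-reduction intervention
#'
#' Benefits split into a resource component (reduction in medical, property
#' and productivity resource costs), an intangible component (the monetized
#' value of health improvement — pain, suffering, lost quality of life), and
#' an optional spillover component (reductions in drug use, smoking or
#' violence, added only for interventions effective against alcohol harm).
#'
#' @param resource_savings,intangible_savings,spillover_savings Nonnegative
#'   monies.
#' @return List with class `benefit_components`; `total` is the component sum.
#' @export
benefit_components <- function(resource_savings, intangible_savings,
                               spillover_savings = 0) {
  stopifnot(resource_savings >= 0, intangible_savings >= 0,
            spillover_savings >= 0)
  structure(
    list(
      resource_savings = resource_savings,
      intangible_savings = intangible_savings,
      spillover_savings = spillover_savings,
      total = resource_savings + intangible_savings + spillover_savings
    ),
    class = "benefit_components"
  )
}

#' @export
print.benefit_components <- function(x, ...) {
  cat("Benefit components:",
      sprintf("resource %s + intangible %s + spillover %s = %s\n",
              money(x$resource_savings, 2), money(x$intangible_savings, 2),
              money(x$spillover_savings, 2), money(x$total, 2)))
  invisible(x)
}

#' Effectiveness estimate for an intervention
#'
#' @param relative_reduction Proportional reduction in the harmful outcome,
#'   in `[0, 1]`.
#' @param target_incidence Current incidence of the harmful outcome, events or
#'   persons per denominator unit per year.
#' @param basis `"per_person"` or `"per_event"` — the basis the incidence is
#'   counted on, which must match the harm unit cost used.
#' @param follow_up_years Follow-up horizon of the estimate.
#' @param demonstration_stage Logical; estimate from a demonstration-stage
#'   trial.
#' @return List with class `effectiveness_estimate`.
#' @export
effectiveness_estimate <- function(relative_reduction, target_incidence,
                                   basis = c("per_event", "per_person"),
                                   follow_up_years = 1,
                                   demonstration_stage = FALSE) {
  basis <- match.arg(basis)
  stopifnot(relative_reduction >= 0, relative_reduction <= 1,
            target_incidence >= 0)
  structure(
    list(relative_reduction = relative_reduction,
         target_incidence = target_incidence, basis = basis,
         follow_up_years = follow_up_years,
         demonstration_stage = demonstration_stage),
    class = "effectiveness_estimate"
  )
}

#' Per-person or per-event unit cost of alcohol-attributable harm
#'
#' Unit costs split into resource and intangible components, standing in for
#' the Western Australian harm-cost database that the published analysis drew
#' on (not publicly released; synthetic or user-supplied values are used
#' here).
#'
#' @param resource_cost,intangible_cost Nonnegative monies per harm unit.
#' @param basis `"per_person"` or `"per_event"`.
#' @param harm_type Optional label.
#' @return List with class `harm_unit_cost`.
#' @export
harm_unit_cost <- function(resource_cost, intangible_cost,
                           basis = c("per_event", "per_person"),
                           harm_type = NA_character_) {
  basis <- match.arg(basis)
  stopifnot(resource_cost >= 0, intangible_cost >= 0)
  structure(
    list(resource_cost = resource_cost, intangible_cost = intangible_cost,
         basis = basis, harm_type = harm_type),
    class = "harm_unit_cost"
  )
}

#' Direct benefit estimation from effectiveness and harm unit costs
#'
#' Approach (i): the relative harm reduction is combined with the current
#' incidence of the harmful behavior and per-person or per-event harm unit
#' costs. Each benefit component is
#' `reduction x incidence x unit cost component`; spillovers are added
#' separately by the caller.
#'
#' @param eff An [effectiveness_estimate()].
#' @param unit A [harm_unit_cost()] on the same basis as `eff`.
#' @return A [benefit_components()].
#' @export
#' @examples
#' eff <- effectiveness_estimate(0.10, 100, "per_event")
#' unit <- harm_unit_cost(50, 200, "per_event")
#' direct_benefit(eff, unit)  # resource 500, intangible 2000
direct_benefit <- function(eff, unit) {
  if (!identical(eff$basis, unit$basis)) {
    stop("basis_mismatch: effectiveness is ", eff$basis,
         " but unit cost is ", unit$basis, call. = FALSE)
  }
  scale <- eff$relative_reduction * eff$target_incidence
  benefit_components(scale * unit$resource_cost, scale * unit$intangible_cost)
}

#' Benefit transfer across jurisdictions
#'
#' Approach (ii): benefits first calculated for a source jurisdiction (the
#' United States for most reviewed studies) are multiplied by the ratio of
#' costs per alcohol-attributable harm in the destination versus the source,
#' which absorbs differences in incidence, cost per incident and currency.
#'
#' @param benefit A [benefit_components()] in the source jurisdiction.
#' @param harm_cost_ratio Positive dimensionless ratio (destination / source).
#' @param source Optional source-jurisdiction label recorded as provenance.
#' @return A [benefit_components()] scaled to the destination, with attribute
#'   `source_jurisdiction`.
#' @export
transfer_benefit <- function(benefit, harm_cost_ratio, source = "US") {
  if (!is.numeric(harm_cost_ratio) || harm_cost_ratio <= 0) {
    stop("harm_cost_ratio must be positive", call. = FALSE)
  }
  out <- benefit_components(
    benefit$resource_savings * harm_cost_ratio,
    benefit$intangible_savings * harm_cost_ratio,
    benefit$spillover_savings * harm_cost_ratio
  )
  attr(out, "source_jurisdiction") <- source
  out
}

#' Demonstration-stage benefit discount
#'
#' Benefits estimated from demonstration-stage trials are reduced (by 25% by
#' default) because effectiveness generally attenuates when programs are
#' scaled up and replicated.
#'
#' @param benefit A [benefit_components()].
#' @param flag Logical; whether the underlying estimate is
#'   demonstration-stage.
#' @param discount Fractional reduction in `[0, 1)`.
#' @return The (possibly) discounted [benefit_components()].
#' @export
apply_demonstration_discount <- function(benefit, flag, discount = 0.25) {
  stopifnot(discount >= 0, discount < 1)
  if (!isTRUE(flag)) return(benefit)
  benefit_components(
    benefit$resource_savings * (1 - discount),
    benefit$intangible_savings * (1 - discount),
    benefit$spillover_savings * (1 - discount)
  )
}

#' Present value of a yearly money stream
#'
#' Discounts a stream of future cost savings to present value at the
#' configured rate; year 0 is undiscounted. Single-year benefits bypass
#' discounting by construction.
#'
#' @param values Numeric vector of monies by year, starting at year 0.
#' @param rate Annual discount rate (>= 0). Default 0.03.
#' @return Present value `sum(values / (1 + rate)^(0:(n-1)))`.
#' @export
#' @examples
#' discount_stream(rep(100, 5), 0.03)  # 471.71
discount_stream <- function(values, rate = 0.03) {
  stopifnot(rate >= 0)
  if (length(values) == 0L) return(0)
  sum(values / (1 + rate)^(seq_along(values) - 1))
}

#' Convert intangible savings to QALYs
#'
#' The value of health improvement expressed in QALYs is the intangible cost
#' savings divided by the value of a statistical life year (VSLY).
#'
#' @param intangible Nonnegative intangible savings.
#' @param vsly Positive value of a statistical life year.
#' @return QALYs gained.
#' @export
#' @examples
#' qalys_from_intangible(182000, 182000)  # 1 QALY
qalys_from_intangible <- function(intangible, vsly) {
  if (!is.numeric(vsly) || any(vsly <= 0)) {
    stop("vsly must be positive", call. = FALSE)
  }
  stopifnot(all(intangible >= 0))
  intangible / vsly
}
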