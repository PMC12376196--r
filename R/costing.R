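#' Cost ingredient (bottom-up costing line item)
#'
#' One line of an ingredients-based costing: a resource quantity, its unit
#' price, and annualization/overhead metadata. Items with `lifetime_years > 1`
#' (equipment, development costs) are annualized to an equivalent annual cost;
#' overhead or joint cost items are recorded but excluded from intervention
#' totals, since delivering an individual intervention is unlikely to move
#' them.
#'
#' @param label Item description.
#' @param quantity Nonnegative count or hours.
#' @param unit_price Nonnegative price per unit.
#' @param lifetime_years Useful life in years, >= 1 (1 for recurrent items).
#' @param is_overhead Logical; overhead/joint cost item (excluded from
#'   totals).
#' @param labor_occupation Optional occupation key for jurisdiction wage
#'   conversion, or `NA`.
#' @return One-row data.frame with class `cost_ingredient`.
#' @export
cost_ingredient <- function(label, quantity, unit_price, lifetime_years = 1,
                            is_overhead = FALSE, labor_occupation = NA_character_) {
  stopifnot(quantity >= 0, unit_price >= 0, lifetime_years >= 1)
  ing <- data.frame(
    label = as.character(label), quantity = as.numeric(quantity),
    unit_price = as.numeric(unit_price),
    lifetime_years = as.numeric(lifetime_years),
    is_overhead = as.logical(is_overhead),
    labor_occupation = as.character(labor_occupation),
    stringsAsFactors = FALSE
  )
  class(ing) <- c("cost_ingredient", class(ing))
  ing
}

#' Equivalent annual cost of a capital outlay
#'
#' Converts a capital cost incurred up front into the constant annual payment
#' whose present value over the item's lifetime, at the given discount rate,
#' equals the capital cost (annuity factor `r / (1 - (1 + r)^-n)`). At rate 0
#' this degenerates to straight-line apportionment `capital / n`.
#'
#' @param capital Capital cost.
#' @param lifetime_years Useful life in years (> 0).
#' @param rate Annual discount rate (>= 0).
#' @return Equivalent annual cost.
#' @export
#' @examples
#' annualize(1000, 5, 0.03)  # 218.35 per year
#' annualize(1000, 5, 0)     # 200 per year (straight line)
annualize <- function(capital, lifetime_years, rate = 0.03) {
  stopifnot(is.numeric(capital), is.numeric(lifetime_years), rate >= 0)
  if (any(lifetime_years <= 0)) stop("zero_lifetime", call. = FALSE)
  if (rate == 0) {
    capital / lifetime_years
  } else {
    capital * rate / (1 - (1 + rate)^(-lifetime_years))
  }
}

#' Cost of a single ingredient
#'
#' Quantity times unit price for recurrent items; the annualized equivalent
#' for items with `lifetime_years > 1`.
#'
#' @param ing A `cost_ingredient` (or one-row data.frame with its columns).
#' @param rate Discount rate used for annualization.
#' @return Annual cost of the item.
#' @export
ingredient_cost <- function(ing, rate = 0.03) {
  outlay <- ing$quantity * ing$unit_price
  ifelse(ing$lifetime_years > 1, annualize(outlay, ing$lifetime_years, rate),
         outlay)
}

#' Total intervention cost from an ingredients list
#'
#' Sums [ingredient_cost()] over all non-overhead items. Overhead items are
#' excluded (and reported via the `excluded_overhead` attribute) because joint
#' costs are not attributable to delivering one intervention.
#'
#' @param ingredients Data.frame of ingredients (rows with the columns of
#'   [cost_ingredient()]), or a list of `cost_ingredient`s.
#' @param rate Discount rate used for annualization.
#' @return Total annual cost (0, with a warning, for an empty list), with
#'   attribute `excluded_overhead` giving the summed overhead left out.
#' @export
total_intervention_cost <- function(ingredients, rate = 0.03) {
  if (is.list(ingredients) && !is.data.frame(ingredients)) {
    ingredients <- do.call(rbind, ingredients)
  }
  if (is.null(ingredients) || nrow(ingredients) == 0L) {
    warning("empty ingredients list; total cost is 0", call. = FALSE)
    return(structure(0, excluded_overhead = 0))
  }
  costs <- ingredient_cost(ingredients, rate)
  keep <- !ingredients$is_overhead
  structure(sum(costs[keep]), excluded_overhead = sum(costs[!keep]))
}

#' Value participant travel and delay time
#'
#' Travel time is valued at 60% of the wage rate and delay time at 90%,
#' matching commonly used transport-economics conventions.
#'
#' @param travel_hours,delay_hours Nonnegative hours.
#' @param wage Hourly wage rate.
#' @param travel_share,delay_share Wage fractions applied to each time type.
#' @return Monetized time cost.
#' @export
#' @examples
#' value_time(10, 0, 20)  # $120
value_time <- function(travel_hours, delay_hours, wage,
                       travel_share = 0.6, delay_share = 0.9) {
  stopifnot(travel_hours >= 0, delay_hours >= 0, wage >= 0)
  travel_share * wage * travel_hours + delay_share * wage * delay_hours
}

#' Welfare cost of reduced alcohol consumption
#'
#' Interventions that reduce consumption (advertising bans, outlet density
#' reduction, sales-hour limits, minimum pricing) are costed at half the
#' purchase price of the alcohol not consumed, reflecting profits across the
#' manufacture-distribution-sales supply chain and hence the welfare loss of
#' the forgone consumption. The supply-chain profit share is exposed for
#' sensitivity analysis.
#'
#' @param drinks_reduced Nonnegative number of standard drinks not consumed.
#' @param pretax_price_per_drink Pre-tax purchase price per standard drink.
#' @param profit_share Fraction of the purchase price counted as welfare loss
#'   (default 0.5).
#' @return Consumption-reduction cost.
#' @export
consumption_reduction_cost <- function(drinks_reduced, pretax_price_per_drink,
                                       profit_share = 0.5) {
  stopifnot(drinks_reduced >= 0, pretax_price_per_drink >= 0,
            profit_share >= 0, profit_share <= 1)
  profit_share * drinks_reduced * pretax_price_per_drink
}

#' Cost of a volumetric tax change
#'
#' The cost of moving to volumetric (alcohol-content-based) taxation is the
#' administrative cost of the shift plus the deadweight loss: the consumer
#' benefit lost from the consumption decrease minus the accompanying increase
#' in tax revenue. A sufficiently large revenue gain makes the total negative
#' (a revenue-neutral shift can have negative net cost).
#'
#' @param admin_shift_cost Nonnegative administrative cost of the change.
#' @param consumer_benefit_loss Consumer welfare lost from reduced
#'   consumption.
#' @param tax_revenue_change Change in tax revenue (positive = gain).
#' @return Net cost of the tax change (may be negative).
#' @export
#' @examples
#' tax_change_cost(0, 100, 30)   # 70 (pure deadweight loss)
#' tax_change_cost(5, 100, 110)  # -5
tax_change_cost <- function(admin_shift_cost, consumer_benefit_loss,
                            tax_revenue_change) {
  stopifnot(admin_shift_cost >= 0)
  admin_shift_cost + (consumer_benefit_loss - tax_revenue_change)
}

#' Upper-bound cost of licensed-establishment liability
#'
#' Dram-shop style liability laws mainly transfer harm costs between payers;
#' the lawsuits themselves are excluded from the intervention cost. What is
#' counted is the cost of passing and implementing the law — taken as a
#' fraction of the expected annual claims value (against organized industry
#' opposition this sits at the top of the estimated range, 7.1%) — plus any
#' court costs. Expected claims are the annual claims value times the share of
#' late-night drink drivers whose last drink was at a licensed establishment
#' (51% in the underlying roadside data) times the share of eligible parties
#' assumed to actually sue (at most half).
#'
#' @param annual_claims_value Annual value of potential harm claims.
#' @param share_last_drink_licensed Fraction whose last drink was at a
#'   licensed establishment (default 0.51).
#' @param share_who_sue Fraction of eligible parties who would sue
#'   (default 0.50).
#' @param implementation_cost_fraction Implementation cost as a fraction of
#'   expected annual claims (default 0.071).
#' @param court_costs Total court costs added (default 0; the source leaves
#'   "modest court costs" unquantified, so they enter as an explicit
#'   parameter).
#' @return Upper-bound annual intervention cost.
#' @export
#' @examples
#' liability_cost(1e6)  # 1e6 * 0.51 * 0.5 * 0.071 = 18105
liability_cost <- function(annual_claims_value,
                           share_last_drink_licensed = 0.51,
                           share_who_sue = 0.50,
                           implementation_cost_fraction = 0.071,
                           court_costs = 0) {
  stopifnot(
    annual_claims_value >= 0,
    share_last_drink_licensed >= 0, share_last_drink_licensed <= 1,
    share_who_sue >= 0, share_who_sue <= 1,
    implementation_cost_fraction >= 0, implementation_cost_fraction <= 1,
    court_costs >= 0
  )
  expected_claims <- annual_claims_value * share_last_drink_licensed *
    share_who_sue
  implementation_cost_fraction * expected_claims + court_costs
}

#' Convert a cost between jurisdictions
#'
#' Labor-oriented costs transfer at the ratio of national average salaries for
#' the relevant occupation; non-labor costs (equipment, media buys) at the
#' purchasing-power-parity ratio; foregone-consumption costs at the ratio of
#' pre-tax drink prices.
#'
#' @param cost Money in the source jurisdiction.
#' @param kind One of `"labor"`, `"nonlabor"`, `"alcohol_price"`.
#' @param src,dst [jurisdiction_profile()]s.
#' @param occupation Occupation key; required when `kind = "labor"`.
#' @return Cost expressed in the destination jurisdiction.
#' @export
convert_cost <- function(cost, kind = c("labor", "nonlabor", "alcohol_price"),
                         src, dst, occupation = NULL) {
  kind <- match.arg(kind)
  ratio <- switch(kind,
    labor = {
      if (is.null(occupation)) {
        stop("unknown_occupation: occupation required for labor conversion",
             call. = FALSE)
      }
      if (!occupation %in% names(src$occupation_wages) ||
          !occupation %in% names(dst$occupation_wages)) {
        stop("unknown_occupation: ", occupation, call. = FALSE)
      }
      dst$occupation_wages[[occupation]] / src$occupation_wages[[occupation]]
    },
    nonlabor = dst$ppp_index / src$ppp_index,
    alcohol_price = dst$pretax_drink_price / src$pretax_drink_price
  )
  cost * ratio
}
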