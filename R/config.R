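#' Economic evaluation configuration
#'
#' Bundles the economy-wide parameters of the evaluation: the annual discount
#' rate applied to future cost savings and to annualization of capital items,
#' the value of a statistical life year (VSLY) used to convert intangible
#' savings to QALYs, the willingness-to-pay threshold for cost-effectiveness
#' classification, and the benefit discount applied to demonstration-stage
#' effectiveness estimates.
#'
#' No default VSLY ships with the package: the source tables imply it rather
#' than print it. Use [calibrate_vsly()] to derive the value implied by a
#' printed table (about A$182,000 for the environmental/workplace/health
#' table, about A$233,000 for the youth/school table), or supply your own.
#'
#' @param discount_rate Annual discount rate, in `[0, 1)`. Default 0.03.
#' @param vsly Value of a statistical life year, AUD per QALY; must be
#'   positive when supplied. Default `NULL` (must be set before QALY
#'   conversion).
#' @param wtp_threshold Willingness-to-pay threshold, AUD per QALY.
#'   Default 50,000.
#' @param demonstration_discount Fractional benefit reduction for
#'   demonstration-stage estimates, in `[0, 1)`. Default 0.25.
#' @param currency,price_year Currency tag metadata; no conversion or
#'   inflation adjustment is ever performed.
#' @return A list with class `econ_config`.
#' @export
econ_config <- function(discount_rate = 0.03, vsly = NULL,
                        wtp_threshold = 50000,
                        demonstration_discount = 0.25,
                        currency = "AUD", price_year = NA_integer_) {
  discount_rate <- as.numeric(discount_rate)
  if (!is.null(vsly)) vsly <- as.numeric(vsly)
  wtp_threshold <- as.numeric(wtp_threshold)
  demonstration_discount <- as.numeric(demonstration_discount)
  stopifnot(
    is.numeric(discount_rate), discount_rate >= 0, discount_rate < 1,
    is.null(vsly) || (is.numeric(vsly) && vsly > 0),
    is.numeric(wtp_threshold), wtp_threshold > 0,
    is.numeric(demonstration_discount),
    demonstration_discount >= 0, demonstration_discount < 1
  )
  structure(
    list(
      discount_rate = discount_rate,
      vsly = vsly,
      wtp_threshold = wtp_threshold,
      demonstration_discount = demonstration_discount,
      currency = currency,
      price_year = price_year
    ),
    class = "econ_config"
  )
}

#' @export
print.econ_config <- function(x, ...) {
  cat("Economic evaluation configuration\n")
  cat(sprintf("  discount rate:          %.1f%%/year\n", 100 * x$discount_rate))
  cat(sprintf("  VSLY:                   %s\n",
              if (is.null(x$vsly)) "<unset>" else money(x$vsly)))
  cat(sprintf("  WTP threshold:          %s per QALY\n", money(x$wtp_threshold)))
  cat(sprintf("  demonstration discount: %.0f%%\n",
              100 * x$demonstration_discount))
  cat(sprintf("  currency:               %s (price year %s)\n",
              x$currency, x$price_year))
  invisible(x)
}

#' Jurisdiction profile for cross-country cost and benefit transfer
#'
#' Multipliers used to move ingredient costs and benefit values between
#' jurisdictions: occupation-specific annual salaries (labor-oriented costs
#' transfer at the salary ratio), a purchasing-power-parity index (non-labor
#' costs), the pre-tax price of a standard drink (foregone-consumption costs),
#' and costs per alcohol-attributable harm (benefit transfer).
#'
#' @param name Jurisdiction name.
#' @param occupation_wages Named numeric vector or list, occupation -> annual
#'   salary.
#' @param ppp_index Purchasing-power-parity index (> 0).
#' @param pretax_drink_price Pre-tax price of a standard drink (> 0).
#' @param harm_cost_per_person,harm_cost_per_event Cost per
#'   alcohol-attributable harm on each basis (> 0).
#' @return A list with class `jurisdiction_profile`.
#' @seealso [convert_cost()], [transfer_benefit()]
#' @export
jurisdiction_profile <- function(name, occupation_wages = c(),
                                 ppp_index = 1, pretax_drink_price = 1,
                                 harm_cost_per_person = 1,
                                 harm_cost_per_event = 1) {
  occupation_wages <- unlist(occupation_wages)
  stopifnot(
    all(occupation_wages > 0),
    ppp_index > 0, pretax_drink_price > 0,
    harm_cost_per_person > 0, harm_cost_per_event > 0
  )
  structure(
    list(
      name = name,
      occupation_wages = occupation_wages,
      ppp_index = ppp_index,
      pretax_drink_price = pretax_drink_price,
      harm_cost_per_person = harm_cost_per_person,
      harm_cost_per_event = harm_cost_per_event
    ),
    class = "jurisdiction_profile"
  )
}

#' Read configuration from a YAML file
#'
#' The file may contain a top-level `econ` block (fields of [econ_config()])
#' and a `jurisdictions` block (named profiles with the fields of
#' [jurisdiction_profile()], occupation wages as a nested map).
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `econ` (an `econ_config`) and `jurisdictions`
#'   (named list of `jurisdiction_profile`s, possibly empty).
#' @export
read_econ_config <- function(path) {
  raw <- yaml::read_yaml(path)
  econ_args <- raw$econ
  econ <- if (is.null(econ_args)) econ_config() else do.call(econ_config, econ_args)
  jur <- lapply(names(raw$jurisdictions), function(nm) {
    args <- raw$jurisdictions[[nm]]
    args$name <- nm
    do.call(jurisdiction_profile, args)
  })
  names(jur) <- names(raw$jurisdictions)
  list(econ = econ, jurisdictions = jur)
}

# $ formatting for messages and print methods
money <- function(x, digits = 0) {
  sign <- ifelse(x < 0, "-", "")
  paste0(sign, "$", formatC(abs(x), format = "f", digits = digits,
                            big.mark = ","))
}
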