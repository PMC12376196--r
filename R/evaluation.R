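#' Benefit-cost ratio
#'
#' Total monetized benefits (resource savings plus the monetized value of
#' health improvement) divided by the cost of implementing the intervention.
#' For interventions with zero or negative cost the ratio is undefined — the
#' row is in the `NO_COST` dominant state — and `NA` is returned; see
#' [evaluation_status()].
#'
#' @param total_savings Total monetized benefits.
#' @param cost Implementation cost.
#' @return Numeric vector; `NA` where `cost <= 0`.
#' @export
#' @examples
#' bcr(184, 4)  # 46
bcr <- function(total_savings, cost) {
  ifelse(cost > 0, total_savings / cost, NA_real_)
}

#' Incremental cost-effectiveness ratio
#'
#' Net cost (implementation cost minus resource savings) per QALY gained.
#' Where resource savings alone meet or exceed a positive cost the
#' intervention is dominant (`NET_SAVING`); where cost is nonpositive it is
#' `NO_COST`; both are returned as `NA` here, with the state available from
#' [evaluation_status()]. A positive net cost with zero QALYs gained has no
#' defined ratio: scalar calls error with `"no_health_gain"`, vectorized
#' calls return `NA`.
#'
#' @param cost Implementation cost.
#' @param resource_savings Reduction in resource costs.
#' @param qalys QALYs gained (intangible savings / VSLY).
#' @return Numeric vector of cost per QALY; `NA` in sentinel states.
#' @export
#' @examples
#' icer(100, 0, 1)  # 100 per QALY
icer <- function(cost, resource_savings, qalys) {
  net <- cost - resource_savings
  bad <- cost > 0 & net > 0 & qalys <= 0
  if (any(bad)) {
    if (length(cost) == 1L) stop("no_health_gain", call. = FALSE)
  }
  ifelse(cost > 0 & net > 0 & qalys > 0, net / qalys, NA_real_)
}

#' Sentinel state of an evaluation
#'
#' @param cost,resource_savings,qalys As in [icer()]; `qalys` may be `NULL`
#'   when only cost-side states are needed.
#' @return Character vector: `"NO_COST"` (cost <= 0), `"NET_SAVING"`
#'   (resource savings >= cost > 0), `"NO_HEALTH_GAIN"` (positive net cost,
#'   no QALYs), or `"ok"`.
#' @export
evaluation_status <- function(cost, resource_savings, qalys = NULL) {
  out <- rep("ok", length(cost))
  if (!is.null(qalys)) {
    out[cost > resource_savings & cost > 0 & qalys <= 0] <- "NO_HEALTH_GAIN"
  }
  out[resource_savings >= cost & cost > 0] <- NET_SAVING
  out[cost <= 0] <- NO_COST
  out
}

#' Implied value of a statistical life year
#'
#' Algebraic inversion of the ICER and QALY-conversion formulas: given a
#' row's printed cost, resource savings, intangible savings and cost/QALY,
#' the VSLY the publication must have used is
#' `intangible * printed_icer / (cost - resource)`.
#'
#' @param cost,resource_savings,intangible_savings Printed row components.
#' @param printed_icer Printed cost per QALY (> 0).
#' @return Implied VSLY. Scalar calls with `cost <= resource_savings` error
#'   with `"net_saving_row"`; vectorized calls return `NA` for such rows.
#' @export
#' @examples
#' implied_vsly(401, 142, 679, 69355)  # about 181,823
implied_vsly <- function(cost, resource_savings, intangible_savings,
                         printed_icer) {
  net <- cost - resource_savings
  bad <- net <= 0 | printed_icer <= 0
  if (any(bad) && length(cost) == 1L) stop("net_saving_row", call. = FALSE)
  ifelse(bad, NA_real_, intangible_savings * printed_icer / net)
}

#' Classify an evaluation result at a willingness-to-pay threshold
#'
#' `NET_SAVING` rows (resource savings cover the cost) are `cost_saving`;
#' `NO_COST` rows are `no_cost_dominant`; a finite ICER at or below the
#' threshold is `cost_effective`; anything else is `not_cost_effective`.
#' A row carrying the `NET_SAVING` sentinel in its ICER cell classifies
#' `cost_saving` even if its cost-side state is `NO_COST` (a negative-cost,
#' positive-benefit row is dominant either way).
#'
#' @param icer Numeric ICER values, or a character vector that may mix
#'   numbers with the literal sentinel tokens `"NET_SAVING"` and
#'   `"NO_COST"` (as stored for printed table cells).
#' @param threshold Willingness-to-pay threshold, cost per QALY
#'   (default A$50,000).
#' @return Character vector over
#'   `{cost_saving, cost_effective, not_cost_effective, no_cost_dominant}`.
#' @export
#' @examples
#' classify(c("NET_SAVING", "9151", "102161"), 50000)
classify <- function(icer, threshold = 50000) {
  x <- as.character(icer)
  out <- character(length(x))
  out[x == NET_SAVING] <- "cost_saving"
  out[x == NO_COST] <- "no_cost_dominant"
  rest <- !(x %in% c(NET_SAVING, NO_COST))
  val <- suppressWarnings(as.numeric(x[rest]))
  out[rest] <- ifelse(!is.na(val) & val <= threshold,
                      "cost_effective", "not_cost_effective")
  out
}

# Parse a printed ICER cell: sentinel tokens stay tokens; a printed "$0" with
# a positive-net-cost claim stays the number 0 (flagged downstream, never
# silently corrected).
parse_icer_cell <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("Net saving", "Net Saving", "Net Savings")] <- NET_SAVING
  x[x %in% c("No cost", "No Cost")] <- NO_COST
  x
}

#' Evaluate a portfolio of intervention records
#'
#' The central evaluation: for each record, total benefits, benefit-cost
#' ratio, QALYs gained (intangible savings / VSLY), ICER with sentinel
#' states, and threshold classification. Returns a classed object with
#' `print`, `summary`, `plot` and `as.data.frame` methods; [league_table()]
#' orders it for reporting.
#'
#' When records carry a printed `icer_printed` column (the packaged fixture
#' tables do), classification honors the printed cell verbatim by default —
#' printed sentinel labels are data, and recomputation-vs-print disagreements
#' are the job of [consistency_report()], not silent correction. Set
#' `use_printed = FALSE` to classify from recomputed values only.
#'
#' @param records Data.frame of intervention records (see
#'   [intervention_record()] for columns; `row_id` is used as identifier when
#'   present).
#' @param config An [econ_config()].
#' @param vsly Value of a statistical life year; defaults to `config$vsly`
#'   and must be set one way or the other.
#' @param threshold Willingness-to-pay threshold; defaults to
#'   `config$wtp_threshold`.
#' @param use_printed Logical; default `TRUE` when an `icer_printed` column
#'   is present.
#' @return An object of class `cea_evaluation`.
#' @export
#' @examples
#' t4 <- load_fixture("table4_rows")
#' ev <- evaluate_portfolio(t4, vsly = 182000)
#' summary(ev)
evaluate_portfolio <- function(records, config = econ_config(), vsly = NULL,
                               threshold = NULL, use_printed = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(vsly)) vsly <- config$vsly
  if (is.null(vsly)) {
    stop("vsly must be supplied (no default ships with the package); ",
         "see calibrate_vsly()", call. = FALSE)
  }
  if (is.null(threshold)) threshold <- config$wtp_threshold
  if (is.null(use_printed)) use_printed <- "icer_printed" %in% names(records)

  if (nrow(records) == 0L) {
    tab <- data.frame(id = character(), name = character(),
                      category = character(), cost = numeric(),
                      resource_savings = numeric(),
                      intangible_savings = numeric(),
                      total_savings = numeric(), qalys = numeric(),
                      bcr = numeric(), icer = numeric(),
                      icer_sentinel = character(),
                      classification = character(),
                      stringsAsFactors = FALSE)
    return(structure(list(table = tab, vsly = vsly, threshold = threshold,
                          config = config, use_printed = use_printed),
                     class = "cea_evaluation"))
  }

  id <- if ("row_id" %in% names(records)) records$row_id else records$id
  cost <- records$cost_per_unit
  res <- records$resource_savings
  intang <- records$intangible_savings
  total <- res + intang
  qalys <- qalys_from_intangible(intang, vsly)
  status <- evaluation_status(cost, res, qalys)
  icer_num <- icer(cost, res, qalys)
  sentinel <- ifelse(status == "ok", NA_character_, status)

  icer_for_class <- ifelse(is.na(sentinel),
                           as.character(icer_num), sentinel)
  if (isTRUE(use_printed) && "icer_printed" %in% names(records)) {
    printed <- parse_icer_cell(records$icer_printed)
    icer_for_class <- ifelse(is.na(printed) | !nzchar(printed),
                             icer_for_class, printed)
  }
  classification <- classify(icer_for_class, threshold)

  tab <- data.frame(
    id = id,
    name = if ("name" %in% names(records)) records$name else id,
    category = if ("category" %in% names(records)) records$category
               else NA_character_,
    cost = cost, resource_savings = res, intangible_savings = intang,
    total_savings = total, qalys = qalys,
    bcr = bcr(total, cost), icer = icer_num, icer_sentinel = sentinel,
    classification = classification,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, vsly = vsly, threshold = threshold,
                 config = config, use_printed = use_printed),
            class = "cea_evaluation")
}

#' @export
as.data.frame.cea_evaluation <- function(x, ...) x$table

#' @export
print.cea_evaluation <- function(x, n = 10, ...) {
  cat(sprintf(
    "Portfolio evaluation: %d interventions (VSLY %s, WTP threshold %s/QALY)\n",
    nrow(x$table), money(x$vsly), money(x$threshold)))
  lt <- league_table(x)
  show <- head(lt, n)
  show$bcr <- ifelse(is.na(show$bcr), "No cost", sprintf("%.1f", show$bcr))
  show$icer <- ifelse(!is.na(show$icer_sentinel),
                      c(NET_SAVING = "Net saving",
                        NO_COST = "No cost",
                        NO_HEALTH_GAIN = "No health gain")[show$icer_sentinel],
                      money(show$icer))
  print(show[, c("id", "cost", "total_savings", "bcr", "icer",
                 "classification")], row.names = FALSE)
  if (nrow(lt) > n) cat(sprintf("... and %d more rows\n", nrow(lt) - n))
  invisible(x)
}

#' @export
summary.cea_evaluation <- function(object, ...) {
  tab <- object$table
  out <- list(
    n = nrow(tab),
    vsly = object$vsly,
    threshold = object$threshold,
    by_classification = table(factor(tab$classification, levels = c(
      "cost_saving", "cost_effective", "not_cost_effective",
      "no_cost_dominant"))),
    by_category = if (all(is.na(tab$category))) NULL
                  else table(tab$category, tab$classification)
  )
  class(out) <- "summary.cea_evaluation"
  out
}

#' @export
print.summary.cea_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation of %d interventions at %s/QALY (VSLY %s)\n",
              x$n, money(x$threshold), money(x$vsly)))
  print(x$by_classification)
  if (!is.null(x$by_category)) {
    cat("\nBy category:\n")
    print(x$by_category)
  }
  invisible(x)
}

#' @export
plot.cea_evaluation <- function(x, sort_key = c("bcr", "icer"), ...) {
  sort_key <- match.arg(sort_key)
  lt <- league_table(x, sort_key)
  vals <- rev(lt$bcr)
  labs <- rev(lt$id)
  keep <- !is.na(vals)
  graphics::barplot(vals[keep], names.arg = labs[keep], horiz = TRUE,
                    las = 1, cex.names = 0.6, xlab = "Benefit-cost ratio",
                    main = "Intervention league table", ...)
  graphics::abline(v = 1, lty = 2)
  invisible(x)
}

#' League table of evaluated interventions
#'
#' Ordered report for priority setting. Dominant rows (cost saving / no cost)
#' sort first; remaining rows sort by descending BCR or ascending ICER; ties
#' break on the intervention identifier, and the sort is stable. Per-category
#' row counts are attached as the `subtotals` attribute, mirroring the
#' published category overview.
#'
#' @param x A `cea_evaluation` (or its table).
#' @param sort_key `"bcr"` (default) or `"icer"`.
#' @return The evaluation table, reordered, with attribute `subtotals`.
#' @export
league_table <- function(x, sort_key = c("bcr", "icer")) {
  sort_key <- match.arg(sort_key)
  tab <- if (inherits(x, "cea_evaluation")) x$table else x
  dominant <- tab$classification %in% c("cost_saving", "no_cost_dominant")
  if (sort_key == "bcr") {
    # no-cost rows (undefined BCR) first, then descending BCR
    key <- ifelse(is.na(tab$bcr), Inf, tab$bcr)
    ord <- order(!dominant, -key, tab$id, method = "radix")
  } else {
    key <- ifelse(is.na(tab$icer), -Inf, tab$icer)
    ord <- order(!dominant, key, tab$id, method = "radix")
  }
  out <- tab[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "subtotals") <- if (all(is.na(out$category))) NULL
                            else table(out$category)
  out
}

#' Calibrate the implied VSLY from a printed league table
#'
#' The publication converts intangible savings to QALYs through a value of a
#' statistical life year it never prints. Inverting the printed ICERs
#' ([implied_vsly()]) recovers it per row; rows with small net cost are
#' excluded because whole-dollar printing dominates the quotient there.
#'
#' @param rows Fixture rows with printed components and `icer_printed`.
#' @param min_net_cost Minimum net cost (cost - resource savings) for a row
#'   to enter the calibration (default $50).
#' @return Object of class `vsly_calibration`: per-row implied values plus
#'   `median`, `mean`, `cv` (coefficient of variation) and `n`.
#' @export
#' @examples
#' cal <- calibrate_vsly(load_fixture("table4_rows"))
#' cal$median  # about 182,000
calibrate_vsly <- function(rows, min_net_cost = 50) {
  printed <- parse_icer_cell(rows$icer_printed)
  icer_val <- suppressWarnings(as.numeric(printed))
  net <- rows$cost_per_unit - rows$resource_savings
  keep <- !is.na(icer_val) & icer_val > 0 & net >= min_net_cost
  implied <- implied_vsly(rows$cost_per_unit[keep],
                          rows$resource_savings[keep],
                          rows$intangible_savings[keep], icer_val[keep])
  tab <- data.frame(
    row_id = if ("row_id" %in% names(rows)) rows$row_id[keep]
             else rows$id[keep],
    net_cost = net[keep], printed_icer = icer_val[keep],
    implied_vsly = implied, stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, n = nrow(tab),
         median = median(implied), mean = mean(implied),
         cv = sd(implied) / mean(implied),
         min_net_cost = min_net_cost),
    class = "vsly_calibration"
  )
}

#' @export
print.vsly_calibration <- function(x, ...) {
  cat(sprintf(
    "Implied VSLY calibration from %d rows (net cost >= %s):\n",
    x$n, money(x$min_net_cost)))
  cat(sprintf("  median %s, mean %s, CV %.2f%%, range [%s, %s]\n",
              money(x$median), money(x$mean), 100 * x$cv,
              money(min(x$table$implied_vsly)),
              money(max(x$table$implied_vsly))))
  invisible(x)
}

#' Consistency check of a printed league table
#'
#' Recomputes, from the stored printed components of each row: the component
#' sum (resource + intangible vs printed total, within $1 of whole-dollar
#' printing), the BCR, the ICER (at a calibrated or supplied VSLY), and the
#' per-row implied VSLY. Rows whose recomputed BCR moves more than `bcr_tol`
#' from the printed value are flagged; the discrepancies are attributable to
#' printed input rounding (a $19 printed cost can carry a half-dollar of
#' hidden precision). Integer-printed BCRs are compared at printed precision.
#' ICER agreement is only judged on rows with net cost of at least
#' `icer_min_net_cost`; smaller denominators are rounding-dominated and get
#' `NA`. Rows whose printed cell claims a sentinel their components
#' contradict (or vice versa) flag `icer_ok = FALSE` and are never silently
#' corrected.
#'
#' @param rows Fixture rows (printed components plus `bcr_printed`,
#'   `icer_printed`).
#' @param vsly VSLY for ICER recomputation; default: median implied VSLY
#'   calibrated from these rows.
#' @param bcr_tol Allowed absolute BCR deviation (default 0.15).
#' @param icer_tol Allowed relative ICER deviation (default 1%).
#' @param icer_min_net_cost Minimum net cost for ICER comparison
#'   (default $250).
#' @param vsly_band Length-2 numeric band for the per-row implied VSLY;
#'   default the calibration median times `c(0.978, 1.022)`.
#' @return Data.frame with per-row recomputed values and logical flags
#'   `sum_ok`, `bcr_ok`, `icer_ok`, `vsly_band`; the VSLY used is attached as
#'   attribute `vsly`.
#' @export
consistency_report <- function(rows, vsly = NULL, bcr_tol = 0.15,
                               icer_tol = 0.01, icer_min_net_cost = 250,
                               vsly_band = NULL) {
  cal <- calibrate_vsly(rows)
  if (is.null(vsly)) vsly <- cal$median
  if (is.null(vsly_band)) vsly_band <- cal$median * c(0.978, 1.022)

  id <- if ("row_id" %in% names(rows)) rows$row_id else rows$id
  cost <- rows$cost_per_unit
  res <- rows$resource_savings
  intang <- rows$intangible_savings
  total_recomputed <- res + intang
  sum_ok <- if (is.null(rows$total_savings)) rep(NA, nrow(rows))
            else abs(total_recomputed - rows$total_savings) <= 1

  bcr_printed_chr <- trimws(as.character(rows$bcr_printed))
  bcr_printed_num <- suppressWarnings(as.numeric(bcr_printed_chr))
  bcr_recomputed <- bcr(total_recomputed, cost)
  printed_integer <- !grepl(".", bcr_printed_chr, fixed = TRUE)
  bcr_ok <- ifelse(
    bcr_printed_chr == NO_COST,
    cost <= 0,
    abs(bcr_recomputed - bcr_printed_num) <= bcr_tol |
      (printed_integer & round(bcr_recomputed) == bcr_printed_num)
  )

  icer_printed_chr <- parse_icer_cell(rows$icer_printed)
  icer_printed_num <- suppressWarnings(as.numeric(icer_printed_chr))
  qalys <- qalys_from_intangible(intang, vsly)
  icer_recomputed <- icer(cost, res, qalys)
  net <- cost - res
  dominant_recomputed <- res >= cost | cost <= 0
  icer_ok <- rep(NA, nrow(rows))
  is_sent <- icer_printed_chr %in% c(NET_SAVING, NO_COST)
  icer_ok[is_sent] <- dominant_recomputed[is_sent]
  comparable <- !is_sent & !is.na(icer_printed_num) & icer_printed_num > 0 &
    net >= icer_min_net_cost
  icer_ok[comparable] <-
    abs(icer_recomputed[comparable] / icer_printed_num[comparable] - 1) <=
    icer_tol
  # a printed number on a row whose components imply dominance (or a printed
  # $0) is a contradiction, not a rounding issue
  contradiction <- !is_sent & !is.na(icer_printed_num) &
    dominant_recomputed
  icer_ok[contradiction] <- FALSE

  implied <- implied_vsly(cost, res, intang,
                          ifelse(is.na(icer_printed_num), -1,
                                 icer_printed_num))
  in_band <- ifelse(is.na(implied), NA,
                    implied >= vsly_band[1] & implied <= vsly_band[2])

  out <- data.frame(
    row_id = id, cost = cost,
    total_recomputed = total_recomputed, sum_ok = sum_ok,
    bcr_printed = bcr_printed_chr, bcr_recomputed = bcr_recomputed,
    bcr_ok = bcr_ok,
    icer_printed = icer_printed_chr, icer_recomputed = icer_recomputed,
    icer_ok = icer_ok,
    implied_vsly = implied, vsly_band = in_band,
    stringsAsFactors = FALSE
  )
  attr(out, "vsly") <- vsly
  out
}
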