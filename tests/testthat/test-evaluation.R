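test_that("BCR is savings over cost, with the no-cost dominant state", {
  expect_equal(bcr(184, 4), 46)
  expect_equal(bcr(100, 100), 1)
  expect_true(is.na(bcr(7, -10)))
  expect_identical(evaluation_status(-10, 1), NO_COST)
  expect_identical(evaluation_status(0, 0), NO_COST)

  # strictly decreasing in cost, strictly increasing in savings
  costs <- sort(runif(20, 1, 100))
  expect_true(all(diff(bcr(500, costs)) < 0))
  savings <- sort(runif(20, 0, 1000))
  expect_true(all(diff(bcr(savings, 7)) > 0))
})

test_that("ICER is net cost per QALY, with net-saving and no-health-gain states", {
  expect_identical(evaluation_status(1, 8, 0.001), NET_SAVING)
  expect_true(is.na(icer(1, 8, 0.001)))

  got <- icer(401, 142, 0.0037335)
  expect_equal(got, (401 - 142) / 0.0037335)
  expect_lt(abs(got / 69355 - 1), 0.001)  # printed value, up to input rounding

  expect_equal(icer(100, 0, 1), 100)
  expect_error(icer(100, 0, 0), "no_health_gain")
  expect_identical(evaluation_status(100, 0, 0), "NO_HEALTH_GAIN")

  # strictly increasing in cost, decreasing in resource savings
  costs <- sort(runif(20, 50, 500))
  expect_true(all(diff(icer(costs, 10, 0.01)) > 0))
  res <- sort(runif(20, 0, 40))
  expect_true(all(diff(icer(50, res, 0.01)) < 0))
})

test_that("threshold classification follows the sentinel and threshold rules", {
  expect_identical(classify("9151", 50000), "cost_effective")
  expect_identical(classify("102161", 50000), "not_cost_effective")
  expect_identical(classify("50000", 50000), "cost_effective")  # boundary: <=
  expect_identical(classify(NET_SAVING), "cost_saving")
  expect_identical(classify(NO_COST), "no_cost_dominant")
  expect_identical(classify(c(NET_SAVING, "123", NO_COST), 100),
                   c("cost_saving", "not_cost_effective", "no_cost_dominant"))

  # monotone: raising the threshold never de-classifies a cost-effective row
  icers <- c(runif(30, 0, 2e5), NET_SAVING, NO_COST)
  lo <- classify(icers, 30000)
  hi <- classify(icers, 90000)
  was_ce <- lo == "cost_effective"
  expect_true(all(hi[was_ce] == "cost_effective"))
})

test_that("implied VSLY inverts the printed ICER algebra", {
  mlda <- implied_vsly(401, 142, 679, 69355)
  expect_equal(mlda, 679 * 69355 / (401 - 142))
  expect_lt(abs(mlda / 181823 - 1), 1e-4)

  saturation <- implied_vsly(51406, 40487, 167137, 11890)
  expect_lt(abs(saturation / 182000 - 1), 0.001)

  gbg <- implied_vsly(102, 46, 3157, 4064)
  expect_equal(gbg, 3157 * 4064 / 56)
  expect_lt(abs(gbg / 229108 - 1), 1e-4)

  expect_error(implied_vsly(100, 200, 50, 1000), "net_saving_row")
})

test_that("VSLY calibration recovers a tight band per published table", {
  cal4 <- calibrate_vsly(load_fixture("table4_rows"))
  expect_gte(min(cal4$table$implied_vsly), 178000)
  expect_lte(max(cal4$table$implied_vsly), 186000)
  expect_lt(cal4$cv, 0.015)
  expect_lt(abs(cal4$median / 182000 - 1), 0.01)

  cal5 <- calibrate_vsly(load_fixture("table5_rows"))
  expect_gte(min(cal5$table$implied_vsly), 225000)
  expect_lte(max(cal5$table$implied_vsly), 245000)
  # the two tables imply materially different constants; the package reports
  # the discrepancy rather than reconciling it
  expect_gt(cal5$median / cal4$median, 1.2)
})

test_that("league table orders dominant rows first, then by key, ties by id", {
  t4 <- load_fixture("table4_rows")
  ev <- evaluate_portfolio(t4, vsly = 182000)
  lt <- league_table(ev)

  avail <- lt[lt$category == "availability" &
                lt$classification == "cost_saving", ]
  expect_identical(avail$id[1:2], c("underage_drinking_enforcement",
                                    "serving_intoxicated_enforcement"))
  expect_true(all(diff(match(lt$classification %in%
                               c("cost_saving", "no_cost_dominant"),
                             c(TRUE, FALSE))) >= 0))
  expect_false(is.null(attr(lt, "subtotals")))

  single <- evaluate_portfolio(t4[1, ], vsly = 182000)
  expect_identical(nrow(league_table(single)), 1L)

  tie <- data.frame(
    id = c("b_prog", "a_prog"), name = c("b", "a"),
    category = "workplace", cost_per_unit = c(10, 10),
    denominator = "participating-worker",
    resource_savings = c(1, 1), intangible_savings = c(99, 99),
    stringsAsFactors = FALSE
  )
  lt_tie <- league_table(evaluate_portfolio(tie, vsly = 182000))
  expect_identical(lt_tie$id, c("a_prog", "b_prog"))
})

test_that("consistency report flags exactly the documented discrepancies", {
  t4 <- load_fixture("table4_rows")
  cr4 <- consistency_report(t4, vsly = 182000)
  expect_true(all(cr4$sum_ok))

  bcr_flagged <- cr4$row_id[!is.na(cr4$bcr_ok) & !cr4$bcr_ok]
  documented <- c("prime_for_life", "rbt_rate_increase",
                  "wine_excise_at_beer_rate", "volumetric_tax_same_deadweight")
  expect_true(all(bcr_flagged %in% documented))
  expect_true(all(c("prime_for_life", "volumetric_tax_same_deadweight") %in%
                    bcr_flagged))

  # the mandated-interlock row prints a net-saving label its own components
  # contradict (net cost $118); it is flagged, never silently corrected
  icer_flagged4 <- cr4$row_id[!is.na(cr4$icer_ok) & !cr4$icer_ok]
  expect_identical(icer_flagged4, "ignition_interlock_mandated")

  t5 <- load_fixture("table5_rows")
  cr5 <- consistency_report(t5)
  expect_true(all(cr5$sum_ok))
  expect_true(all(is.na(cr5$bcr_ok) | cr5$bcr_ok))
  # printed "$0" cost/QALY on a row whose components imply a net saving
  expect_true("project_toward_no_drugs" %in%
                cr5$row_id[!is.na(cr5$icer_ok) & !cr5$icer_ok])
})

test_that("portfolio evaluation classifies fixtures from printed labels", {
  t4 <- load_fixture("table4_rows")
  ev <- evaluate_portfolio(t4, vsly = 182000)
  expect_identical(sum(ev$table$classification == "cost_saving"), 18L)

  # recomputed-only classification demotes the label-contradicting rows
  ev2 <- evaluate_portfolio(t4, vsly = 182000, use_printed = FALSE)
  tab2 <- ev2$table
  expect_identical(
    tab2$classification[tab2$id == "ignition_interlock_mandated"],
    "cost_effective")
  expect_identical(
    tab2$classification[tab2$id == "volumetric_tax_same_revenue"],
    "no_cost_dominant")
  expect_identical(sum(tab2$classification == "cost_saving"), 16L)

  expect_error(evaluate_portfolio(t4), "vsly")
})
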