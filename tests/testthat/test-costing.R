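# brute-force present value of a constant end-of-year payment stream
pv_stream <- function(payment, n, rate) {
  sum(payment / (1 + rate)^(seq_len(n)))
}

test_that("ingredient cost is quantity times price, annualized for capital", {
  expect_equal(ingredient_cost(cost_ingredient("pens", 10, 5)), 50)
  expect_equal(ingredient_cost(cost_ingredient("none", 0, 99)), 0)

  # capital item: the equivalent annual cost must repay the outlay exactly
  eq <- ingredient_cost(cost_ingredient("server", 1, 1000, 5), rate = 0.03)
  expect_equal(eq, 1000 * 0.03 / (1 - 1.03^-5))
  expect_equal(pv_stream(eq, 5, 0.03), 1000)
  expect_equal(round(eq, 2), 218.35)
})

test_that("annualization is NPV-consistent and degenerates to straight line", {
  expect_equal(annualize(1000, 5, 0), 200)
  expect_equal(annualize(1000, 1, 0.03), 1030)
  expect_error(annualize(1000, 0, 0.03), "zero_lifetime")

  for (rate in c(0.01, 0.03, 0.07, 0.12)) {
    for (n in c(1, 2, 5, 10, 30)) {
      capital <- 12345.67
      eac <- annualize(capital, n, rate)
      expect_lt(abs(pv_stream(eac, n, rate) / capital - 1), 1e-9)
    }
  }
})

test_that("annualize and ingredient_cost are elementwise over item vectors", {
  caps <- c(1000, 500, 2000)
  lives <- c(5, 2, 10)
  expect_equal(annualize(caps, lives, 0.03),
               vapply(1:3, function(i) annualize(caps[i], lives[i], 0.03),
                      numeric(1)))
  ings <- rbind(cost_ingredient("a", 1, 1000, 5),
                cost_ingredient("b", 2, 10, 1),
                cost_ingredient("c", 1, 500, 2))
  expect_equal(ingredient_cost(ings, 0.03),
               c(annualize(1000, 5, 0.03), 20, annualize(500, 2, 0.03)))
})

test_that("total cost is additive, order-invariant, and excludes overhead", {
  a <- cost_ingredient("a", 10, 5)
  b <- cost_ingredient("b", 6, 5)
  expect_equal(as.numeric(total_intervention_cost(rbind(a, b))), 80)
  expect_equal(as.numeric(total_intervention_cost(rbind(b, a))), 80)

  oh <- cost_ingredient("rent share", 1, 99, is_overhead = TRUE)
  tot <- total_intervention_cost(rbind(a, oh))
  expect_equal(as.numeric(tot), 50)
  expect_equal(attr(tot, "excluded_overhead"), 99)

  expect_warning(empty <- total_intervention_cost(list()), "empty")
  expect_equal(as.numeric(empty), 0)
})

test_that("travel time is valued at 60% and delay time at 90% of the wage", {
  expect_equal(value_time(10, 0, 20), 120)
  expect_equal(value_time(0, 10, 20), 180)
  expect_equal(value_time(0, 0, 55), 0)
  expect_equal(value_time(3, 4, 20), 0.6 * 20 * 3 + 0.9 * 20 * 4)
})

test_that("foregone consumption is costed at half the pre-tax price", {
  expect_equal(consumption_reduction_cost(1000, 2), 1000)
  expect_equal(consumption_reduction_cost(0, 2), 0)
  expect_equal(consumption_reduction_cost(10000, 1.5), 7500)
  expect_equal(consumption_reduction_cost(100, 2, profit_share = 0.3), 60)
})

test_that("tax change cost is admin cost plus deadweight loss", {
  expect_equal(tax_change_cost(0, 100, 30), 70)
  expect_equal(tax_change_cost(5, 100, 110), -5)
  expect_equal(tax_change_cost(0, 100, 100), 0)
  # with no admin cost the result is the pure deadweight loss
  set.seed(11)
  for (i in 1:20) {
    loss <- runif(1, 0, 1000)
    rev <- runif(1, 0, 1000)
    expect_equal(tax_change_cost(0, loss, rev), loss - rev)
  }
})

test_that("liability cost is the implementation fraction of expected claims", {
  expect_equal(liability_cost(1e6), 1e6 * 0.51 * 0.5 * 0.071)
  expect_equal(liability_cost(1e6), 18105)
  expect_equal(liability_cost(1e6, share_who_sue = 0, court_costs = 1234),
               1234)
  expect_equal(liability_cost(0), 0)
})

test_that("jurisdiction conversion applies the matching ratio, invertibly", {
  us <- jurisdiction_profile("US",
                             occupation_wages = c(teacher = 60000,
                                                  police = 70000),
                             ppp_index = 1, pretax_drink_price = 1.25)
  wa <- jurisdiction_profile("WA",
                             occupation_wages = c(teacher = 72000,
                                                  police = 91000),
                             ppp_index = 1.4, pretax_drink_price = 1)
  expect_equal(convert_cost(100, "labor", us, wa, occupation = "teacher"),
               120)
  expect_equal(convert_cost(100, "labor", us, us, occupation = "teacher"),
               100)
  expect_equal(convert_cost(100, "alcohol_price", us, wa), 80)
  expect_error(convert_cost(100, "labor", us, wa), "unknown_occupation")
  expect_error(convert_cost(100, "labor", us, wa, occupation = "astronaut"),
               "unknown_occupation")

  for (kind in c("labor", "nonlabor", "alcohol_price")) {
    occ <- if (kind == "labor") "police" else NULL
    out <- convert_cost(250, kind, us, wa, occupation = occ)
    back <- convert_cost(out, kind, wa, us, occupation = occ)
    expect_equal(back, 250)
  }
})
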