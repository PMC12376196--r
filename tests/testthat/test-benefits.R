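test_that("direct benefit is reduction x incidence x unit cost, per component", {
  eff <- effectiveness_estimate(0.10, 100, "per_event")
  unit <- harm_unit_cost(50, 200, "per_event")
  b <- direct_benefit(eff, unit)
  expect_equal(b$resource_savings, 500)
  expect_equal(b$intangible_savings, 2000)
  expect_equal(b$total, 2500)

  none <- direct_benefit(effectiveness_estimate(0, 100, "per_event"), unit)
  expect_equal(none$total, 0)

  b2 <- direct_benefit(effectiveness_estimate(0.25, 40, "per_event"),
                       harm_unit_cost(100, 364, "per_event"))
  expect_equal(b2$resource_savings, 1000)
  expect_equal(b2$intangible_savings, 3640)

  expect_error(
    direct_benefit(effectiveness_estimate(0.1, 10, "per_person"), unit),
    "basis_mismatch")

  # linear in each of reduction, incidence and unit costs
  set.seed(3)
  for (i in 1:10) {
    red <- runif(1, 0, 0.5); inc <- runif(1, 1, 100); k <- runif(1, 0.1, 5)
    base <- direct_benefit(effectiveness_estimate(red, inc, "per_event"), unit)
    scaled <- direct_benefit(effectiveness_estimate(red, k * inc, "per_event"),
                             unit)
    expect_equal(scaled$total, k * base$total)
  }
})

test_that("benefit transfer scales every component by the harm-cost ratio", {
  b <- benefit_components(100, 400)
  moved <- transfer_benefit(b, 1.3)
  expect_equal(moved$resource_savings, 130)
  expect_equal(moved$intangible_savings, 520)
  expect_equal(attr(moved, "source_jurisdiction"), "US")

  expect_equal(transfer_benefit(b, 1)$total, b$total)
  half <- transfer_benefit(benefit_components(5446, 20056), 0.5)
  expect_equal(half$resource_savings, 2723)
  expect_equal(half$intangible_savings, 10028)
  expect_error(transfer_benefit(b, 0), "positive")
})

test_that("demonstration-stage discount attenuates benefits by 25%", {
  b <- benefit_components(100, 400)
  d <- apply_demonstration_discount(b, TRUE, 0.25)
  expect_equal(d$resource_savings, 75)
  expect_equal(d$intangible_savings, 300)
  expect_equal(apply_demonstration_discount(b, FALSE)$total, 500)
  expect_equal(apply_demonstration_discount(b, TRUE, 0)$total, 500)

  # scalar operations commute: discount-then-transfer = transfer-then-discount
  one <- transfer_benefit(apply_demonstration_discount(b, TRUE, 0.25), 1.3)
  two <- apply_demonstration_discount(transfer_benefit(b, 1.3), TRUE, 0.25)
  expect_equal(one$resource_savings, two$resource_savings)
  expect_equal(one$intangible_savings, two$intangible_savings)
  expect_equal(one$total, two$total)
})

test_that("stream discounting matches the brute-force present-value sum", {
  expect_equal(discount_stream(100, 0.07), 100)
  expect_equal(discount_stream(c(0, 103), 0.03), 100)
  brute <- sum(100 / 1.03^(0:4))
  expect_equal(discount_stream(rep(100, 5), 0.03), brute)
  expect_equal(round(brute, 2), 471.71)

  set.seed(5)
  for (i in 1:10) {
    values <- runif(8, 0, 500)
    expect_equal(discount_stream(values, 0), sum(values))
    expect_lt(discount_stream(values, 0.05), discount_stream(values, 0.02))
  }
})

test_that("QALY conversion divides intangible savings by the VSLY", {
  expect_equal(qalys_from_intangible(182000, 182000), 1)
  expect_equal(qalys_from_intangible(0, 182000), 0)
  expect_error(qalys_from_intangible(100, 0), "positive")
  expect_error(qalys_from_intangible(100, -1), "positive")

  # conversion and monetization are mutual inverses
  set.seed(9)
  q <- runif(10, 0, 5)
  vsly <- 182000
  expect_equal(qalys_from_intangible(q * vsly, vsly), q)
})
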