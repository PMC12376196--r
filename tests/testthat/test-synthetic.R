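test_that("generation is bit-identical under a fixed seed", {
  a <- generate_portfolio(generator_config(n_interventions = 15, seed = 99))
  b <- generate_portfolio(generator_config(n_interventions = 15, seed = 99))
  expect_identical(a, b)
  c <- generate_portfolio(generator_config(n_interventions = 15, seed = 100))
  expect_false(identical(a$interventions, c$interventions))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  invisible(generate_portfolio(generator_config(n_interventions = 5,
                                                seed = 7)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("an empty portfolio is returned with a warning", {
  expect_warning(p <- generate_portfolio(
    generator_config(n_interventions = 0)), "empty")
  expect_identical(nrow(p$interventions), 0L)
})

test_that("pipeline recomputation reproduces the closed-form ground truth", {
  for (seed in 1:5) {
    p <- generate_portfolio(generator_config(n_interventions = 20,
                                             seed = seed))
    rec <- assemble_records(p)
    ev <- evaluate_portfolio(rec, vsly = p$config$vsly,
                             threshold = p$config$wtp_threshold)
    tab <- ev$table[match(p$truth$id, ev$table$id), ]
    expect_equal(tab$cost, p$truth$cost, tolerance = 1e-9)
    expect_equal(tab$bcr, p$truth$bcr, tolerance = 1e-9)
    expect_equal(tab$icer, p$truth$icer, tolerance = 1e-9)
    expect_equal(tab$qalys, p$truth$qalys, tolerance = 1e-9)
    expect_identical(tab$classification, p$truth$classification)
  }
})

test_that("zero intangible share leaves no QALY denominator anywhere", {
  p <- generate_portfolio(generator_config(n_interventions = 30, seed = 2,
                                           intangible_share = 0))
  ev <- evaluate_portfolio(p$interventions, vsly = p$config$vsly)
  expect_true(all(is.na(ev$table$icer)))
  expect_true(all(ev$table$icer_sentinel %in%
                    c(NET_SAVING, NO_COST, "NO_HEALTH_GAIN")))
  expect_false(any(ev$table$classification == "cost_effective"))
})

test_that("the empirical intangible share tracks the configured share", {
  p <- generate_portfolio(generator_config(n_interventions = 1000, seed = 3))
  share <- sum(p$interventions$intangible_savings) /
    sum(p$interventions$resource_savings + p$interventions$intangible_savings)
  expect_lt(abs(share - 0.8), 0.02)
})

test_that("printed-style rounding stays within the analytic BCR bound", {
  p <- generate_portfolio(generator_config(n_interventions = 200, seed = 4))
  expect_identical(perturb_rounding(p, 0), p)

  u <- 1
  r <- perturb_rounding(p, u)$interventions
  truth <- p$truth
  ok <- r$cost_per_unit > 0 & truth$cost > 0
  rounded_bcr <- (r$resource_savings + r$intangible_savings)[ok] /
    r$cost_per_unit[ok]
  # |T'/c' - T/c| <= |T'-T|/c' + T |c-c'| / (c c'), with |T'-T| <= u and
  # |c-c'| <= u/2 under component-wise rounding to unit u
  bound <- u / r$cost_per_unit[ok] +
    truth$total_savings[ok] * (u / 2) / (truth$cost[ok] * r$cost_per_unit[ok])
  expect_true(all(abs(rounded_bcr - truth$bcr[ok]) <= bound + 1e-12))
})

test_that("portfolios round-trip through a CSV directory", {
  p <- generate_portfolio(generator_config(n_interventions = 8, seed = 6))
  dir <- withr::local_tempdir()
  write_portfolio(p, dir)
  expect_setequal(list.files(dir),
                  c("interventions.csv", "ingredients.csv",
                    "effectiveness.csv", "harm_costs.csv",
                    "ground_truth.csv"))
  back <- read_interventions(file.path(dir, "interventions.csv"))
  expect_equal(back$cost_per_unit, p$interventions$cost_per_unit)
  expect_equal(back$intangible_savings, p$interventions$intangible_savings)
})
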