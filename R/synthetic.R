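#' Synthetic portfolio generator configuration
#'
#' Parameters of the synthetic intervention portfolios used to validate the
#' pipeline end to end: ingredient-level cost structure (log-normal unit
#' prices, occasional capital items and overhead lines), effectiveness
#' estimates with per-event harm unit costs split into resource and
#' intangible components, and a known ground-truth BCR/ICER per intervention.
#' The intangible share defaults to 0.8, matching the roughly 80-85%
#' intangible share observed across the published environmental-intervention
#' rows.
#'
#' @param n_interventions Number of interventions to generate.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @param ingredient_count_range Integer range of costing line items per
#'   intervention.
#' @param unit_price_meanlog,unit_price_sdlog Log-normal unit price
#'   parameters (median `exp(meanlog)` dollars).
#' @param capital_probability Probability a line item is a capital item with
#'   multi-year lifetime.
#' @param lifetime_range Integer range of capital-item lifetimes, years.
#' @param overhead_probability Probability a line item is overhead (recorded
#'   but excluded from totals).
#' @param effectiveness_range Range of the relative harm reduction.
#' @param incidence_mean Mean incidence of the harmful event per denominator
#'   unit per year (drawn as `1 + Poisson(mean - 1)` so every intervention
#'   has nonzero exposure).
#' @param harm_cost_meanlog,harm_cost_sdlog Log-normal total harm unit cost
#'   parameters.
#' @param intangible_share Mean fraction of the harm unit cost that is
#'   intangible, in `[0, 1]` (default 0.8).
#' @param intangible_share_conc Beta concentration of the per-row intangible
#'   share around its mean (shares of exactly 0 or 1 are kept degenerate).
#' @param demonstration_probability Probability an intervention's
#'   effectiveness is demonstration-stage.
#' @param discount_rate,demonstration_discount,vsly,wtp_threshold Economic
#'   parameters shared with the pipeline.
#' @return List with class `generator_config`.
#' @export
generator_config <- function(n_interventions = 20, seed = 1,
                             ingredient_count_range = c(2L, 6L),
                             unit_price_meanlog = log(50),
                             unit_price_sdlog = 0.8,
                             capital_probability = 0.2,
                             lifetime_range = c(2L, 10L),
                             overhead_probability = 0.15,
                             effectiveness_range = c(0.02, 0.30),
                             incidence_mean = 50,
                             harm_cost_meanlog = log(2000),
                             harm_cost_sdlog = 0.7,
                             intangible_share = 0.8,
                             intangible_share_conc = 50,
                             demonstration_probability = 0.2,
                             discount_rate = 0.03,
                             demonstration_discount = 0.25,
                             vsly = 182000, wtp_threshold = 50000) {
  stopifnot(
    n_interventions >= 0,
    ingredient_count_range[1] >= 1,
    ingredient_count_range[1] <= ingredient_count_range[2],
    effectiveness_range[1] >= 0, effectiveness_range[2] <= 1,
    effectiveness_range[1] <= effectiveness_range[2],
    lifetime_range[1] >= 2, lifetime_range[1] <= lifetime_range[2],
    intangible_share >= 0, intangible_share <= 1,
    incidence_mean >= 1, vsly > 0
  )
  structure(as.list(environment()), class = "generator_config")
}

# run code under a private RNG state so generation neither depends on nor
# disturbs the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic intervention portfolio with known ground truth
#'
#' Draws ingredient-level costs, effectiveness estimates and harm unit costs,
#' and computes each intervention's exact BCR, ICER, QALYs and classification
#' from the closed-form definitions *inside the generator* — deliberately
#' duplicating, not importing, the pipeline formulas — so the ground-truth
#' table is an independent oracle for the pipeline.
#'
#' @param cfg A [generator_config()].
#' @return List with class `synthetic_portfolio`: data.frames
#'   `interventions` (final per-unit records, pipeline input schema),
#'   `ingredients`, `effectiveness`, `harm_costs`, the independent `truth`
#'   table, and the `config`. `n_interventions = 0` yields empty tables with
#'   a warning.
#' @export
#' @examples
#' p <- generate_portfolio(generator_config(n_interventions = 5, seed = 42))
#' p$truth$bcr
generate_portfolio <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_interventions
  if (n == 0L) {
    warning("n_interventions = 0; empty portfolio", call. = FALSE)
    empty <- data.frame()
    return(structure(list(interventions = empty, ingredients = empty,
                          effectiveness = empty, harm_costs = empty,
                          truth = empty, config = cfg),
                     class = "synthetic_portfolio"))
  }
  with_local_seed(cfg$seed, {
    id <- sprintf("synth_%04d", seq_len(n))
    person_units <- c("driver", "youth", "adult", "client", "student",
                      "person-treated", "participating-worker")

    k <- sample(seq(cfg$ingredient_count_range[1],
                    cfg$ingredient_count_range[2]), n, replace = TRUE)
    ing_id <- rep(id, k)
    m <- sum(k)
    ingredients <- data.frame(
      id = ing_id,
      label = paste0("item_", unlist(lapply(k, seq_len))),
      quantity = round(runif(m, 1, 100)),
      unit_price = round(rlnorm(m, cfg$unit_price_meanlog,
                                cfg$unit_price_sdlog), 2),
      lifetime_years = ifelse(
        runif(m) < cfg$capital_probability,
        sample(seq(cfg$lifetime_range[1], cfg$lifetime_range[2]), m,
               replace = TRUE), 1),
      is_overhead = runif(m) < cfg$overhead_probability,
      labor_occupation = NA_character_,
      stringsAsFactors = FALSE
    )

    effectiveness <- data.frame(
      id = id,
      relative_reduction = runif(n, cfg$effectiveness_range[1],
                                 cfg$effectiveness_range[2]),
      target_incidence = 1 + rpois(n, cfg$incidence_mean - 1),
      basis = "per_event",
      demonstration_stage = runif(n) < cfg$demonstration_probability,
      stringsAsFactors = FALSE
    )

    total_harm <- rlnorm(n, cfg$harm_cost_meanlog, cfg$harm_cost_sdlog)
    share <- if (cfg$intangible_share %in% c(0, 1)) {
      rep(cfg$intangible_share, n)
    } else {
      rbeta(n, cfg$intangible_share * cfg$intangible_share_conc,
            (1 - cfg$intangible_share) * cfg$intangible_share_conc)
    }
    harm_costs <- data.frame(
      id = id, harm_type = "alcohol_attributable_event", basis = "per_event",
      resource_cost = total_harm * (1 - share),
      intangible_cost = total_harm * share,
      stringsAsFactors = FALSE
    )

    # ---- independent closed-form ground truth (duplicates the pipeline
    # definitions on purpose; do not replace with package functions) ----
    r <- cfg$discount_rate
    L <- ingredients$lifetime_years
    annuity <- if (r == 0) 1 / L else r / (1 - (1 + r)^(-L))
    item_annual <- ingredients$quantity * ingredients$unit_price *
      ifelse(L > 1, annuity, 1)
    item_annual[ingredients$is_overhead] <- 0
    truth_cost <- as.numeric(
      rowsum(item_annual, ingredients$id)[id, 1])
    att <- ifelse(effectiveness$demonstration_stage,
                  1 - cfg$demonstration_discount, 1)
    scale <- effectiveness$relative_reduction *
      effectiveness$target_incidence * att
    truth_resource <- scale * harm_costs$resource_cost
    truth_intangible <- scale * harm_costs$intangible_cost
    truth_total <- truth_resource + truth_intangible
    truth_qalys <- truth_intangible / cfg$vsly
    truth_bcr <- ifelse(truth_cost > 0, truth_total / truth_cost, NA_real_)
    truth_net <- truth_cost - truth_resource
    truth_icer <- ifelse(truth_cost > 0 & truth_net > 0 & truth_qalys > 0,
                         truth_net / truth_qalys, NA_real_)
    truth_class <- ifelse(
      truth_cost <= 0, "no_cost_dominant",
      ifelse(truth_resource >= truth_cost, "cost_saving",
             ifelse(truth_qalys > 0 & truth_net / truth_qalys <=
                      cfg$wtp_threshold,
                    "cost_effective", "not_cost_effective")))
    truth <- data.frame(
      id = id, cost = truth_cost, resource_savings = truth_resource,
      intangible_savings = truth_intangible, total_savings = truth_total,
      qalys = truth_qalys, bcr = truth_bcr, icer = truth_icer,
      classification = truth_class, stringsAsFactors = FALSE
    )

    interventions <- data.frame(
      id = id, name = paste("Synthetic intervention", seq_len(n)),
      category = sample(setdiff(intervention_categories(), "pricing"), n,
                        replace = TRUE),
      cost_per_unit = truth_cost,
      denominator = sample(person_units, n, replace = TRUE),
      resource_savings = truth_resource,
      intangible_savings = truth_intangible,
      quality_rating = sample(c("A", "B", "C"), n, replace = TRUE),
      demonstration_stage = effectiveness$demonstration_stage,
      flags = ifelse(effectiveness$demonstration_stage,
                     "demonstration_discount", ""),
      stringsAsFactors = FALSE
    )

    structure(list(interventions = interventions, ingredients = ingredients,
                   effectiveness = effectiveness, harm_costs = harm_costs,
                   truth = truth, config = cfg),
              class = "synthetic_portfolio")
  })
}

#' @export
print.synthetic_portfolio <- function(x, ...) {
  cat(sprintf(
    "Synthetic portfolio: %d interventions, %d costing items (seed %d)\n",
    nrow(x$interventions), nrow(x$ingredients), x$config$seed))
  invisible(x)
}

#' Recompute a synthetic portfolio through the pipeline
#'
#' Runs the generated raw inputs through the package's own stages — total
#' intervention cost from the ingredients list, direct benefit estimation
#' from effectiveness and harm unit costs, demonstration-stage discounting —
#' and assembles intervention records for [evaluate_portfolio()]. Used to
#' check the pipeline against the generator's independent ground truth.
#'
#' @param portfolio A `synthetic_portfolio`.
#' @return Data.frame of intervention records with pipeline-computed
#'   `cost_per_unit`, `resource_savings` and `intangible_savings`.
#' @export
assemble_records <- function(portfolio) {
  stopifnot(inherits(portfolio, "synthetic_portfolio"))
  cfg <- portfolio$config
  recs <- portfolio$interventions
  eff <- portfolio$effectiveness
  harm <- portfolio$harm_costs
  for (i in seq_len(nrow(recs))) {
    ing <- portfolio$ingredients[portfolio$ingredients$id == recs$id[i], ]
    recs$cost_per_unit[i] <- total_intervention_cost(ing, cfg$discount_rate)
    b <- direct_benefit(
      effectiveness_estimate(eff$relative_reduction[i],
                             eff$target_incidence[i], eff$basis[i],
                             demonstration_stage = eff$demonstration_stage[i]),
      harm_unit_cost(harm$resource_cost[i], harm$intangible_cost[i],
                     harm$basis[i])
    )
    b <- apply_demonstration_discount(b, eff$demonstration_stage[i],
                                      cfg$demonstration_discount)
    recs$resource_savings[i] <- b$resource_savings
    recs$intangible_savings[i] <- b$intangible_savings
  }
  recs
}

#' Apply printed-style rounding to a portfolio
#'
#' Rounds the money columns of the intervention records to a dollar unit,
#' emulating the whole-dollar printing of the published tables; the ground
#' truth is left untouched. Used to verify that consistency-check tolerances
#' absorb rounding of the observed magnitude (worst-case BCR shift for a row
#' rounded by half a unit each way is
#' `savings * u/2 / cost^2 + u/2 / cost`).
#'
#' @param portfolio A `synthetic_portfolio`.
#' @param dollars Rounding unit in dollars; 0 is the identity.
#' @return The portfolio with rounded intervention records.
#' @export
perturb_rounding <- function(portfolio, dollars = 1) {
  stopifnot(inherits(portfolio, "synthetic_portfolio"), dollars >= 0)
  if (dollars == 0) return(portfolio)
  recs <- portfolio$interventions
  for (col in c("cost_per_unit", "resource_savings", "intangible_savings")) {
    recs[[col]] <- round(recs[[col]] / dollars) * dollars
  }
  portfolio$interventions <- recs
  portfolio
}

#' Write a synthetic portfolio to a directory of CSV files
#'
#' Emits `interventions.csv`, `ingredients.csv`, `effectiveness.csv`,
#' `harm_costs.csv` and `ground_truth.csv` with the same schemas the loaders
#' consume.
#'
#' @param portfolio A `synthetic_portfolio`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_portfolio <- function(portfolio, dir) {
  stopifnot(inherits(portfolio, "synthetic_portfolio"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list(interventions = portfolio$interventions,
                ingredients = portfolio$ingredients,
                effectiveness = portfolio$effectiveness,
                harm_costs = portfolio$harm_costs,
                ground_truth = portfolio$truth)
  for (nm in names(files)) {
    write.csv(files[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE, quote = TRUE, na = "")
  }
  invisible(dir)
}
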