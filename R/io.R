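.fixture_names <- c("table1_counts", "table2_ratings", "table3_flags",
                    "table4_rows", "table5_rows")

#' Load a packaged fixture table
#'
#' The published tables ship with the package as UTF-8 CSV: the category
#' overview (`table1_counts`), study quality ratings (`table2_ratings`),
#' standardization-adjustment flags (`table3_flags`), and the two
#' cost-effectiveness league tables (`table4_rows`, `table5_rows`). Printed
#' values are preserved verbatim: sentinel cells ("Net saving", "No cost")
#' are stored as the literal tokens `NET_SAVING` / `NO_COST`, and the
#' Project Toward No Drugs row keeps its printed `$0` cost/QALY cell
#' unchanged (the consistency report flags it rather than correcting it).
#'
#' @param name One of `r paste0('\x60', .fixture_names, '\x60', collapse = ", ")`.
#' @return A data.frame. For the league tables, money columns are numeric
#'   while `bcr_printed` / `icer_printed` stay character so printed precision
#'   (one decimal vs integer) is not lost. `table1_counts` carries the
#'   published subtotal structure in attributes `subtotals` and `total`.
#' @export
#' @examples
#' nrow(load_fixture("table4_rows"))  # 33
load_fixture <- function(name) {
  if (length(name) != 1L || !name %in% .fixture_names) {
    stop("unknown fixture: ", name, "; expected one of ",
         paste(.fixture_names, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "alcocea")
  if (!nzchar(path)) stop("fixture file missing: ", name, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 encoding = "UTF-8")
  if (name %in% c("table4_rows", "table5_rows")) {
    for (col in c("cost_per_unit", "resource_savings", "intangible_savings",
                  "total_savings")) {
      df[[col]] <- as.numeric(df[[col]])
    }
    df$demonstration_stage <- as.logical(df$demonstration_stage)
    df$flags[is.na(df$flags)] <- ""
  } else if (name == "table1_counts") {
    df$n <- as.integer(df$n)
    subtotals <- tapply(df$n, df$category_group, sum)
    attr(df, "subtotals") <- subtotals
    attr(df, "total") <- sum(df$n)
  } else if (name == "table3_flags") {
    for (col in c("uniform_benefits", "other_modifications", "costs_computed",
                  "demonstration_stage")) {
      df[[col]] <- as.logical(df[[col]])
    }
  }
  df
}

.intervention_columns <- c(
  "id", "name", "category", "cost_per_unit", "denominator",
  "resource_savings", "intangible_savings", "quality_rating",
  "demonstration_stage", "flags"
)

#' Read and write intervention records as CSV
#'
#' The interventions CSV schema has a mandatory header with columns
#' `id,name,category,cost_per_unit,denominator,resource_savings,`
#' `intangible_savings,quality_rating,demonstration_stage,flags` (flags
#' `";"`-separated). `read_interventions(write_interventions(x))` is the
#' identity. Missing columns raise `schema_violation`; non-numeric money
#' cells are reported with their line number.
#'
#' @param path File path.
#' @return `read_interventions()`: data.frame of records (validated with
#'   [validate_record()]; violations raise an error naming the offending
#'   rows).
#' @export
read_interventions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 encoding = "UTF-8")
  # row_id/intervention_id fixtures satisfy the schema through their row_id
  if (!"id" %in% names(df) && "row_id" %in% names(df)) df$id <- df$row_id
  missing <- setdiff(.intervention_columns, names(df))
  if (length(missing) > 0L) {
    stop("schema_violation: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("cost_per_unit", "resource_savings", "intangible_savings")) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(num) & nzchar(trimws(df[[col]]))
    if (any(bad)) {
      stop(sprintf("non-numeric value in column '%s' at line %d: '%s'",
                   col, which(bad)[1] + 1L, df[[col]][which(bad)[1]]),
           call. = FALSE)
    }
    df[[col]] <- num
  }
  df$demonstration_stage <- as.logical(df$demonstration_stage)
  df$flags[is.na(df$flags)] <- ""
  v <- validate_record(df)
  if (inherits(v, "record_violations")) {
    stop("invalid records: ",
         paste(names(v), vapply(v, paste, "", collapse = "+"),
               sep = ": ", collapse = "; "), call. = FALSE)
  }
  df
}

#' @rdname read_interventions
#' @param records Data.frame of intervention records.
#' @export
write_interventions <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write a league table as CSV
#'
#' Columns `id,name,category,cost,resource,intangible,total,bcr,icer,`
#' `classification`. Sentinel states are written as the literal tokens
#' `NET_SAVING` / `NO_COST` so that round-trips are unambiguous (an empty
#' cell would not distinguish the two dominant states).
#'
#' @param report A `cea_evaluation` or a league table from [league_table()].
#' @param path Output file path.
#' @export
write_league <- function(report, path) {
  tab <- if (inherits(report, "cea_evaluation")) league_table(report)
         else report
  out <- data.frame(
    id = tab$id, name = tab$name, category = tab$category,
    cost = tab$cost, resource = tab$resource_savings,
    intangible = tab$intangible_savings, total = tab$total_savings,
    bcr = ifelse(is.na(tab$bcr), NO_COST, as.character(tab$bcr)),
    icer = ifelse(!is.na(tab$icer_sentinel), tab$icer_sentinel,
                  as.character(tab$icer)),
    classification = tab$classification,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Run the full evaluation pipeline
#'
#' Loads records (a packaged fixture by name, a CSV path, or an in-memory
#' data.frame), evaluates the portfolio, orders the league table, and — when
#' the input carries printed ratio columns — recomputes the printed-table
#' consistency report. Deterministic given inputs and configuration; stage
#' decisions (overhead exclusions, flagged rows) are collected in `log`.
#'
#' @param input Fixture name (`"table4_rows"` / `"table5_rows"`), a CSV path,
#'   or a data.frame of records. An empty data.frame yields empty outputs
#'   with a warning.
#' @param config An [econ_config()].
#' @param vsly,threshold Overrides for the config values; `vsly = NULL` with
#'   a fixture input calibrates the implied VSLY from that table.
#' @param sort_key League-table sort key, `"bcr"` or `"icer"`.
#' @return List with class `cea_pipeline`: `evaluation`, `league`,
#'   `consistency` (or `NULL`), `vsly`, `log`.
#' @export
run_pipeline <- function(input, config = econ_config(), vsly = NULL,
                         threshold = NULL, sort_key = "bcr") {
  log <- character()
  note <- function(stage, event) {
    log <<- c(log, sprintf("[%s] %s", stage, event))
  }

  records <- if (is.data.frame(input)) {
    note("load", sprintf("in-memory records: %d rows", nrow(input)))
    input
  } else if (is.character(input) && input %in% .fixture_names) {
    note("load", sprintf("fixture %s", input))
    load_fixture(input)
  } else if (is.character(input)) {
    note("load", sprintf("CSV %s", input))
    read_interventions(input)
  } else {
    stop("input must be a fixture name, CSV path or data.frame",
         call. = FALSE)
  }

  if (nrow(records) == 0L) {
    warning("empty input; empty outputs", call. = FALSE)
    ev <- evaluate_portfolio(records, config,
                             vsly = if (is.null(vsly)) 1 else vsly,
                             threshold = threshold)
    return(structure(list(evaluation = ev, league = league_table(ev),
                          consistency = NULL, vsly = ev$vsly, log = log),
                     class = "cea_pipeline"))
  }

  has_printed <- "icer_printed" %in% names(records)
  if (is.null(vsly)) vsly <- config$vsly
  if (is.null(vsly) && has_printed) {
    cal <- calibrate_vsly(records)
    vsly <- cal$median
    note("calibrate", sprintf("implied VSLY median %s (n=%d, CV %.2f%%)",
                              money(vsly), cal$n, 100 * cal$cv))
  }

  ev <- evaluate_portfolio(records, config, vsly = vsly,
                           threshold = threshold)
  note("evaluate", sprintf("%d rows; %d cost_saving, %d cost_effective",
                           nrow(ev$table),
                           sum(ev$table$classification == "cost_saving"),
                           sum(ev$table$classification == "cost_effective")))

  consistency <- NULL
  if (has_printed) {
    consistency <- consistency_report(records, vsly = vsly)
    flagged <- consistency$row_id[
      (!is.na(consistency$bcr_ok) & !consistency$bcr_ok) |
        (!is.na(consistency$icer_ok) & !consistency$icer_ok)]
    if (length(flagged) > 0L) {
      note("check", paste("flagged rows:", paste(flagged, collapse = ", ")))
    }
  }

  structure(list(evaluation = ev, league = league_table(ev, sort_key),
                 consistency = consistency, vsly = vsly, log = log),
            class = "cea_pipeline")
}

#' @export
print.cea_pipeline <- function(x, ...) {
  cat("Evaluation pipeline run\n")
  for (line in x$log) cat(" ", line, "\n")
  print(x$evaluation)
  invisible(x)
}
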