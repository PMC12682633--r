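#' Load a run configuration
#'
#' Configurations are plain lists (or YAML files) with the fields used by
#' [run_burden_analysis()] and [run_projection()]:
#' `burden_table` (CSV path), `population` (CSV path),
#' `standard_population` (builtin name or path, default `"who_world"`),
#' `strata` (list of `measure`/`location`/`sex`/`cause` selections; default
#' all strata present in the table), `model` (arguments for [apc_spec()]),
#' `horizon`, `split_year`, `scenario`, `out_dir` and `seed`.
#'
#' @param config A list, or a path to a YAML file.
#' @return The configuration list with defaults filled in.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    check_that(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  check_that(is.list(config), "config must be a list or a YAML file path")
  config$standard_population <- config$standard_population %||% "who_world"
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "."
  config
}

# Strata present in a burden table (ignoring risk-attributed rows).
.table_strata <- function(df) {
  df <- df[is.na(df$rei) | df$rei == "" | df$rei == "none", , drop = FALSE]
  unique(df[c("measure", "location", "sex")])
}

.write_manifest <- function(config, out_dir, stage, files) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    inputs = list(burden_table = config$burden_table %||% NA,
                  population = config$population %||% NA,
                  standard_population = config$standard_population),
    outputs = files,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("bapcburden")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run the descriptive burden analysis
#'
#' For every (measure, location, sex) stratum in the configuration this
#' computes the ASR series (via [lexis_asr_series()]), the EAPC of that
#' series, and - when the burden table carries risk-attributed rows or a
#' PAF table is supplied - the attributable burden per risk. Outputs are
#' written as GBD-dialect CSVs with an extra `quantity` column, plus a run
#' manifest recording inputs, seed and versions. Deterministic: rerunning
#' the same configuration gives byte-identical tables (the manifest
#' timestamp aside).
#'
#' @param config See [load_config()]. Optional elements: `sdi` (named list
#'   or vector location -> SDI in `[0, 1]`) for quintile summaries, `paf`
#'   (data.frame with columns `risk, location, sex, age_group, year, paf`).
#' @return Invisibly, a named list of the output data.frames.
#' @export
run_burden_analysis <- function(config) {
  config <- load_config(config)
  table <- read_burden_table(config$burden_table)
  population <- read_population_grid(config$population)
  weights <- read_standard_population(config$standard_population)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strata <- config$strata %||%
    split(.table_strata(table), seq_len(nrow(.table_strata(table))))
  asr_rows <- list(); eapc_rows <- list()
  for (st in strata) {
    series <- tryCatch(
      lexis_asr_series(
        to_lexis_grid(table, population, st$measure, st$location, st$sex),
        weights),
      error = function(e) stop(sprintf("stage asr, stratum (%s, %s, %s): %s",
                                       st$measure, st$location, st$sex,
                                       conditionMessage(e)), call. = FALSE))
    asr_rows[[length(asr_rows) + 1]] <- data.frame(
      quantity = "asr", measure = st$measure, location = st$location,
      sex = st$sex, year = series$year, val = series$asr,
      stringsAsFactors = FALSE)
    e <- compute_eapc(series)
    eapc_rows[[length(eapc_rows) + 1]] <- data.frame(
      quantity = "eapc", measure = st$measure, location = st$location,
      sex = st$sex, val = e$eapc, lower = e$ci_lower, upper = e$ci_upper,
      beta = e$beta, se = e$se, stringsAsFactors = FALSE)
  }
  out <- list(asr = do.call(rbind, asr_rows), eapc = do.call(rbind, eapc_rows))
  # risk attribution: PAF x total, joined at the finest common stratum
  if (!is.null(config$paf)) {
    paf <- as.data.frame(config$paf)
    df <- as.data.frame(table)
    tot <- df[(is.na(df$rei) | df$rei == "" | df$rei == "none") &
                df$metric == "number", , drop = FALSE]
    j <- merge(tot, paf,
               by.x = c("location", "sex", "age", "year"),
               by.y = c("location", "sex", "age_group", "year"))
    j$attributable <- attributable_burden(j$val, j$paf)
    out$attributable <- data.frame(
      quantity = "attributable", measure = j$measure, location = j$location,
      sex = j$sex, age = j$age, year = j$year, risk = j$risk,
      val = j$attributable, stringsAsFactors = FALSE)
  }
  if (!is.null(config$sdi)) {
    sdi <- unlist(config$sdi)
    out$sdi_quintiles <- data.frame(
      quantity = "sdi_quintile", location = names(sdi), sdi = as.numeric(sdi),
      quintile = as.character(stratify_by_sdi(sdi)), stringsAsFactors = FALSE)
  }
  files <- character(0)
  for (nm in names(out)) {
    f <- file.path(out_dir, sprintf("%s.csv", nm))
    utils::write.csv(out[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  .write_manifest(config, out_dir, "burden_analysis", files)
  invisible(out)
}

#' Run the projection pipeline
#'
#' Fits the Bayesian APC model independently per (measure, sex) stratum
#' (no pooling across strata; a `both`-sex stratum is fitted on its own
#' pooled counts, not assembled from the sex-specific forecasts), projects
#' `horizon` years ahead, and writes forecast tables in the GBD dialect
#' (`quantity` = asir/asmr/asdr by measure, with `val`/`lower`/`upper`).
#' When `split_year` is set, a back-test report over the held-out window is
#' written as well.
#'
#' @param config See [load_config()]; requires `horizon` and a `model`
#'   block (arguments for [apc_spec()]).
#' @return Invisibly, a list with the forecast table and any back-test
#'   reports.
#' @export
run_projection <- function(config) {
  config <- load_config(config)
  check_that(!is.null(config$horizon), "config$horizon is required")
  table <- read_burden_table(config$burden_table)
  population <- read_population_grid(config$population)
  weights <- read_standard_population(config$standard_population)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strata <- config$strata %||%
    split(.table_strata(table), seq_len(nrow(.table_strata(table))))
  quantity_of <- c(incidence = "asir", deaths = "asmr", DALYs = "asdr",
                   prevalence = "aspr")
  fc_rows <- list(); reports <- list()
  for (st in strata) {
    grid <- to_lexis_grid(table, population, st$measure, st$location, st$sex)
    spec <- do.call(apc_spec, c(config$model %||% list(),
                                list(seed = config$seed)))
    fit <- fit_apc(grid, spec)
    fc <- apc_forecast(fit, config$horizon, weights = weights,
                       scenario = config$scenario)
    fc_rows[[length(fc_rows) + 1]] <- data.frame(
      quantity = unname(quantity_of[st$measure]), measure = st$measure,
      location = st$location, sex = st$sex, year = fc$summary$year,
      val = fc$summary$asr, lower = fc$summary$lower,
      upper = fc$summary$upper, stringsAsFactors = FALSE)
    if (!is.null(config$split_year)) {
      rep <- backtest(grid, spec, config$split_year)
      key <- paste(st$measure, st$sex, sep = "_")
      reports[[key]] <- rep
      validation_report_table(
        rep, file.path(out_dir, sprintf("backtest_%s.csv", key)))
    }
  }
  forecast_table <- do.call(rbind, fc_rows)
  f <- file.path(out_dir, "forecast.csv")
  utils::write.csv(forecast_table, f, row.names = FALSE)
  .write_manifest(config, out_dir, "projection", f)
  invisible(list(forecast = forecast_table, backtests = reports))
}
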