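#' @importFrom utils read.csv write.csv
NULL

# Required columns of the GBD results dialect.
gbd_columns <- c("measure", "location", "sex", "age", "cause", "rei",
                 "metric", "year", "val", "upper", "lower")

valid_measures <- c("incidence", "deaths", "DALYs", "prevalence")
valid_sexes    <- c("male", "female", "both")
valid_metrics  <- c("number", "rate")

#' Parse GBD-style age-group labels into integer bounds
#'
#' Labels are either closed ranges `"X to Y"` (e.g. `"0 to 4"`) or a terminal
#' open group `"Z plus"` (e.g. `"85 plus"`). The open group is assigned a
#' nominal upper bound so that its width equals the preceding group's width
#' (or `open_width` when it is the only group), giving a deterministic
#' cohort mapping.
#'
#' @param labels Character vector of age-group labels.
#' @param open_width Width assigned to a terminal open group when no
#'   preceding closed group is available. Default 5.
#' @return A data.frame with columns `age_group`, `lower`, `upper` (years,
#'   closed integer bounds), ordered as given.
#' @export
parse_age_groups <- function(labels, open_width = 5) {
  labels <- as.character(labels)
  lower <- upper <- rep(NA_real_, length(labels))
  for (i in seq_along(labels)) {
    lab <- trimws(labels[i])
    if (grepl("^[0-9]+ to [0-9]+$", lab)) {
      parts <- as.numeric(strsplit(lab, " to ", fixed = TRUE)[[1]])
      lower[i] <- parts[1]; upper[i] <- parts[2]
    } else if (grepl("^[0-9]+ plus$", lab)) {
      lower[i] <- as.numeric(sub(" plus$", "", lab))
      upper[i] <- NA_real_  # filled below
    } else if (grepl("^<[0-9]+$", lab)) {
      lower[i] <- 0; upper[i] <- as.numeric(sub("^<", "", lab)) - 1
    } else {
      stop(sprintf("unparseable age-group label: '%s'", lab), call. = FALSE)
    }
  }
  ord <- order(lower)
  widths <- upper - lower + 1
  for (i in seq_along(labels)) {
    if (is.na(upper[i])) {
      pos <- which(ord == i)
      w <- if (pos > 1) widths[ord[pos - 1]] else open_width
      if (is.na(w)) w <- open_width
      upper[i] <- lower[i] + w - 1
    }
  }
  data.frame(age_group = labels, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

#' Construct a validated burden table
#'
#' A burden table is a long-format data.frame in the GBD results dialect:
#' one record per (measure, location, sex, age, cause, rei, metric, year)
#' with a point value `val` and uncertainty bounds `lower`/`upper`.
#' `metric = "rate"` values are per 100,000 person-years.
#'
#' @param df A data.frame carrying at least the dialect's columns
#'   (`measure, location, sex, age, cause, rei, metric, year, val, upper,
#'   lower`). Extra columns are preserved.
#' @return The validated data.frame with class `burden_table`.
#' @export
burden_table <- function(df) {
  missing_cols <- setdiff(gbd_columns, names(df))
  check_that(length(missing_cols) == 0,
             "missing required column(s): %s", paste(missing_cols, collapse = ", "))
  df$year <- as.integer(df$year)
  for (col in c("val", "upper", "lower")) df[[col]] <- as.numeric(df[[col]])
  bad <- which(!(df$measure %in% valid_measures))
  check_that(length(bad) == 0, "invalid measure '%s' (record %d)",
             df$measure[bad[1]], bad[1])
  bad <- which(!(df$sex %in% valid_sexes))
  check_that(length(bad) == 0, "invalid sex '%s' (record %d)", df$sex[bad[1]], bad[1])
  bad <- which(!(df$metric %in% valid_metrics))
  check_that(length(bad) == 0, "invalid metric '%s' (record %d)",
             df$metric[bad[1]], bad[1])
  bad <- which(df$val < 0)
  check_that(length(bad) == 0, "negative value in record %d", bad[1])
  bad <- which(df$lower > df$val | df$val > df$upper)
  if (length(bad) > 0) {
    k <- bad[1]
    stop(sprintf(
      "value outside [lower, upper] for record (%s, %s, %s, %s, %s, %s, %d)",
      df$measure[k], df$location[k], df$sex[k], df$age[k], df$rei[k],
      df$metric[k], df$year[k]), call. = FALSE)
  }
  key <- do.call(paste, c(df[c("measure", "location", "sex", "age", "rei",
                               "metric", "year")], sep = "\r"))
  dup <- which(duplicated(key))
  check_that(length(dup) == 0, "duplicate key at record %d: %s",
             dup[1], gsub("\r", " | ", key[dup[1]]))
  # validate age labels parse
  parse_age_groups(unique(df$age))
  class(df) <- c("burden_table", "data.frame")
  df
}

#' Read a burden table from a GBD-results-dialect CSV file
#'
#' @param path Path to a comma-separated UTF-8 file whose header contains the
#'   dialect's required columns (`measure, location, sex, age, cause, rei,
#'   metric, year, val, upper, lower`). Unknown columns are preserved.
#' @param dialect Schema name; only `"gbd"` is supported.
#' @return A [burden_table()].
#' @export
read_burden_table <- function(path, dialect = "gbd") {
  check_that(identical(dialect, "gbd"), "unknown dialect '%s'", dialect)
  check_that(file.exists(path), "file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  burden_table(df)
}

#' Write a burden table as GBD-dialect CSV
#'
#' Round-trips with [read_burden_table()]: numeric columns are written with
#' full double precision (up to 15 significant digits).
#'
#' @param table A [burden_table()] (or compatible data.frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(table, path) {
  df <- as.data.frame(table)
  for (col in c("val", "upper", "lower")) {
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a standard-population weight table
#'
#' Standard populations are two-column CSV files (`age_group, weight`) with
#' nonnegative weights on an arbitrary scale; [compute_asr()] normalizes them,
#' so rescaling all weights leaves every downstream ASR unchanged. The
#' builtin `"who_world"` table is the WHO World Standard population
#' aggregated to eighteen 5-year groups (0 to 4 ... 85 plus). Comparative
#' claims across locations or studies require choosing the standard
#' explicitly; no silent default beyond this documented fixture is applied.
#'
#' @param source Path to a CSV file, or the builtin name `"who_world"`.
#' @return A named numeric vector of weights (names are age-group labels),
#'   with class `standard_population`.
#' @export
read_standard_population <- function(source = "who_world") {
  if (identical(source, "who_world")) {
    path <- system.file("extdata", "who_world_standard.csv",
                        package = "bapcburden", mustWork = TRUE)
  } else {
    check_that(file.exists(source), "file not found: %s", source)
    path <- source
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_that(nrow(df) > 0, "empty standard-population file: %s", path)
  check_that(all(c("age_group", "weight") %in% names(df)),
             "standard population needs columns age_group, weight")
  w <- as.numeric(df$weight)
  check_that(!anyNA(w) && all(w >= 0), "weights must be nonnegative reals")
  check_that(any(w > 0), "all-zero standard-population weights")
  names(w) <- as.character(df$age_group)
  ab <- parse_age_groups(names(w))
  ab <- ab[order(ab$lower), ]
  gaps <- ab$lower[-1] - ab$upper[-nrow(ab)]
  check_that(all(gaps == 1), "age groups must be non-overlapping and contiguous")
  class(w) <- "standard_population"
  w
}

#' Construct a population (person-years) grid
#'
#' @param n Matrix of person-years, `A` age groups (rows) by `T` years
#'   (columns); strictly positive.
#' @param age_groups Character vector of `A` age-group labels.
#' @param years Integer vector of `T` calendar years (consecutive).
#' @return An object of class `population_grid`.
#' @export
population_grid <- function(n, age_groups, years) {
  n <- as.matrix(n)
  check_that(nrow(n) == length(age_groups), "nrow(n) must equal length(age_groups)")
  check_that(ncol(n) == length(years), "ncol(n) must equal length(years)")
  check_that(all(is.finite(n)) && all(n > 0), "person-years must be strictly positive")
  check_that(all(diff(as.integer(years)) == 1L), "years must be consecutive")
  dimnames(n) <- list(age_groups, years)
  structure(list(n = n, age_groups = as.character(age_groups),
                 years = as.integer(years)),
            class = "population_grid")
}

#' Read or write a population grid as long-format CSV
#'
#' The file has columns `age_group, year, person_years`, one row per cell.
#'
#' @param path CSV file path.
#' @return A [population_grid()].
#' @export
read_population_grid <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("age_group", "year", "person_years") %in% names(df)),
             "population grid needs columns age_group, year, person_years")
  ab <- parse_age_groups(unique(df$age_group))
  ages <- ab$age_group[order(ab$lower)]
  years <- sort(unique(df$year))
  n <- matrix(NA_real_, length(ages), length(years))
  n[cbind(match(df$age_group, ages), match(df$year, years))] <- df$person_years
  check_that(!anyNA(n), "population grid has missing (age_group, year) cells")
  population_grid(n, ages, years)
}

#' @rdname read_population_grid
#' @param population A [population_grid()] to write.
#' @export
write_population_grid <- function(population, path) {
  df <- data.frame(
    age_group = rep(population$age_groups, times = length(population$years)),
    year = rep(population$years, each = length(population$age_groups)),
    person_years = formatC(as.numeric(population$n), digits = 17,
                           format = "g"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a Lexis grid of event counts and person-years
#'
#' The grid holds counts `y[a, t]` and exposures `n[a, t]` over `A` age
#' groups and `T` annual periods, with the diagonal cohort index
#' `c(a, t) = M * (A - a) + t` (age group 1 = youngest, `M` = age-group
#' width in period units), so the oldest age at the first period is cohort 1.
#'
#' @param y Count matrix (`A` x `T`), nonnegative.
#' @param n Person-years matrix (`A` x `T`), strictly positive.
#' @param age_groups,years Labels as in [population_grid()].
#' @param age_width Age-group width `M` in period units (default 5).
#' @return An object of class `lexis_grid` with elements `y`, `n`,
#'   `age_groups`, `years`, `age_width`, `cohort` (index matrix) and
#'   `n_cohorts`.
#' @export
lexis_grid <- function(y, n, age_groups, years, age_width = 5) {
  y <- as.matrix(y); n <- as.matrix(n)
  check_that(all(dim(y) == dim(n)), "y and n must have identical dimensions")
  check_that(nrow(y) == length(age_groups) && ncol(y) == length(years),
             "dimensions must match age_groups x years")
  check_that(all(is.finite(y)) && all(y >= 0), "counts must be nonnegative")
  check_that(all(is.finite(n)) && all(n > 0), "person-years must be positive")
  A <- nrow(y); Tn <- ncol(y)
  cohort <- build_cohort_index(A, Tn, age_width)
  dimnames(y) <- dimnames(n) <- list(age_groups, years)
  structure(list(y = y, n = n, age_groups = as.character(age_groups),
                 years = as.integer(years), age_width = as.integer(age_width),
                 cohort = cohort, n_cohorts = max(cohort)),
            class = "lexis_grid")
}

#' @export
print.lexis_grid <- function(x, ...) {
  cat(sprintf("<lexis_grid> %d age groups x %d years (%d-%d), M = %d, %d cohorts\n",
              nrow(x$y), ncol(x$y), min(x$years), max(x$years),
              x$age_width, x$n_cohorts))
  cat(sprintf("  total events %.0f over %.3g person-years\n",
              sum(x$y), sum(x$n)))
  invisible(x)
}

#' Assemble a Lexis grid from a burden table and a population grid
#'
#' Selects the records of one (measure, location, sex) stratum and aligns
#' them with the population grid. `metric = "number"` records are used
#' directly; if absent for a cell, `metric = "rate"` records (per 100,000)
#' are converted via `count = rate * n / 100000`. Missing cells raise an
#' error naming them unless `allow_missing = TRUE`, in which case they are
#' returned in the `missing` element and their counts set to `NA` (never
#' silently zero-filled).
#'
#' @param table A [burden_table()].
#' @param population A [population_grid()].
#' @param measure,location,sex Stratum selectors.
#' @param cause Optional cause filter (default: all records of the stratum).
#' @param age_width Age width `M` in period units (default 5).
#' @param allow_missing Keep going when cells are absent (default FALSE).
#' @return A [lexis_grid()] (with attribute `missing` when allowed).
#' @export
to_lexis_grid <- function(table, population, measure, location, sex,
                          cause = NULL, age_width = 5, allow_missing = FALSE) {
  df <- as.data.frame(table)
  keep <- df$measure == measure & df$location == location & df$sex == sex &
    (is.na(df$rei) | df$rei == "" | df$rei == "none")
  if (!is.null(cause)) keep <- keep & df$cause == cause
  df <- df[keep, , drop = FALSE]
  check_that(nrow(df) > 0, "no records for stratum (%s, %s, %s)",
             measure, location, sex)
  A <- length(population$age_groups); Tn <- length(population$years)
  y <- matrix(NA_real_, A, Tn)
  num <- df[df$metric == "number", , drop = FALSE]
  rat <- df[df$metric == "rate", , drop = FALSE]
  ai <- match(num$age, population$age_groups)
  ti <- match(num$year, population$years)
  ok <- !is.na(ai) & !is.na(ti)
  y[cbind(ai[ok], ti[ok])] <- num$val[ok]
  if (anyNA(y) && nrow(rat) > 0) {
    ai <- match(rat$age, population$age_groups)
    ti <- match(rat$year, population$years)
    ok <- !is.na(ai) & !is.na(ti)
    idx <- cbind(ai[ok], ti[ok])
    fill <- is.na(y[idx])
    y[idx[fill, , drop = FALSE]] <-
      rat$val[ok][fill] * population$n[idx[fill, , drop = FALSE]] / 1e5
  }
  if (anyNA(y)) {
    miss <- which(is.na(y), arr.ind = TRUE)
    labels <- sprintf("(%s, %d)", population$age_groups[miss[, 1]],
                      population$years[miss[, 2]])
    if (!allow_missing) {
      stop(sprintf("missing cell(s) in stratum (%s, %s, %s): %s",
                   measure, location, sex,
                   paste(utils::head(labels, 10), collapse = "; ")),
           call. = FALSE)
    }
    grid <- lexis_grid(ifelse(is.na(y), 0, y), population$n,
                       population$age_groups, population$years, age_width)
    attr(grid, "missing") <- labels
    return(grid)
  }
  lexis_grid(y, population$n, population$age_groups, population$years,
             age_width)
}
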