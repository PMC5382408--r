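# Aggregated registry tables: construction, validation, CSV exchange.

#' Registry CSV schema and registration types
#'
#' `REGISTRY_COLUMNS` is the exact column set of the registry exchange CSV;
#' `REGISTRY_TYPES` the two registration mechanisms.
#'
#' @export
REGISTRY_COLUMNS <- c(
  "network", "disease", "sex", "age_lo", "age_hi", "person_years",
  "n_registered", "prev_count", "inc_count", "deaths_with_disease",
  "inst_with_disease", "seen_in_window"
)

#' @rdname REGISTRY_COLUMNS
#' @export
REGISTRY_TYPES <- c("episode_of_care", "episode_of_disease")

#' Canonical age bands
#'
#' Half-open integer age bands partitioning \[0, 100). Five-year bands are the
#' canonical exchange granularity; internal computation runs on a single-year
#' grid 0--99 with band rates applied uniformly within a band.
#'
#' @param width band width in years (default 5)
#' @param max_age exclusive upper bound of the grid (default 100)
#' @return data.frame with columns `age_lo`, `age_hi`
#' @export
age_bands <- function(width = 5, max_age = 100) {
  lo <- seq(0L, max_age - width, by = width)
  data.frame(age_lo = lo, age_hi = lo + width)
}

#' Construct a registry table
#'
#' An aggregated GP-registry table: one row per network x disease x sex x
#' age-band stratum, carrying person-years, the registered population on
#' 1 January, point-prevalent and incident counts, and deaths and
#' institutionalizations among the diseased. The registration mechanism
#' (episode of care vs episode of disease) and the lookback window used to
#' separate incident from prevalent cases are table-level metadata.
#'
#' When `n_registered` is missing it is imputed as `round(person_years)`,
#' assuming a stable population.
#'
#' @param rows data.frame with the columns in [REGISTRY_COLUMNS]
#'   (`seen_in_window` may be `NA` for episode-of-disease tables)
#' @param registry_type `"episode_of_care"` or `"episode_of_disease"`
#' @param lookback_years non-negative integer; years before the index year
#'   searched for prior disease-coded contacts
#' @param check validate and stop on violations (default TRUE)
#' @return object of class `registry_table` (a data.frame with attributes
#'   `registry_type` and `lookback_years`)
#' @seealso [validate_table()], [read_registry_table()]
#' @export
registry_table <- function(rows, registry_type = "episode_of_disease",
                           lookback_years = 0L, check = TRUE) {
  registry_type <- match.arg(registry_type, REGISTRY_TYPES)
  if (!is.data.frame(rows)) stop("`rows` must be a data.frame")
  missing_cols <- setdiff(setdiff(REGISTRY_COLUMNS, "seen_in_window"),
                          names(rows))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"seen_in_window" %in% names(rows)) rows$seen_in_window <- NA_real_
  rows <- rows[, REGISTRY_COLUMNS]
  num_cols <- setdiff(REGISTRY_COLUMNS, c("network", "disease", "sex"))
  for (cc in num_cols) {
    v <- rows[[cc]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric cell in column '%s', row %d: '%s'",
                     cc, bad[1], v[bad[1]]))
      }
      rows[[cc]] <- suppressWarnings(as.numeric(v))
    }
  }
  miss_n <- is.na(rows$n_registered)
  if (any(miss_n)) rows$n_registered[miss_n] <- round(rows$person_years[miss_n])
  lookback_years <- as.integer(lookback_years)
  if (is.na(lookback_years) || lookback_years < 0) {
    stop("`lookback_years` must be a non-negative integer")
  }
  out <- structure(rows,
                   class = c("registry_table", "data.frame"),
                   registry_type = registry_type,
                   lookback_years = lookback_years)
  if (check) {
    v <- validate_table(out)
    if (nrow(v) > 0) {
      stop("invalid registry table:\n",
           paste(utils::head(v$message, 10), collapse = "\n"))
    }
  }
  out
}

#' @export
#' @rdname registry_table
registry_type <- function(t) attr(t, "registry_type")

#' @export
#' @rdname registry_table
lookback_years <- function(t) attr(t, "lookback_years")

violation <- function(network, disease, sex, age_lo, field, rule) {
  data.frame(network = as.character(network), disease = as.character(disease),
             sex = as.character(sex), age_lo = age_lo, field = field,
             rule = rule,
             message = sprintf("[%s/%s/%s/age %s] %s: %s",
                               network, disease, sex, age_lo, field, rule),
             stringsAsFactors = FALSE)
}

#' Validate a registry table
#'
#' Total validator: never raises on syntactically valid input; violations are
#' returned as data. Checks stratum uniqueness, count invariants
#' (`prev_count <= n_registered`,
#' `deaths_with_disease + inst_with_disease <= prev_count + inc_count`),
#' non-negativity, band bounds, and that the bands of each
#' network x disease x sex series partition \[0, 100) without gaps or overlaps.
#'
#' @param t a `registry_table` (or plain data.frame with the same columns)
#' @return data.frame of violation records (zero rows when valid), with
#'   columns network, disease, sex, age_lo, field, rule, message
#' @export
validate_table <- function(t) {
  out <- list()
  add <- function(v) out[[length(out) + 1]] <<- v
  for (k in seq_len(nrow(t))) {
    r <- t[k, ]
    ctx <- list(r$network, r$disease, r$sex, r$age_lo)
    chk <- function(cond, field, rule) {
      if (isTRUE(cond)) add(violation(ctx[[1]], ctx[[2]], ctx[[3]], ctx[[4]],
                                      field, rule))
    }
    chk(is.na(r$age_lo) || is.na(r$age_hi) || r$age_lo < 0 ||
          r$age_hi > 100 || r$age_lo >= r$age_hi,
        "age_band", "requires 0 <= age_lo < age_hi <= 100")
    for (cc in c("person_years", "n_registered", "prev_count", "inc_count",
                 "deaths_with_disease", "inst_with_disease")) {
      chk(!is.na(r[[cc]]) && r[[cc]] < 0, cc, "must be non-negative")
    }
    chk(!is.na(r$prev_count) && !is.na(r$n_registered) &&
          r$prev_count > r$n_registered,
        "prev_count", "exceeds n_registered")
    chk(!is.na(r$deaths_with_disease) && !is.na(r$inst_with_disease) &&
          r$deaths_with_disease + r$inst_with_disease >
            r$prev_count + r$inc_count,
        "deaths_with_disease",
        "deaths + institutionalizations exceed prev_count + inc_count")
    chk(!r$sex %in% c("f", "m"), "sex", "must be 'f' or 'm'")
    if (identical(attr(t, "registry_type"), "episode_of_care")) {
      chk(is.na(r$seen_in_window), "seen_in_window",
          "required for episode_of_care tables")
      chk(!is.na(r$seen_in_window) && r$seen_in_window < r$inc_count,
          "seen_in_window", "smaller than inc_count")
    }
  }
  # band partition per series
  key <- paste(t$network, t$disease, t$sex, sep = "\r")
  for (g in unique(key)) {
    s <- t[key == g, c("age_lo", "age_hi")]
    s <- s[order(s$age_lo), , drop = FALSE]
    if (any(is.na(s$age_lo)) || any(is.na(s$age_hi))) next
    first <- t[key == g, ][1, ]
    bad <- function(rule) add(violation(first$network, first$disease,
                                        first$sex, s$age_lo[1], "age_band",
                                        rule))
    if (anyDuplicated(s$age_lo)) bad("duplicate age bands")
    if (s$age_lo[1] != 0 || s$age_hi[nrow(s)] != 100) {
      bad("bands must span [0,100)")
    }
    if (nrow(s) > 1) {
      d <- s$age_lo[-1] - s$age_hi[-nrow(s)]
      if (any(d > 0)) bad("gap between bands")
      if (any(d < 0)) bad("overlapping bands")
    }
  }
  if (length(out) == 0) {
    violation(character(), character(), character(), numeric(),
              character(), character())[0, ]
  } else {
    do.call(rbind, out)
  }
}

#' Read a registry table from CSV
#'
#' Expects the column schema of [REGISTRY_COLUMNS] (header mandatory, UTF-8,
#' "." decimal separator, empty cell = missing). Two optional metadata columns,
#' `registry_type` and `lookback_years` (constant over rows), carry the
#' table-level fields through a round trip; absent, they default to
#' `episode_of_disease` / 0.
#'
#' @param path CSV file path
#' @return a validated [registry_table()]
#' @export
read_registry_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  rtype <- "episode_of_disease"
  lb <- 0L
  if ("registry_type" %in% names(raw)) {
    rtype <- unique(raw$registry_type)
    if (length(rtype) != 1) stop("registry_type must be constant over rows")
  }
  if ("lookback_years" %in% names(raw)) {
    lb <- unique(raw$lookback_years)
    if (length(lb) != 1) stop("lookback_years must be constant over rows")
  }
  registry_table(raw[, intersect(names(raw), REGISTRY_COLUMNS)],
                 registry_type = rtype, lookback_years = lb)
}

#' Write a registry table to CSV
#'
#' Inverse of [read_registry_table()]; the metadata attributes are written as
#' the `registry_type` / `lookback_years` columns so that read-after-write is
#' the identity.
#'
#' @param t a `registry_table`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_registry_table <- function(t, path) {
  df <- as.data.frame(t)
  df$registry_type <- registry_type(t)
  df$lookback_years <- lookback_years(t)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a standard population
#'
#' Stratum weights for direct age-sex standardization. Raw weights (e.g.
#' population counts) are renormalized to sum to one; a message records the
#' rescaling.
#'
#' @param df data.frame with columns sex, age_lo, age_hi, weight
#' @return object of class `standard_population`
#' @export
standard_population <- function(df) {
  need <- c("sex", "age_lo", "age_hi", "weight")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, need]
  if (any(is.na(df$weight)) || !is.numeric(df$weight)) {
    stop("weights must be numeric and non-missing")
  }
  if (any(df$weight < 0)) stop("negative weight in standard population")
  s <- sum(df$weight)
  if (s <= 0) stop("standard population weights sum to zero")
  if (abs(s - 1) > 1e-9) {
    message(sprintf("renormalizing standard population weights (sum = %g)", s))
    df$weight <- df$weight / s
  }
  structure(df, class = c("standard_population", "data.frame"))
}

#' Read a standard population from CSV
#'
#' @param path CSV with columns sex, age_lo, age_hi, weight
#' @return a [standard_population()] with weights normalized to sum 1
#' @export
read_standard_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  standard_population(utils::read.csv(path, stringsAsFactors = FALSE))
}
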