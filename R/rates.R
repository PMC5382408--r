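# Observed incidence/prevalence, direct standardization, summaries across
# networks, and the period life-table check on registry mortality.

#' Person-years free of disease
#'
#' Half-period bookkeeping: point-prevalent cases contribute no disease-free
#' time, incident cases contribute half a year before onset is registered, and
#' diseased persons leaving by death or institutionalization hand back half a
#' year. Floored at zero.
#'
#' @param person_years total person-years in the stratum
#' @param prev_count point-prevalent cases on 1 January
#' @param inc_count incident cases during the year
#' @param deaths_with_disease deaths among the diseased
#' @param inst_with_disease institutionalizations among the diseased
#' @return disease-free person-years (vectorized)
#' @export
person_years_at_risk <- function(person_years, prev_count, inc_count,
                                 deaths_with_disease = 0,
                                 inst_with_disease = 0) {
  pmax(0, person_years - prev_count - 0.5 * inc_count +
         0.5 * (deaths_with_disease + inst_with_disease))
}

#' Observed incidence density
#'
#' New cases per person-year free of disease.
#'
#' @inheritParams person_years_at_risk
#' @return incidence rate per person-year (vectorized)
#' @export
observed_incidence <- function(person_years, prev_count, inc_count,
                               deaths_with_disease = 0,
                               inst_with_disease = 0) {
  py_free <- person_years_at_risk(person_years, prev_count, inc_count,
                                  deaths_with_disease, inst_with_disease)
  if (any(py_free <= 0)) stop("no disease-free exposure in stratum")
  inc_count / py_free
}

#' Observed point prevalence
#'
#' Episode-of-disease registries count open disease episodes on 1 January:
#' `prev_count / n_registered`. Episode-of-care registries only see a chronic
#' disease when the patient contacts the GP, so prevalence is reconstructed
#' from the patients seen for the disease anywhere in the lookback window,
#' minus those first seen in the index year (the incident cases):
#' `(seen_in_window - inc_count) / n_registered`.
#'
#' @param n_registered patients registered on 1 January
#' @param prev_count point-prevalent cases (episode-of-disease)
#' @param inc_count incident cases in the index year
#' @param seen_in_window patients with any disease-coded contact in the
#'   window (episode-of-care only)
#' @param registry_type `"episode_of_disease"` or `"episode_of_care"`
#' @return prevalence proportion in \[0, 1\] (vectorized)
#' @export
observed_prevalence <- function(n_registered, prev_count, inc_count = 0,
                                seen_in_window = NA,
                                registry_type = "episode_of_disease") {
  registry_type <- match.arg(registry_type, REGISTRY_TYPES)
  if (any(n_registered <= 0)) stop("n_registered must be positive")
  if (registry_type == "episode_of_disease") {
    prev_count / n_registered
  } else {
    if (any(is.na(seen_in_window))) {
      stop("episode_of_care prevalence requires seen_in_window")
    }
    if (any(seen_in_window < inc_count)) {
      stop("seen_in_window smaller than inc_count")
    }
    (seen_in_window - inc_count) / n_registered
  }
}

#' Observed rates for every stratum of a registry table
#'
#' @param t a [registry_table()]
#' @return data.frame: stratum keys plus `py_free`, `incidence`
#'   (per person-year), `prevalence` (proportion)
#' @export
observed_rates <- function(t) {
  py_free <- person_years_at_risk(t$person_years, t$prev_count, t$inc_count,
                                  t$deaths_with_disease, t$inst_with_disease)
  inc <- ifelse(py_free > 0, t$inc_count / py_free, NA_real_)
  prev <- rep(NA_real_, nrow(t))
  pos <- t$n_registered > 0
  if (any(pos)) {
    prev[pos] <- observed_prevalence(t$n_registered[pos], t$prev_count[pos],
                                     t$inc_count[pos], t$seen_in_window[pos],
                                     registry_type(t))
  }
  data.frame(network = t$network, disease = t$disease, sex = t$sex,
             age_lo = t$age_lo, age_hi = t$age_hi, py_free = py_free,
             incidence = inc, prevalence = prev, stringsAsFactors = FALSE)
}

#' Construct a rate schedule
#'
#' Age-sex stratified rates: incidence per person-year, prevalence as a
#' proportion, or mortality as an annual probability.
#'
#' @param df data.frame with columns sex, age_lo, age_hi, value
#' @param kind one of "incidence", "prevalence", "mortality"
#' @return object of class `rate_schedule`
#' @export
rate_schedule <- function(df, kind = c("incidence", "prevalence", "mortality")) {
  kind <- match.arg(kind)
  need <- c("sex", "age_lo", "age_hi", "value")
  if (!all(need %in% names(df))) {
    stop("rate schedule needs columns ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (any(df$value < 0, na.rm = TRUE)) stop("negative rate")
  if (kind %in% c("prevalence", "mortality") &&
      any(df$value > 1, na.rm = TRUE)) {
    stop(kind, " values must lie in [0, 1]")
  }
  structure(df, class = c("rate_schedule", "data.frame"), kind = kind)
}

#' A standardized rate per 1,000 with optional percentile CI
#'
#' @param value point estimate per 1,000
#' @param ci_lo,ci_hi optional 95% bounds per 1,000
#' @param se_log optional standard error on the log scale
#' @return object of class `standardized_rate`
#' @export
standardized_rate <- function(value, ci_lo = NA_real_, ci_hi = NA_real_,
                              se_log = NA_real_) {
  if (!is.na(ci_lo) && !is.na(ci_hi) && !(ci_lo <= value && value <= ci_hi)) {
    stop("ci_lo <= value <= ci_hi violated")
  }
  structure(list(value = value, ci_lo = ci_lo, ci_hi = ci_hi,
                 se_log = se_log),
            class = "standardized_rate")
}

#' @export
print.standardized_rate <- function(x, ...) {
  ci <- if (!is.na(x$ci_lo)) sprintf(" (%.2f - %.2f)", x$ci_lo, x$ci_hi) else ""
  cat(sprintf("%.3f per 1,000%s\n", x$value, ci))
  invisible(x)
}

#' Direct age-sex standardization
#'
#' Weights stratum-specific rates by a fixed standard population's stratum
#' shares: `1000 * sum(w_s * r_s)`.
#'
#' @param r a [rate_schedule()]
#' @param w a [standard_population()] on the identical (sex, band) strata
#' @return a [standardized_rate()] (no CI)
#' @export
direct_standardize <- function(r, w) {
  m <- merge(as.data.frame(w), as.data.frame(r),
             by = c("sex", "age_lo", "age_hi"), all.x = TRUE)
  if (any(is.na(m$value))) {
    miss <- m[is.na(m$value), c("sex", "age_lo", "age_hi")]
    stop("rate schedule missing strata: ",
         paste(sprintf("%s[%d,%d)", miss$sex, miss$age_lo, miss$age_hi),
               collapse = ", "))
  }
  if (nrow(m) < nrow(r)) {
    warning("rate schedule has strata absent from the standard population")
  }
  standardized_rate(1000 * sum(m$weight * m$value))
}

rate_values <- function(rates) {
  vapply(rates, function(x) {
    if (inherits(x, "standardized_rate")) x$value else as.numeric(x)
  }, numeric(1))
}

#' Simple mean of standardized rates over networks
#'
#' Unweighted arithmetic mean of network-specific standardized rates; no CI
#' is attached.
#'
#' @param rates list of [standardized_rate()] objects or a numeric vector
#'   (per 1,000)
#' @return a [standardized_rate()]
#' @export
simple_mean <- function(rates) {
  if (is.numeric(rates)) rates <- as.list(rates)
  if (length(rates) == 0) stop("empty rate list")
  standardized_rate(mean(rate_values(rates)))
}

#' Max/min ratio of standardized rates
#'
#' Spread of network estimates: highest divided by lowest.
#'
#' @inheritParams simple_mean
#' @return ratio as a plain number
#' @export
max_min_ratio <- function(rates) {
  if (is.numeric(rates)) rates <- as.list(rates)
  if (length(rates) == 0) stop("empty rate list")
  v <- rate_values(rates)
  if (min(v) <= 0) stop("minimum rate is zero; ratio undefined")
  max(v) / min(v)
}

#' Period life expectancy from annual death probabilities
#'
#' Direct life-table summation with the half-year convention: survivors of a
#' year contribute one year, those dying contribute half. The grid is capped
#' at age 99; everyone still alive in the cap year dies during it (documented
#' truncation).
#'
#' @param q annual death probabilities for ages `from_age` to 99 (a numeric
#'   vector of length `100 - from_age`)
#' @param from_age age at which the expectancy is evaluated (default 0)
#' @return remaining life expectancy in years
#' @export
life_expectancy <- function(q, from_age = 0) {
  n_needed <- 100 - from_age
  if (length(q) < n_needed) {
    stop(sprintf("need death probabilities for ages %d..99 (%d values, got %d)",
                 from_age, n_needed, length(q)))
  }
  q <- q[seq_len(n_needed)]
  if (any(is.na(q)) || any(q < 0) || any(q > 1)) {
    stop("death probabilities must lie in [0, 1]")
  }
  q[n_needed] <- 1  # cap: everyone alive at 99 dies in that year
  l <- cumprod(c(1, 1 - q[-n_needed]))
  sum(l * (1 - q)) + 0.5 * sum(l * q)
}

#' Half-up rounding for presentation
#'
#' Standard commercial rounding (0.5 always rounds away from zero), used when
#' printing per-1,000 rates: one decimal for incidence, whole numbers for
#' prevalence.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname round_half_up
#' @param measure "incidence" (one decimal) or "prevalence" (integer)
#' @export
present_rate <- function(x, measure = c("incidence", "prevalence")) {
  measure <- match.arg(measure)
  round_half_up(x, digits = if (measure == "incidence") 1 else 0)
}
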