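# Discrete-time illness-death cohort projection and the observed-vs-projected
# prevalence consistency check.
#
# Annual forward recursion on ages 0..99, all flows computed from the
# start-of-year state:
#   S(a+1) = S(a) * (1 - i(a) - m(a))
#   C(a+1) = C(a) * (1 - m(a) - f(a) - r(a)) + S(a) * i(a)
# S = disease-free occupancy, C = diseased occupancy; i incidence, m general
# mortality, f excess mortality of the diseased, r institutionalization.
# Chronic diseases: no remission state.

AGE_GRID <- 0:99

expand_to_grid <- function(x, ages = AGE_GRID, bands = NULL) {
  if (length(x) == 1) return(rep(x, length(ages)))
  if (length(x) == length(ages)) return(x)
  if (!is.null(bands) && length(x) == nrow(bands)) {
    idx <- findInterval(ages, bands$age_lo)
    return(x[idx])
  }
  stop("rate vector must be scalar, per-age, or per-band")
}

#' Age-specific transition schedules for the illness-death model
#'
#' Annual transition probabilities on the single-year grid 0--99 for one sex:
#' incidence `i`, general mortality `m`, excess mortality of the diseased `f`,
#' and institutionalization of the diseased `r`. Scalars are recycled; band
#' vectors are expanded by constant interpolation when `bands` is supplied.
#'
#' @param i,m,f,r annual probabilities (scalar, length-100, or per band)
#' @param bands optional data.frame (age_lo, age_hi) matching band-length
#'   inputs
#' @return object of class `disease_schedules`: list with per-age vectors
#'   `i`, `m`, `f`, `r` and `ages`
#' @export
disease_schedules <- function(i, m, f = 0, r = 0, bands = NULL) {
  s <- list(ages = AGE_GRID,
            i = expand_to_grid(i, bands = bands),
            m = expand_to_grid(m, bands = bands),
            f = expand_to_grid(f, bands = bands),
            r = expand_to_grid(r, bands = bands))
  for (nm in c("i", "m", "f", "r")) {
    v <- s[[nm]]
    if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
      stop("schedule '", nm, "' must lie in [0, 1]")
    }
  }
  if (any(s$i + s$m > 1)) stop("i(a) + m(a) exceeds 1")
  if (any(s$m + s$f + s$r > 1)) stop("m(a) + f(a) + r(a) exceeds 1")
  structure(s, class = "disease_schedules")
}

#' Project a hypothetical birth cohort through the illness-death model
#'
#' Applies the disease inflow (incidence) and outflow (mortality and
#' institutionalization of the diseased) of a network to a cohort of newborns,
#' assuming stable rates over time. Occupancies are reported at every integer
#' age as start-of-year state; `S(0) = 1`, `C(0) = 0`.
#'
#' @param s a [disease_schedules()]
#' @return data.frame of class `cohort_state`: age, `S` (disease-free), `C`
#'   (diseased), `cum_dead`, `cum_inst`; rows for ages 0..99
#' @export
project_cohort <- function(s) {
  if (!inherits(s, "disease_schedules")) stop("expected disease_schedules")
  n <- length(s$ages)
  S <- C <- dead <- inst <- numeric(n)
  S[1] <- 1
  for (k in seq_len(n - 1)) {
    S[k + 1] <- S[k] * (1 - s$i[k] - s$m[k])
    C[k + 1] <- C[k] * (1 - s$m[k] - s$f[k] - s$r[k]) + S[k] * s$i[k]
    dead[k + 1] <- dead[k] + S[k] * s$m[k] + C[k] * (s$m[k] + s$f[k])
    inst[k + 1] <- inst[k] + C[k] * s$r[k]
  }
  structure(data.frame(age = s$ages, S = S, C = C,
                       cum_dead = dead, cum_inst = inst),
            class = c("cohort_state", "data.frame"))
}

#' Projected prevalence from a cohort state
#'
#' Single-year prevalence `p(a) = C(a) / (S(a) + C(a))`; band values are the
#' occupancy-weighted mean of single-year prevalence within the band
#' (equivalently `sum(C) / sum(S + C)` over the band's ages). Ages where the
#' cohort is extinct are reported as missing.
#'
#' @param c a `cohort_state` from [project_cohort()]
#' @param bands optional data.frame (age_lo, age_hi); when given, a banded
#'   [rate_schedule()] for sex `sex` is returned instead of per-age values
#' @param sex sex label for the banded schedule (default "f")
#' @return numeric vector over ages 0..99, or a prevalence [rate_schedule()]
#' @export
projected_prevalence <- function(c, bands = NULL, sex = "f") {
  alive <- c$S + c$C
  p <- ifelse(alive > 0, c$C / alive, NA_real_)
  if (is.null(bands)) return(p)
  val <- vapply(seq_len(nrow(bands)), function(k) {
    in_band <- c$age >= bands$age_lo[k] & c$age < bands$age_hi[k]
    denom <- sum(alive[in_band])
    if (denom > 0) sum(c$C[in_band]) / denom else NA_real_
  }, numeric(1))
  rate_schedule(data.frame(sex = sex, age_lo = bands$age_lo,
                           age_hi = bands$age_hi, value = val),
                kind = "prevalence")
}

#' Observed vs projected prevalence consistency report
#'
#' Per-stratum difference (projected - observed) and ratio
#' (projected / observed; missing when observed is zero), summarized by the
#' mean absolute difference. A close match means the network's incidence,
#' prevalence and mortality are mutually consistent under stationarity.
#'
#' @param observed,projected prevalence [rate_schedule()]s on identical
#'   (sex, band) strata
#' @return data.frame of class `consistency_report` with attribute `mad`
#'   (mean absolute difference)
#' @export
consistency_report <- function(observed, projected) {
  m <- merge(as.data.frame(observed), as.data.frame(projected),
             by = c("sex", "age_lo", "age_hi"),
             suffixes = c("_obs", "_proj"))
  if (nrow(m) != nrow(observed) || nrow(m) != nrow(projected)) {
    stop("observed and projected schedules have mismatching strata")
  }
  m <- m[order(m$sex, m$age_lo), ]
  rownames(m) <- NULL
  names(m)[names(m) == "value_obs"] <- "observed"
  names(m)[names(m) == "value_proj"] <- "projected"
  m$difference <- m$projected - m$observed
  m$ratio <- ifelse(m$observed > 0, m$projected / m$observed, NA_real_)
  structure(m, class = c("consistency_report", "data.frame"),
            mad = mean(abs(m$difference), na.rm = TRUE))
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency report: %d strata, mean |projected - observed| = %.4g\n",
              nrow(x), attr(x, "mad")))
  print.data.frame(x, ...)
  invisible(x)
}
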