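# Patient-level synthetic GP registries: a true illness-death process observed
# through episode-of-disease or episode-of-care registration with an annual
# contact probability and a lookback window.
#
# The simulator is a stochastic realization of the projection recursion in
# project_cohort(): per year, a disease-free person acquires the disease with
# probability i(a) or dies with m(a) (mutually exclusive); a person diseased at
# the start of the year dies with m(a) + f(a) or is institutionalized with
# r(a); new onsets face the diseased outflow from the next year on. Prevalent
# at the index date therefore means onset strictly before the index age.

#' Truth configuration for the synthetic registry
#'
#' @param disease disease label (free text)
#' @param schedules named list (`"f"`, `"m"`) of [disease_schedules()]; a
#'   single `disease_schedules` is used for both sexes
#' @param population total number of simulated persons (births across birth
#'   cohorts, both sexes)
#' @param age_weights length-100 non-negative weights allocating persons to
#'   age-at-index 0..99 (default uniform); the realized index-year age
#'   structure is additionally shaped by survival
#' @return object of class `truth_config`
#' @export
truth_config <- function(disease, schedules, population,
                         age_weights = NULL) {
  if (inherits(schedules, "disease_schedules")) {
    schedules <- list(f = schedules, m = schedules)
  }
  stopifnot(all(c("f", "m") %in% names(schedules)))
  if (population <= 0) stop("population must be positive")
  if (is.null(age_weights)) age_weights <- rep(1, 100)
  if (length(age_weights) != 100 || any(age_weights < 0) ||
      sum(age_weights) <= 0) {
    stop("age_weights must be 100 non-negative values")
  }
  structure(list(disease = disease, schedules = schedules,
                 population = population,
                 age_weights = age_weights / sum(age_weights)),
            class = "truth_config")
}

#' Observation configuration for registry extraction
#'
#' @param registry_type `"episode_of_care"` or `"episode_of_disease"`
#' @param contact_prob annual probability that a prevalent case has a
#'   disease-coded GP contact, in (0, 1\]
#' @param lookback_years years before the index year searched for prior
#'   contacts when classifying incident vs prevalent (episode-of-care)
#' @param mortality_underreport fraction of deaths among the diseased missing
#'   from the registry, in \[0, 1)
#' @return object of class `observation_config`
#' @export
observation_config <- function(registry_type = "episode_of_disease",
                               contact_prob = 1, lookback_years = 0L,
                               mortality_underreport = 0) {
  registry_type <- match.arg(registry_type, REGISTRY_TYPES)
  if (contact_prob <= 0 || contact_prob > 1) {
    stop("contact_prob must lie in (0, 1]")
  }
  lookback_years <- as.integer(lookback_years)
  if (lookback_years < 0 || lookback_years > 99) {
    stop("lookback_years must lie in [0, 99]")
  }
  if (mortality_underreport < 0 || mortality_underreport >= 1) {
    stop("mortality_underreport must lie in [0, 1)")
  }
  structure(list(registry_type = registry_type, contact_prob = contact_prob,
                 lookback_years = lookback_years,
                 mortality_underreport = mortality_underreport),
            class = "observation_config")
}

simulate_truth_sex <- function(n, A, sch) {
  status <- integer(n)  # 0 healthy, 1 diseased, 2 dead, 3 institutionalized
  onset <- death <- inst <- rep(NA_integer_, n)
  for (t in 0:max(A)) {
    act <- which(status <= 1L & A >= t)
    if (length(act) == 0) next
    st <- status[act]
    h <- act[st == 0L]
    dz <- act[st == 1L]
    if (length(h) > 0) {
      u <- stats::runif(length(h))
      on <- u < sch$i[t + 1]
      de <- !on & u < sch$i[t + 1] + sch$m[t + 1]
      onset[h[on]] <- t
      status[h[on]] <- 1L
      death[h[de]] <- t
      status[h[de]] <- 2L
    }
    if (length(dz) > 0) {
      v <- stats::runif(length(dz))
      mf <- sch$m[t + 1] + sch$f[t + 1]
      de <- v < mf
      ins <- !de & v < mf + sch$r[t + 1]
      death[dz[de]] <- t
      status[dz[de]] <- 2L
      inst[dz[ins]] <- t
      status[dz[ins]] <- 3L
    }
  }
  data.frame(age_at_index = A, onset_age = onset, death_age = death,
             inst_age = inst)
}

#' Simulate patient histories from the true illness-death process
#'
#' Year-by-year simulation with stationary rates: onset with `i(a)`, death
#' with `m(a)` while disease-free and `m(a) + f(a)` while diseased,
#' institutionalization with `r(a)` while diseased. Reproducible given the
#' seed. Contacts are added separately by [add_contacts()].
#'
#' @param truth a [truth_config()]
#' @param seed integer RNG seed (required)
#' @return data.frame of class `patient_histories`: `id`, `sex`,
#'   `age_at_index`, `onset_age`, `death_age`, `inst_age` (`NA` = no event);
#'   persons dying or institutionalized before the index date are retained
#'   (extraction filters them)
#' @export
simulate_truth <- function(truth, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  per_sex <- round(truth$population * truth$age_weights / 2)
  out <- list()
  for (sx in c("f", "m")) {
    n_a <- per_sex
    A <- rep(0:99, times = n_a)
    h <- simulate_truth_sex(length(A), A, truth$schedules[[sx]])
    h$sex <- sx
    out[[sx]] <- h
  }
  h <- do.call(rbind, out)
  h <- h[, c("sex", "age_at_index", "onset_age", "death_age", "inst_age")]
  rownames(h) <- NULL
  h$id <- seq_len(nrow(h))
  structure(h[, c("id", "sex", "age_at_index", "onset_age", "death_age",
                  "inst_age")],
            class = c("patient_histories", "data.frame"),
            disease = truth$disease)
}

#' Add disease-coded GP contacts to patient histories
#'
#' Every alive, post-onset patient-year in the observation window (the index
#' year plus `lookback_years` before it) receives a contact independently with
#' probability `contact_prob`; the onset year always has a contact, since a
#' diagnosis implies a visit. Contacts are stored as a logical matrix
#' attribute `"contacts"` whose last column is the index year.
#'
#' @param h a [simulate_truth()] result
#' @param obs an [observation_config()]
#' @param seed integer RNG seed (required)
#' @return `h` with attributes `contacts` and `obs`
#' @export
add_contacts <- function(h, obs, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  L <- obs$lookback_years
  n <- nrow(h)
  A <- h$age_at_index
  end_age <- pmin(ifelse(is.na(h$death_age), Inf, h$death_age),
                  ifelse(is.na(h$inst_age), Inf, h$inst_age), A)
  M <- matrix(FALSE, n, L + 1)
  for (j in seq_len(L + 1)) {
    t <- A - (L + 1 - j)
    valid <- !is.na(h$onset_age) & t >= h$onset_age & t >= 0 & t <= end_age
    M[, j] <- valid & (stats::runif(n) < obs$contact_prob | t == h$onset_age)
  }
  attr(h, "contacts") <- M
  attr(h, "obs") <- obs
  h
}

present_at_index <- function(h) {
  A <- h$age_at_index
  (is.na(h$death_age) | h$death_age >= A) &
    (is.na(h$inst_age) | h$inst_age >= A)
}

aggregate_strata <- function(h, per_patient, disease, network, bands,
                             registry_type, lookback, underreport, seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  A <- h$age_at_index
  band_idx <- findInterval(A, bands$age_lo)
  rows <- list()
  for (sx in c("f", "m")) {
    for (k in seq_len(nrow(bands))) {
      sel <- h$sex == sx & band_idx == k
      deaths <- sum(per_patient$death[sel])
      if (underreport > 0 && deaths > 0) {
        deaths <- stats::rbinom(1, deaths, 1 - underreport)
      }
      rows[[length(rows) + 1]] <- data.frame(
        network = network, disease = disease, sex = sx,
        age_lo = bands$age_lo[k], age_hi = bands$age_hi[k],
        person_years = sum(per_patient$py[sel]),
        n_registered = sum(per_patient$present[sel]),
        prev_count = sum(per_patient$prev[sel]),
        inc_count = sum(per_patient$inc[sel]),
        deaths_with_disease = deaths,
        inst_with_disease = sum(per_patient$inst[sel]),
        seen_in_window = if (is.null(per_patient$seen)) NA_real_
                         else sum(per_patient$seen[sel]),
        stringsAsFactors = FALSE)
    }
  }
  registry_table(do.call(rbind, rows), registry_type = registry_type,
                 lookback_years = lookback)
}

#' Extract an episode-of-disease registry table
#'
#' Disease-based registration sees every open disease episode: prevalent =
#' alive at the index date with onset before it, incident = onset during the
#' index year. Deaths among the diseased can be thinned to emulate
#' under-registration of mortality.
#'
#' @param h a [simulate_truth()] result
#' @param disease,network labels for the output strata
#' @param bands age bands (default [age_bands()])
#' @param mortality_underreport fraction of diseased deaths dropped
#' @param seed RNG seed for the thinning (required when
#'   `mortality_underreport > 0`)
#' @return a [registry_table()] of type `episode_of_disease`
#' @export
extract_disease_based <- function(h, disease = attr(h, "disease"),
                                  network = "synthetic", bands = age_bands(),
                                  mortality_underreport = 0, seed = NULL) {
  if (mortality_underreport > 0 && is.null(seed)) {
    stop("seed is required when thinning deaths")
  }
  A <- h$age_at_index
  present <- present_at_index(h)
  diseased <- !is.na(h$onset_age)
  event_at_A <- present & ((!is.na(h$death_age) & h$death_age == A) |
                             (!is.na(h$inst_age) & h$inst_age == A))
  pp <- list(
    present = present,
    py = present * 1 - 0.5 * event_at_A,
    prev = present & diseased & h$onset_age < A,
    inc = present & diseased & h$onset_age == A,
    death = present & diseased & !is.na(h$death_age) & h$death_age == A,
    inst = present & diseased & !is.na(h$inst_age) & h$inst_age == A)
  aggregate_strata(h, pp, disease, network, bands, "episode_of_disease", 0L,
                   mortality_underreport, seed)
}

#' Extract an episode-of-care registry table
#'
#' Care-based registration only sees a chronic disease when the patient
#' contacts the GP. A registered patient counts as *seen* when any window year
#' has a disease-coded contact; as *incident* when the first contact in the
#' window falls in the index year; and as prevalent otherwise
#' (`prev_count = seen_in_window - inc_count`). Truly prevalent cases with no
#' window contact are absent from the counts entirely, and long-standing
#' prevalent cases whose only window contact falls in the index year are
#' misclassified as incident -- the mechanism quantified by
#' [implied_misclassification()].
#'
#' @param h histories with contacts from [add_contacts()]
#' @inheritParams extract_disease_based
#' @return a [registry_table()] of type `episode_of_care`
#' @export
extract_care_based <- function(h, disease = attr(h, "disease"),
                               network = "synthetic", bands = age_bands(),
                               mortality_underreport = 0, seed = NULL) {
  M <- attr(h, "contacts")
  obs <- attr(h, "obs")
  if (is.null(M) || is.null(obs) || nrow(M) != nrow(h)) {
    stop("run add_contacts() first (no contact matrix for these histories)")
  }
  if (mortality_underreport > 0 && is.null(seed)) {
    stop("seed is required when thinning deaths")
  }
  L <- obs$lookback_years
  A <- h$age_at_index
  present <- present_at_index(h)
  any_contact <- rowSums(M) > 0
  prior_contact <- if (L > 0) rowSums(M[, seq_len(L), drop = FALSE]) > 0
                   else rep(FALSE, nrow(h))
  seen <- present & any_contact
  inc <- seen & M[, L + 1] & !prior_contact
  event_at_A <- present & ((!is.na(h$death_age) & h$death_age == A) |
                             (!is.na(h$inst_age) & h$inst_age == A))
  pp <- list(
    present = present,
    py = present * 1 - 0.5 * event_at_A,
    prev = seen & !inc,
    inc = inc,
    seen = seen,
    death = seen & !is.na(h$death_age) & h$death_age == A,
    inst = seen & !is.na(h$inst_age) & h$inst_age == A)
  aggregate_strata(h, pp, disease, network, bands, "episode_of_care",
                   L, mortality_underreport, seed)
}

#' Analytic misclassification and missed-case fractions
#'
#' For a long-standing prevalent case with independent annual contact
#' probability `rho` and a lookback of `L` years: the probability of being
#' seen only in the index year (hence misclassified as incident) is
#' `kappa = rho * (1 - rho)^L`; the probability of no contact at all in the
#' window (hence missed entirely) is `missed = (1 - rho)^(L + 1)`.
#'
#' @param rho annual contact probability in (0, 1\]
#' @param L lookback window in years (>= 0)
#' @return list with `kappa` and `missed`
#' @export
implied_misclassification <- function(rho, L) {
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  if (L < 0) stop("L must be non-negative")
  list(kappa = rho * (1 - rho)^L, missed = (1 - rho)^(L + 1))
}

make_schedules <- function(i_coefs, m_intercept = -10.3, m_slope = 0.095,
                           phi_f = 0.5, phi_r = 0.4) {
  a <- AGE_GRID
  m <- pmin(0.6, exp(m_intercept + m_slope * a))
  r <- pmin(0.25, phi_r * m)
  f <- pmin(phi_f * m, pmax(0, 1 - m - r))
  i <- incidence_from_params(i_coefs)
  i <- pmin(i, 1 - m)
  disease_schedules(i = i, m = m, f = f, r = r)
}

#' Named synthetic scenarios
#'
#' Presets spanning the contrast between high-contact diseases (diabetes,
#' where guidelines imply several GP visits per year) and low-contact ones
#' (knee osteoarthritis, where a diagnosed patient may not contact the GP for
#' years), observed through care- or disease-based registration. Contact
#' probabilities are illustrative, not calibrated to any survey.
#'
#' @param population persons per scenario (default 200,000)
#' @return named list; each element has `truth` ([truth_config()]) and `obs`
#'   ([observation_config()])
#' @export
preset_scenarios <- function(population = 2e5) {
  sched <- function(coefs_f, coefs_m, phi_f) {
    list(f = make_schedules(coefs_f, m_intercept = -10.3, phi_f = phi_f),
         m = make_schedules(coefs_m, m_intercept = -10.0, phi_f = phi_f))
  }
  list(
    diabetes_like = list(
      truth = truth_config("diabetes_like",
                           sched(c(log(0.004), 1.5, -0.5, 0),
                                 c(log(0.0045), 1.5, -0.5, 0), phi_f = 0.5),
                           population),
      obs = observation_config("episode_of_care", contact_prob = 0.95,
                               lookback_years = 2)),
    copd_like = list(
      truth = truth_config("copd_like",
                           sched(c(log(0.002), 1.8, -0.6, 0),
                                 c(log(0.0025), 1.8, -0.6, 0), phi_f = 0.8),
                           population),
      obs = observation_config("episode_of_care", contact_prob = 0.7,
                               lookback_years = 2)),
    heart_failure_like = list(
      truth = truth_config("heart_failure_like",
                           sched(c(log(0.0008), 3.0, 0.5, 0),
                                 c(log(0.001), 3.0, 0.5, 0), phi_f = 1.5),
                           population),
      obs = observation_config("episode_of_disease", contact_prob = 0.9)),
    knee_oa_like = list(
      truth = truth_config("knee_oa_like",
                           sched(c(log(0.003), 1.2, -0.6, 0),
                                 c(log(0.0025), 1.2, -0.6, 0), phi_f = 0.05),
                           population),
      obs = observation_config("episode_of_care", contact_prob = 0.3,
                               lookback_years = 2))
  )
}

#' Five-network bundle
#'
#' One disease observed by five networks whose person-year sizes echo a
#' realistic national mix (270,000 / 14,000 / 44,000 / 14,000 / 88,000) and
#' whose registration types alternate between episode-of-care and
#' episode-of-disease.
#'
#' @param scenario preset name (see [preset_scenarios()])
#' @param scale multiplier on the network sizes (use < 1 for quick tests)
#' @return named list per network: `truth`, `obs`
#' @export
five_network_bundle <- function(scenario = "diabetes_like", scale = 1) {
  base <- preset_scenarios()[[scenario]]
  if (is.null(base)) stop("unknown scenario: ", scenario)
  sizes <- c(net_a = 270000, net_b = 14000, net_c = 44000,
             net_d = 14000, net_e = 88000)
  types <- c(net_a = "episode_of_care", net_b = "episode_of_disease",
             net_c = "episode_of_disease", net_d = "episode_of_care",
             net_e = "episode_of_disease")
  out <- list()
  for (nm in names(sizes)) {
    tr <- base$truth
    tr$population <- sizes[[nm]] * scale
    ob <- base$obs
    ob$registry_type <- types[[nm]]
    if (ob$registry_type == "episode_of_care" && ob$lookback_years == 0) {
      ob$lookback_years <- 2L
    }
    out[[nm]] <- list(truth = tr, obs = ob)
  }
  out
}

#' Simulate and extract one synthetic registry
#'
#' Convenience chain: [simulate_truth()], [add_contacts()] (episode-of-care
#' only), then the matching extraction operator.
#'
#' @param truth a [truth_config()]
#' @param obs an [observation_config()]
#' @param seed integer RNG seed
#' @param network network label
#' @param bands age bands
#' @return a validated [registry_table()]
#' @export
simulate_registry <- function(truth, obs, seed, network = "synthetic",
                              bands = age_bands()) {
  h <- simulate_truth(truth, seed = seed)
  if (obs$registry_type == "episode_of_care") {
    h <- add_contacts(h, obs, seed = seed + 1L)
    extract_care_based(h, network = network, bands = bands,
                       mortality_underreport = obs$mortality_underreport,
                       seed = seed + 2L)
  } else {
    extract_disease_based(h, network = network, bands = bands,
                          mortality_underreport = obs$mortality_underreport,
                          seed = seed + 2L)
  }
}
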