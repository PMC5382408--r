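# Joint maximum-likelihood estimation of age-specific incidence and the
# misclassification fraction kappa from observed incident and prevalent
# counts, with mortality/institutionalization schedules held fixed.
#
# Model, per sex and stratum (age band):
#   p_mod(a)    prevalence projected from i(a) and the fixed outflow
#   E[prev]     = n_registered * (1 - kappa) * p_mod
#   E[inc]      = PY_free * i + kappa * n_registered * p_mod,
#                 PY_free = person_years * (1 - p_mod)
# Prevalent counts are binomial, incident counts Poisson; misclassification of
# incident cases as prevalent is assumed rare and ignored. kappa is constant
# over age within sex.

#' Incidence schedule from log-polynomial parameters
#'
#' `i(a) = exp(sum_j c_j * x^j)` with `x = (a - 50) / 50` (age centered at 50
#' and scaled to roughly \[-1, 1\]). Values are clipped to
#' `[1e-10, 0.5]` before use.
#'
#' @param coefficients numeric vector `(c_0, ..., c_d)`; the degree is
#'   `length(coefficients) - 1`
#' @param ages integer ages (default the 0--99 grid)
#' @return annual incidence probabilities at `ages`
#' @export
incidence_from_params <- function(coefficients, ages = AGE_GRID) {
  x <- (ages - 50) / 50
  X <- outer(x, seq_along(coefficients) - 1, "^")
  pmin(0.5, pmax(1e-10, exp(drop(X %*% coefficients))))
}

# Band-level model quantities for one sex.
# i_age: per-age incidence; fixed: disease_schedules carrying m, f, r
# (its i slot is ignored); bands: data.frame age_lo/age_hi;
# person_years, n_registered: per-band exposures.
band_expectations <- function(i_age, kappa, fixed, bands,
                              person_years, n_registered) {
  i_age <- pmin(i_age, 1 - fixed$m)  # keep i + m <= 1 at extreme trial values
  s <- disease_schedules(i = i_age, m = fixed$m, f = fixed$f, r = fixed$r)
  st <- project_cohort(s)
  alive <- st$S + st$C
  nb <- nrow(bands)
  p_mod <- i_band <- numeric(nb)
  for (k in seq_len(nb)) {
    in_band <- st$age >= bands$age_lo[k] & st$age < bands$age_hi[k]
    a_sum <- sum(alive[in_band])
    p_mod[k] <- if (a_sum > 0) sum(st$C[in_band]) / a_sum else 0
    s_sum <- sum(st$S[in_band])
    i_band[k] <- if (s_sum > 0) {
      sum(st$S[in_band] * i_age[in_band]) / s_sum
    } else {
      mean(i_age[in_band])
    }
  }
  py_free <- person_years * (1 - p_mod)
  data.frame(age_lo = bands$age_lo, age_hi = bands$age_hi,
             p_mod = p_mod, i_band = i_band, py_free = py_free,
             E_inc = py_free * i_band + kappa * n_registered * p_mod,
             E_prev = n_registered * (1 - kappa) * p_mod)
}

#' Expected incident and prevalent counts under the misclassification model
#'
#' @param i per-age incidence vector (length 100) or banded incidence
#'   [rate_schedule()] for one sex
#' @param kappa misclassification fraction in \[0, 1)
#' @param fixed a [disease_schedules()] supplying the fixed outflow `m`, `f`,
#'   `r` (its `i` slot is ignored)
#' @param exposures data.frame with columns age_lo, age_hi, person_years,
#'   n_registered for one sex
#' @return data.frame with `p_mod`, `i_band`, `py_free`, `E_inc`, `E_prev`
#'   per band
#' @export
expected_counts <- function(i, kappa, fixed, exposures) {
  if (kappa < 0 || kappa >= 1) stop("kappa must lie in [0, 1)")
  bands <- exposures[, c("age_lo", "age_hi")]
  if (inherits(i, "rate_schedule") || is.data.frame(i)) {
    i <- expand_to_grid(i$value, bands = i[, c("age_lo", "age_hi")])
  } else {
    i <- expand_to_grid(i)
  }
  band_expectations(i, kappa, fixed, bands,
                    exposures$person_years, exposures$n_registered)
}

# negative log-likelihood for one sex; theta = (coefs, qlogis(kappa)) or
# just coefs when kappa is pinned to zero.
dismod_negll <- function(theta, d, fixed, degree, kappa_fixed = NULL) {
  p <- degree + 1
  coefs <- theta[seq_len(p)]
  kappa <- if (is.null(kappa_fixed)) stats::plogis(theta[p + 1]) else kappa_fixed
  i_age <- incidence_from_params(coefs)
  e <- band_expectations(i_age, kappa, fixed, d$bands,
                         d$person_years, d$n_registered)
  psucc <- pmin(1 - 1e-12, (1 - kappa) * e$p_mod)
  ll <- sum(stats::dpois(d$inc_count, e$E_inc, log = TRUE)) +
    sum(stats::dbinom(d$prev_count, d$n_registered, psucc, log = TRUE))
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' DisMod log-likelihood
#'
#' Sum over strata of the Poisson log-pmf of the incident count at `E[inc]`
#' and the binomial log-pmf of the prevalent count with `n_registered` trials
#' and success probability `(1 - kappa) * p_mod`. Returns `-Inf` (a valid
#' value, not an error) when an expected count is zero but the observed count
#' is positive.
#'
#' @param coefficients log-polynomial incidence coefficients (one sex)
#' @param kappa misclassification fraction in \[0, 1)
#' @param data a [registry_table()] restricted to one sex (or a data.frame
#'   with the same columns)
#' @param fixed a [disease_schedules()] with the fixed outflow
#' @return log-likelihood (scalar)
#' @export
dismod_loglik <- function(coefficients, kappa, data, fixed) {
  if (length(unique(data$sex)) != 1) stop("data must hold a single sex")
  d <- sex_data(data, unique(data$sex))
  e <- band_expectations(incidence_from_params(coefficients), kappa, fixed,
                         d$bands, d$person_years, d$n_registered)
  psucc <- pmin(1 - 1e-12, (1 - kappa) * e$p_mod)
  sum(stats::dpois(d$inc_count, e$E_inc, log = TRUE)) +
    sum(stats::dbinom(d$prev_count, d$n_registered, psucc, log = TRUE))
}

numeric_hessian <- function(fn, theta, rel_step = 1e-4) {
  p <- length(theta)
  h <- rel_step * pmax(1, abs(theta))
  H <- matrix(NA_real_, p, p)
  for (a in seq_len(p)) {
    for (b in a:p) {
      ea <- eb <- numeric(p)
      ea[a] <- h[a]; eb[b] <- h[b]
      H[a, b] <- H[b, a] <-
        (fn(theta + ea + eb) - fn(theta + ea - eb) -
           fn(theta - ea + eb) + fn(theta - ea - eb)) / (4 * h[a] * h[b])
    }
  }
  H
}

sex_data <- function(t, sex) {
  rows <- as.data.frame(t)[t$sex == sex, ]
  rows <- rows[order(rows$age_lo), ]
  list(bands = rows[, c("age_lo", "age_hi")],
       person_years = rows$person_years,
       n_registered = round(rows$n_registered),
       inc_count = round(rows$inc_count),
       prev_count = round(rows$prev_count))
}

fit_dismod_sex <- function(d, fixed, degree, kappa_start, max_iter, reltol,
                           boundary_tol = 1e-4) {
  p <- degree + 1
  # start: Poisson regression of observed incident counts, ignoring
  # misclassification
  py_free_obs <- person_years_at_risk(d$person_years, d$prev_count,
                                      d$inc_count)
  use <- py_free_obs > 0
  x <- ((d$bands$age_lo + d$bands$age_hi) / 2 - 50) / 50
  X <- outer(x, seq_len(p) - 1, "^")
  start <- rep(0, p)
  start[1] <- log(max(sum(d$inc_count), 0.5) / max(sum(py_free_obs), 1))
  fit0 <- tryCatch(
    suppressWarnings(
      stats::glm.fit(X[use, , drop = FALSE], d$inc_count[use],
                     offset = log(py_free_obs[use]),
                     family = stats::poisson())),
    error = function(e) NULL)
  if (!is.null(fit0) && all(is.finite(fit0$coefficients))) {
    start <- fit0$coefficients
  }
  ctl <- list(maxit = max_iter, reltol = reltol)
  theta0 <- c(start, stats::qlogis(kappa_start))
  opt <- stats::optim(theta0, dismod_negll, d = d, fixed = fixed,
                      degree = degree, method = "BFGS", control = ctl)
  kappa_hat <- stats::plogis(opt$par[p + 1])
  boundary <- kappa_hat < boundary_tol
  if (boundary) {
    # pin kappa to 0 and refit the incidence coefficients alone
    opt <- stats::optim(opt$par[seq_len(p)], dismod_negll, d = d,
                        fixed = fixed, degree = degree, kappa_fixed = 0,
                        method = "BFGS", control = ctl)
    kappa_hat <- 0
    theta <- opt$par
    fn <- function(th) dismod_negll(th, d, fixed, degree, kappa_fixed = 0)
  } else {
    theta <- opt$par
    fn <- function(th) dismod_negll(th, d, fixed, degree)
  }
  converged <- opt$convergence == 0
  H <- numeric_hessian(fn, theta)
  covariance <- tryCatch({
    V <- solve(H)
    if (!all(is.finite(V))) stop("non-finite")
    V
  }, error = function(e) NULL)
  if (is.null(covariance)) converged <- FALSE
  list(coefficients = theta[seq_len(p)],
       kappa = kappa_hat,
       theta = theta,
       covariance = covariance,
       loglik = -opt$value,
       converged = converged,
       kappa_on_boundary = boundary,
       data = d)
}

#' Fit the joint incidence-prevalence-misclassification (DisMod) model
#'
#' Maximizes the Poisson (incidence) x binomial (prevalence) likelihood over
#' the log-polynomial incidence coefficients and a logit-transformed
#' misclassification fraction kappa, separately per sex, by quasi-Newton
#' (BFGS) iteration. Starting values come from a Poisson regression of the
#' observed incident counts ignoring misclassification; kappa starts at 0.05.
#' The covariance is the inverse of a central-difference Hessian at the
#' optimum. When the kappa estimate falls below `1e-4` it is pinned to zero,
#' the remaining parameters are refit, the boundary flag is set, and no kappa
#' confidence interval should be reported.
#'
#' @param data a [registry_table()] restricted to one network and disease
#' @param fixed named list (by sex, `"f"`/`"m"`) of [disease_schedules()]
#'   supplying the fixed outflow; a single `disease_schedules` is recycled
#' @param degree polynomial degree for log-incidence (1--4, default 3)
#' @param kappa_start starting value for kappa (default 0.05)
#' @param max_iter optimizer iteration cap (default 500)
#' @param reltol relative tolerance on the log-likelihood (default 1e-8)
#' @return object of class `dismod_fit`: per-sex parameter estimates, kappa,
#'   covariance (on the internal scale: coefficients plus logit-kappa),
#'   log-likelihood, convergence and boundary flags
#' @export
fit_dismod <- function(data, fixed, degree = 3, kappa_start = 0.05,
                       max_iter = 500, reltol = 1e-8) {
  if (!degree %in% 1:4) stop("degree must be between 1 and 4")
  if (inherits(fixed, "disease_schedules")) fixed <- list(f = fixed, m = fixed)
  if (length(unique(data$network)) > 1 || length(unique(data$disease)) > 1) {
    stop("fit one network x disease at a time")
  }
  sexes <- intersect(c("f", "m"), unique(data$sex))
  if (length(sexes) == 0) stop("no rows to fit")
  fits <- list()
  for (sx in sexes) {
    d <- sex_data(data, sx)
    if (sum(d$person_years > 0) < 2) {
      stop("need >= 2 age bands with positive exposure for sex ", sx)
    }
    fits[[sx]] <- fit_dismod_sex(d, fixed[[sx]], degree, kappa_start,
                                 max_iter, reltol)
  }
  structure(list(sexes = fits,
                 degree = degree,
                 network = unique(data$network),
                 disease = unique(data$disease),
                 loglik = sum(vapply(fits, `[[`, numeric(1), "loglik")),
                 converged = all(vapply(fits, `[[`, logical(1), "converged"))),
            class = "dismod_fit")
}

#' @export
print.dismod_fit <- function(x, ...) {
  cat(sprintf("DisMod fit: %s / %s (degree %d)\n",
              x$network, x$disease, x$degree))
  for (sx in names(x$sexes)) {
    f <- x$sexes[[sx]]
    cat(sprintf("  %s: kappa = %.4f%s, loglik = %.2f, converged = %s\n",
                sx, f$kappa,
                if (f$kappa_on_boundary) " (boundary)" else "",
                f$loglik, f$converged))
  }
  invisible(x)
}

#' Draw parameter vectors from the fitted model
#'
#' Multivariate-normal draws around the maximum-likelihood estimate using the
#' estimated covariance matrix, the parametric-bootstrap input for percentile
#' confidence intervals. kappa draws are produced on the logit scale, so they
#' fall in (0, 1) automatically; for boundary fits kappa stays pinned at 0 in
#' every draw.
#'
#' @param fit a converged [fit_dismod()] result
#' @param n number of draws (default 1000)
#' @param seed integer RNG seed (required; draws are reproducible)
#' @return object of class `param_draws`: per sex, an `n x p` coefficient
#'   matrix and a length-`n` kappa vector
#' @export
sample_params <- function(fit, n = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  if (!fit$converged) stop("cannot sample from a non-converged fit")
  set.seed(as.integer(seed))
  p <- fit$degree + 1
  out <- list()
  for (sx in names(fit$sexes)) {
    f <- fit$sexes[[sx]]
    V <- f$covariance
    mu <- f$theta
    eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
    if (any(eg$values < -1e-8 * max(abs(eg$values), 1))) {
      stop("covariance not positive semi-definite; refit (kappa may be on ",
           "the boundary)")
    }
    lam <- pmax(eg$values, 0)
    z <- matrix(stats::rnorm(n * length(mu)), n, length(mu))
    draws <- sweep(z %*% diag(sqrt(lam), length(lam)) %*% t(eg$vectors),
                   2, mu, "+")
    kappa <- if (f$kappa_on_boundary) {
      rep(0, n)
    } else {
      pmin(1 - 1e-12, pmax(0, stats::plogis(draws[, p + 1])))
    }
    out[[sx]] <- list(coefficients = draws[, seq_len(p), drop = FALSE],
                      kappa = kappa)
  }
  structure(list(sexes = out, n = n, seed = as.integer(seed),
                 degree = fit$degree),
            class = "param_draws")
}

std_rates_from_params <- function(coefs_by_sex, fixed, stdpop, bands) {
  inc_rows <- prev_rows <- list()
  for (sx in names(coefs_by_sex)) {
    i_age <- pmin(incidence_from_params(coefs_by_sex[[sx]]),
                  1 - fixed[[sx]]$m)
    s <- disease_schedules(i = i_age, m = fixed[[sx]]$m,
                           f = fixed[[sx]]$f, r = fixed[[sx]]$r)
    st <- project_cohort(s)
    prev_rows[[sx]] <- as.data.frame(projected_prevalence(st, bands, sex = sx))
    i_band <- vapply(seq_len(nrow(bands)), function(k) {
      in_band <- st$age >= bands$age_lo[k] & st$age < bands$age_hi[k]
      s_sum <- sum(st$S[in_band])
      if (s_sum > 0) sum(st$S[in_band] * i_age[in_band]) / s_sum
      else mean(i_age[in_band])
    }, numeric(1))
    inc_rows[[sx]] <- data.frame(sex = sx, age_lo = bands$age_lo,
                                 age_hi = bands$age_hi, value = i_band)
  }
  inc_s <- rate_schedule(do.call(rbind, inc_rows), "incidence")
  prev_df <- do.call(rbind, prev_rows)
  prev_df$value[is.na(prev_df$value)] <- 0  # extinct band: no survivors
  prev_s <- rate_schedule(prev_df, "prevalence")
  c(incidence = direct_standardize(inc_s, stdpop)$value,
    prevalence = direct_standardize(prev_s, stdpop)$value)
}

#' Standardized modeled rates with percentile confidence intervals
#'
#' For every parameter draw, rebuilds the incidence schedule, projects the
#' illness-death cohort, and directly standardizes modeled incidence and
#' prevalence; the point estimate uses the maximum-likelihood parameters and
#' the 95% interval is the 2.5th/97.5th percentile over draws. `se_log` is the
#' standard deviation of the log rates over draws (the meta-analysis input).
#' Draws producing non-finite rates are dropped with a message; more than 10%
#' dropped is an error.
#'
#' @param draws a [sample_params()] result
#' @param fit the [fit_dismod()] the draws came from
#' @param fixed fixed outflow schedules, as in [fit_dismod()]
#' @param stdpop a [standard_population()]
#' @param bands age bands for standardization (default [age_bands()])
#' @return list with [standardized_rate()] elements `incidence` and
#'   `prevalence` (per 1,000) and `n_used` draws
#' @export
standardized_rate_ci <- function(draws, fit, fixed, stdpop,
                                 bands = age_bands()) {
  if (inherits(fixed, "disease_schedules")) fixed <- list(f = fixed, m = fixed)
  sexes <- names(draws$sexes)
  point <- std_rates_from_params(
    lapply(fit$sexes[sexes], `[[`, "coefficients"), fixed, stdpop, bands)
  vals <- matrix(NA_real_, draws$n, 2,
                 dimnames = list(NULL, c("incidence", "prevalence")))
  for (j in seq_len(draws$n)) {
    cs <- lapply(draws$sexes, function(sd) sd$coefficients[j, ])
    vals[j, ] <- std_rates_from_params(cs, fixed, stdpop, bands)
  }
  ok <- apply(is.finite(vals), 1, all)
  if (sum(!ok) > 0) {
    message(sprintf("dropped %d non-finite draw(s)", sum(!ok)))
    if (mean(!ok) > 0.10) stop("more than 10% of draws non-finite")
  }
  vals <- vals[ok, , drop = FALSE]
  mk <- function(measure) {
    v <- vals[, measure]
    qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    standardized_rate(point[[measure]],
                      ci_lo = min(qs[1], point[[measure]]),
                      ci_hi = max(qs[2], point[[measure]]),
                      se_log = stats::sd(log(pmax(v, 1e-300))))
  }
  list(incidence = mk("incidence"), prevalence = mk("prevalence"),
       n_used = sum(ok))
}
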