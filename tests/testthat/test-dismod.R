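# Shared toy world for the fitting tests: truth inside the model family.
fit_world <- local({
  coefs <- list(f = c(log(0.004), 1.2, -0.4, 0),
                m = c(log(0.005), 1.2, -0.4, 0))
  m <- pmin(0.5, exp(-10 + 0.09 * (0:99)))
  fixed <- list(
    f = disease_schedules(i = 0, m = m, f = 0.4 * m, r = 0.2 * m),
    m = disease_schedules(i = 0, m = m, f = 0.4 * m, r = 0.2 * m))
  list(coefs = coefs, fixed = fixed)
})

# Registry table whose counts equal their model expectations (rounded).
exact_expectation_table <- function(kappa, n_per_band = 1e6,
                                    bands = age_bands()) {
  w <- fit_world
  rows <- list()
  for (sx in c("f", "m")) {
    exposures <- data.frame(age_lo = bands$age_lo, age_hi = bands$age_hi,
                            person_years = n_per_band,
                            n_registered = n_per_band)
    e <- expected_counts(incidence_from_params(w$coefs[[sx]]), kappa,
                         w$fixed[[sx]], exposures)
    rows[[sx]] <- data.frame(
      network = "exact", disease = "toy", sex = sx,
      age_lo = bands$age_lo, age_hi = bands$age_hi,
      person_years = n_per_band, n_registered = n_per_band,
      prev_count = round(e$E_prev), inc_count = round(e$E_inc),
      deaths_with_disease = 0, inst_with_disease = 0,
      seen_in_window = NA)
  }
  registry_table(do.call(rbind, rows))
}

test_that("log-polynomial incidence evaluates and clips as specified", {
  expect_equal(incidence_from_params(c(log(0.01), 0, 0, 0)),
               rep(0.01, 100))
  expect_equal(incidence_from_params(c(log(0.01), 1), ages = 100),
               0.01 * exp(1))
  expect_equal(incidence_from_params(c(log(0.9), 0)), rep(0.5, 100))  # clip
  expect_equal(incidence_from_params(c(-60, 0)), rep(1e-10, 100))    # floor
})

test_that("expected counts follow the misclassification identities", {
  w <- fit_world
  exposures <- data.frame(age_lo = c(40, 60), age_hi = c(60, 80),
                          person_years = c(1e4, 1e4),
                          n_registered = c(1e4, 1e4))
  i_age <- incidence_from_params(w$coefs$f)
  e0 <- expected_counts(i_age, 0, w$fixed$f, exposures)
  expect_equal(e0$E_inc, e0$py_free * e0$i_band)  # kappa = 0: no extra term
  expect_equal(e0$E_prev, exposures$n_registered * e0$p_mod)

  e1 <- expected_counts(i_age, 0.1, w$fixed$f, exposures)
  expect_equal(e1$E_inc,
               e1$py_free * e1$i_band + 0.1 * 1e4 * e1$p_mod)
  expect_equal(e1$E_prev, 0.9 * 1e4 * e1$p_mod)
  expect_equal(e1$py_free, 1e4 * (1 - e1$p_mod))
})

test_that("the log-likelihood equals an independent log-pmf sum", {
  w <- fit_world
  t <- exact_expectation_table(kappa = 0.1, n_per_band = 5e4)
  tf <- t[t$sex == "f", ]
  ll <- dismod_loglik(w$coefs$f, 0.1, tf, w$fixed$f)

  exposures <- data.frame(age_lo = tf$age_lo, age_hi = tf$age_hi,
                          person_years = tf$person_years,
                          n_registered = tf$n_registered)
  e <- expected_counts(incidence_from_params(w$coefs$f), 0.1, w$fixed$f,
                       exposures)
  ll_oracle <- sum(oracle_pois_logpmf(tf$inc_count, e$E_inc)) +
    sum(oracle_binom_logpmf(tf$prev_count, tf$n_registered,
                            0.9 * e$p_mod))
  expect_equal(ll, ll_oracle, tolerance = 1e-10)
})

test_that("log-likelihood handles closed-form and boundary cases", {
  w <- fit_world
  b <- data.frame(network = "x", disease = "d", sex = "f",
                  age_lo = c(50, 60), age_hi = c(60, 70),
                  person_years = 1000, n_registered = 1000,
                  prev_count = c(0, 0), inc_count = c(0, 0),
                  deaths_with_disease = 0, inst_with_disease = 0,
                  seen_in_window = NA)
  t0 <- registry_table(b, check = FALSE)
  exposures <- data.frame(age_lo = b$age_lo, age_hi = b$age_hi,
                          person_years = 1000, n_registered = 1000)
  e <- expected_counts(incidence_from_params(w$coefs$f), 0, w$fixed$f,
                       exposures)
  # zero observed counts: Poisson terms are -lambda exactly
  ll <- dismod_loglik(w$coefs$f, 0, t0, w$fixed$f)
  ll_manual <- sum(-e$E_inc) +
    sum(1000 * log(1 - e$p_mod))
  expect_equal(ll, ll_manual, tolerance = 1e-10)

  # all registered prevalent with success prob < 1: finite and negative
  b$prev_count <- 1000
  t1 <- registry_table(b, check = FALSE)
  ll1 <- dismod_loglik(w$coefs$f, 0, t1, w$fixed$f)
  expect_true(is.finite(ll1) && ll1 < 0)
  expect_equal(ll1 - sum(-e$E_inc), sum(1000 * log(e$p_mod)),
               tolerance = 1e-8)
})

test_that("exact-expectation data returns the generating kappa to 1e-3", {
  t <- exact_expectation_table(kappa = 0.15)
  fit <- fit_dismod(t, fit_world$fixed, degree = 3)
  expect_true(fit$converged)
  for (sx in c("f", "m")) {
    expect_false(fit$sexes[[sx]]$kappa_on_boundary)
    expect_equal(fit$sexes[[sx]]$kappa, 0.15, tolerance = 1e-3)
    expect_equal(fit$sexes[[sx]]$coefficients, fit_world$coefs[[sx]],
                 tolerance = 0.02)
  }
})

test_that("duplicating every stratum doubles the log-likelihood only", {
  t <- exact_expectation_table(kappa = 0.1, n_per_band = 1e5)
  fit1 <- fit_dismod(t, fit_world$fixed)
  t2 <- registry_table(rbind(as.data.frame(t), as.data.frame(t)),
                       check = FALSE)
  fit2 <- fit_dismod(t2, fit_world$fixed)
  expect_equal(fit2$sexes$f$kappa, fit1$sexes$f$kappa, tolerance = 1e-3)
  expect_equal(fit2$sexes$f$coefficients, fit1$sexes$f$coefficients,
               tolerance = 1e-2)
  expect_equal(fit2$loglik, 2 * fit1$loglik, tolerance = 1e-4)
})

test_that("the ML optimum beats the generating parameters on noisy data", {
  sc <- preset_scenarios(population = 5e4)$diabetes_like
  for (seed in 1:3) {
    tab <- simulate_registry(sc$truth, observation_config("episode_of_disease"),
                             seed = seed, network = "n")
    fit <- fit_dismod(tab, sc$truth$schedules)
    for (sx in c("f", "m")) {
      d <- tab[tab$sex == sx, ]
      ll_true <- dismod_loglik(
        c(log(sc$truth$schedules[[sx]]$i[51]), 0, 0, 0), 0,
        d, sc$truth$schedules[[sx]])
      expect_gte(fit$sexes[[sx]]$loglik, ll_true)
    }
  }
})

test_that("kappa = 0 worlds produce the boundary flag and pinning", {
  sc <- preset_scenarios(population = 1e5)$diabetes_like
  tab <- simulate_registry(sc$truth, observation_config("episode_of_disease"),
                           seed = 9, network = "n")
  fit <- fit_dismod(tab, sc$truth$schedules)
  for (sx in c("f", "m")) {
    expect_true(fit$sexes[[sx]]$kappa_on_boundary)
    expect_identical(fit$sexes[[sx]]$kappa, 0)
    # boundary refit drops the kappa column from the covariance
    expect_equal(ncol(fit$sexes[[sx]]$covariance), fit$degree + 1)
  }
})

test_that("parameter draws are reproducible and honor the covariance", {
  t <- exact_expectation_table(kappa = 0.15, n_per_band = 1e5)
  fit <- fit_dismod(t, fit_world$fixed)
  d1 <- sample_params(fit, n = 50, seed = 123)
  d2 <- sample_params(fit, n = 50, seed = 123)
  expect_identical(d1, d2)
  expect_error(sample_params(fit, n = 10), "seed")

  # zero covariance: every draw equals the estimate
  fit0 <- fit
  for (sx in c("f", "m")) {
    fit0$sexes[[sx]]$covariance <- matrix(0, 5, 5)
  }
  dz <- sample_params(fit0, n = 20, seed = 1)
  for (sx in c("f", "m")) {
    expect_equal(dz$sexes[[sx]]$coefficients,
                 matrix(rep(fit$sexes[[sx]]$coefficients, each = 20), 20, 4),
                 tolerance = 1e-12)
    expect_equal(dz$sexes[[sx]]$kappa,
                 rep(fit$sexes[[sx]]$kappa, 20), tolerance = 1e-12)
  }

  # diagonal covariance: empirical SDs within 5% of specification
  sds <- c(0.05, 0.02, 0.02, 0.02, 0.1)
  fitd <- fit
  fitd$sexes$f$covariance <- diag(sds^2)
  dd <- sample_params(fitd, n = 10000, seed = 77)
  emp <- apply(dd$sexes$f$coefficients, 2, sd)
  expect_true(all(abs(emp / sds[1:4] - 1) < 0.05))

  # non-PSD covariance is rejected with advice
  fitb <- fit
  vbad <- diag(5)
  vbad[1:2, 1:2] <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues -1 and 3
  fitb$sexes$f$covariance <- vbad
  expect_error(sample_params(fitb, n = 5, seed = 1), "positive semi-definite")
})

test_that("standardized-rate CIs come from sorted draw percentiles", {
  t <- exact_expectation_table(kappa = 0.15, n_per_band = 1e5)
  fit <- fit_dismod(t, fit_world$fixed)
  stdpop <- default_standard_population()
  draws <- sample_params(fit, n = 200, seed = 5)
  sr <- standardized_rate_ci(draws, fit, fit_world$fixed, stdpop)
  expect_equal(sr$n_used, 200)
  for (ms in c("incidence", "prevalence")) {
    x <- sr[[ms]]
    expect_true(x$ci_lo <= x$value && x$value <= x$ci_hi)
    expect_gt(x$se_log, 0)
  }

  # degenerate draws collapse the interval onto the point estimate
  fit0 <- fit
  for (sx in c("f", "m")) fit0$sexes[[sx]]$covariance <- matrix(0, 5, 5)
  dz <- sample_params(fit0, n = 30, seed = 2)
  sr0 <- standardized_rate_ci(dz, fit0, fit_world$fixed, stdpop)
  expect_equal(sr0$incidence$ci_lo, sr0$incidence$value, tolerance = 1e-10)
  expect_equal(sr0$incidence$ci_hi, sr0$incidence$value, tolerance = 1e-10)
  expect_equal(sr0$prevalence$se_log, 0, tolerance = 1e-12)
})

test_that("percentile bounds match an explicit sort-based computation", {
  set.seed(31)
  x <- rlnorm(500)
  expect_equal(unname(quantile(x, c(0.025, 0.975), type = 7)),
               c(oracle_quantile7(x, 0.025), oracle_quantile7(x, 0.975)))
})

test_that("CI coverage for standardized incidence is near nominal", {
  # scaled down from the specified 1e6-person-year worlds to stay within the
  # suite's runtime budget; the band is the specified wide 20-replicate one
  sc <- preset_scenarios(population = 1.5e5)$diabetes_like
  stdpop <- default_standard_population()
  truth_inc <- list()
  for (sx in c("f", "m")) {
    st <- project_cohort(sc$truth$schedules[[sx]])
    b <- age_bands()
    i_age <- sc$truth$schedules[[sx]]$i
    v <- vapply(seq_len(nrow(b)), function(k) {
      sel <- st$age >= b$age_lo[k] & st$age < b$age_hi[k]
      sum(st$S[sel] * i_age[sel]) / sum(st$S[sel])
    }, numeric(1))
    truth_inc[[sx]] <- data.frame(sex = sx, age_lo = b$age_lo,
                                  age_hi = b$age_hi, value = v)
  }
  true_std <- direct_standardize(
    rate_schedule(do.call(rbind, truth_inc), "incidence"), stdpop)$value

  hits <- 0
  n_rep <- 20
  for (seed in seq_len(n_rep)) {
    tab <- simulate_registry(sc$truth,
                             observation_config("episode_of_disease"),
                             seed = 1000 + seed, network = "n")
    fit <- fit_dismod(tab, sc$truth$schedules)
    if (!fit$converged) next
    draws <- sample_params(fit, n = 200, seed = seed)
    sr <- standardized_rate_ci(draws, fit, sc$truth$schedules, stdpop)
    if (sr$incidence$ci_lo <= true_std && true_std <= sr$incidence$ci_hi) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_rep, 0.88)
})
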