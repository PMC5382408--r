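# Independent oracles used across test files. These deliberately use a
# different formulation than the package internals.

# Illness-death projection as 4-state Markov transition-matrix products:
# states (S, C, dead, gone). Returns data.frame(age, S, C, dead, gone).
oracle_project <- function(i, m, f, r, n_ages = 100) {
  i <- rep_len(i, n_ages); m <- rep_len(m, n_ages)
  f <- rep_len(f, n_ages); r <- rep_len(r, n_ages)
  v <- c(1, 0, 0, 0)
  out <- matrix(NA_real_, n_ages, 4)
  out[1, ] <- v
  for (a in seq_len(n_ages - 1)) {
    T <- rbind(
      c(1 - i[a] - m[a], i[a], m[a], 0),
      c(0, 1 - m[a] - f[a] - r[a], m[a] + f[a], r[a]),
      c(0, 0, 1, 0),
      c(0, 0, 0, 1))
    v <- drop(v %*% T)
    out[a + 1, ] <- v
  }
  data.frame(age = seq_len(n_ages) - 1, S = out[, 1], C = out[, 2],
             dead = out[, 3], gone = out[, 4])
}

# Life expectancy by direct summation over the death-age distribution,
# with the cap convention (everyone alive at the last grid age dies then).
oracle_le <- function(q, from_age = 0) {
  n <- 100 - from_age
  q <- q[seq_len(n)]
  q[n] <- 1
  # everyone dies by the cap (q[n] = 1): sum years-lived over the death-age
  # distribution, death in year k meaning k - 1 whole years plus half a year
  l <- 1
  le <- 0
  for (k in seq_len(n)) {
    le <- le + l * q[k] * (k - 1 + 0.5)
    l <- l * (1 - q[k])
  }
  le
}

# DerSimonian-Laird pooling, coded from the moment formulas directly.
oracle_dl <- function(y, se) {
  k <- length(y)
  if (k == 1) {
    return(list(mu = y, se = se, tau2 = 0, Q = 0))
  }
  w <- se^-2
  yw <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yw)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / c_dl)
  wstar <- 1 / (se^2 + tau2)
  list(mu = sum(wstar * y) / sum(wstar), se = sum(wstar)^-0.5,
       tau2 = tau2, Q = Q)
}

# Explicit log-pmfs (no dpois/dbinom).
oracle_pois_logpmf <- function(k, lambda) {
  ifelse(lambda == 0, ifelse(k == 0, 0, -Inf),
         k * log(lambda) - lambda - lgamma(k + 1))
}
oracle_binom_logpmf <- function(k, n, p) {
  lchoose(n, k) + ifelse(k == 0, 0, k * log(p)) +
    ifelse(n - k == 0, 0, (n - k) * log(1 - p))
}

# Type-7 percentile by explicit sorting and interpolation.
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Small valid registry table for io tests.
toy_registry <- function(registry_type = "episode_of_disease",
                         lookback = 0L) {
  b <- age_bands(width = 50, max_age = 100)
  rows <- expand.grid(sex = c("f", "m"), k = 1:2,
                      stringsAsFactors = FALSE)
  df <- data.frame(network = "toy", disease = "diabetes",
                   sex = rows$sex,
                   age_lo = b$age_lo[rows$k], age_hi = b$age_hi[rows$k],
                   person_years = c(1000, 1000, 800, 800),
                   n_registered = c(1000, 1000, 800, 800),
                   prev_count = c(10, 12, 80, 90),
                   inc_count = c(2, 3, 8, 9),
                   deaths_with_disease = c(0, 0, 4, 5),
                   inst_with_disease = c(0, 0, 1, 1),
                   seen_in_window = c(12, 15, 88, 99))
  registry_table(df, registry_type = registry_type,
                 lookback_years = lookback)
}
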