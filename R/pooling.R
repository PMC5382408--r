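# Random-effects pooling of network-specific standardized rates on the log
# scale (DerSimonian-Laird moment estimator, normal-quantile CI).

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools log standardized rates across networks. Fixed weights
#' `w_i = 1 / se_i^2` give the heterogeneity statistic
#' `Q = sum(w_i * (y_i - ybar_w)^2)`; the between-network variance is
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))`; random
#' weights `1 / (se_i^2 + tau2)` give the pooled estimate and its standard
#' error, with a 1.96 normal-quantile CI (no Knapp-Hartung adjustment).
#' A single study passes through unchanged with `tau2 = Q = 0`.
#'
#' @param y log standardized rates, one per network (log of the per-person
#'   rate; the result is reported per 1,000)
#' @param se standard errors of `y` (log scale), all positive
#' @return object of class `meta_result`: `pooled`, `ci_lo`, `ci_hi`
#'   (per 1,000), `tau2`, `Q`, `k`, `se_pooled`, `log_pooled`
#' @export
dl_meta <- function(y, se) {
  k <- length(y)
  if (k == 0) stop("no studies to pool")
  if (length(se) != k) stop("y and se lengths differ")
  if (any(!is.finite(y)) || any(!is.finite(se)) || any(se <= 0)) {
    stop("se must be positive and finite")
  }
  if (k == 1) {
    mu <- y; se_p <- se; tau2 <- 0; Q <- 0
  } else {
    w <- 1 / se^2
    ybar <- sum(w * y) / sum(w)
    Q <- sum(w * (y - ybar)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (se^2 + tau2)
    mu <- sum(ws * y) / sum(ws)
    se_p <- sqrt(1 / sum(ws))
  }
  structure(list(pooled = 1000 * exp(mu),
                 ci_lo = 1000 * exp(mu - 1.96 * se_p),
                 ci_hi = 1000 * exp(mu + 1.96 * se_p),
                 tau2 = tau2, Q = Q, k = k,
                 se_pooled = se_p, log_pooled = mu),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("pooled rate: %.3f per 1,000 (95%% CI %.3f - %.3f), k = %d, tau2 = %.4g, Q = %.3f\n",
              x$pooled, x$ci_lo, x$ci_hi, x$k, x$tau2, x$Q))
  invisible(x)
}

#' Pool network estimates given per-1,000 rates and log-scale SEs
#'
#' Convenience wrapper around [dl_meta()] for the pipeline's estimate tables.
#' Networks without a usable standard error (non-converged fits, boundary
#' cases without CI) are excluded with a message, mirroring the convention of
#' omitting unreliable networks from the pooled row.
#'
#' @param estimates data.frame with columns `network`, `value_per_1000`,
#'   `se_log`
#' @return a `meta_result`, or `NULL` when no network is poolable
#' @export
pool_networks <- function(estimates) {
  ok <- is.finite(estimates$value_per_1000) & estimates$value_per_1000 > 0 &
    is.finite(estimates$se_log) & estimates$se_log > 0
  if (any(!ok)) {
    message("excluded from pooling: ",
            paste(estimates$network[!ok], collapse = ", "))
  }
  if (!any(ok)) return(NULL)
  dl_meta(log(estimates$value_per_1000[ok] / 1000), estimates$se_log[ok])
}
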