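# Pareto-smoothed importance-sampling leave-one-out cross-validation.
# Implemented from the standard recipe: raw LOO importance ratios are
# 1/p(y_i | theta_s); the largest ~20% of log-ratios are replaced by
# quantiles of a generalized Pareto distribution fitted to the tail
# (Zhang-Stephens profile posterior-mean estimator), capped at the raw
# maximum; the smoothed weights give elpd_loo per observation.

# fit GPD to exceedances x (> 0); returns shape k and scale sigma
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  b <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) /
    (prior_bs * x[max(1, floor(n / 4 + 0.5))])
  ks <- vapply(b, function(bj) -mean(log1p(-bj * x)), numeric(1))
  lls <- n * (log(b / ks) + ks - 1)
  w <- 1 / vapply(lls, function(l) sum(exp(lls - l)), numeric(1))
  b_star <- sum(b * w)
  k <- -mean(log1p(-b_star * x))
  list(k = k, sigma = k / b_star)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-k * log1p(-p)) / k
}

# smooth one observation's log importance ratios; returns list(lw, khat)
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, khat = -Inf))
  ord <- order(lw, decreasing = TRUE)
  tail_idx <- ord[seq_len(M)]
  cutoff <- lw[ord[M + 1]]
  exc <- exp(lw[tail_idx]) - exp(cutoff)
  if (all(exc <= 0) || length(unique(exc)) < 2)
    return(list(lw = lw, khat = -Inf))
  fit <- gpd_fit(exc[exc > 0])
  qs <- gpd_quantile((seq_len(M) - 0.5) / M, fit$k, fit$sigma)
  smoothed <- sort(log(exp(cutoff) + qs), decreasing = TRUE)
  smoothed <- pmin(smoothed, max(lw))  # never exceed the raw maximum
  lw[tail_idx] <- smoothed
  list(lw = lw - max(lw), khat = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' Estimates leave-one-out ELPD from a matrix of pointwise log-likelihoods
#' (posterior draws in rows, observations in columns) by Pareto-smoothed
#' importance sampling.  Pareto shape diagnostics above 0.7 flag
#' observations whose LOO estimate is unreliable.
#'
#' @param log_lik draws x observations matrix, or a `dcm_fit`.
#' @return list of class `psis_loo`: `elpd_loo`, `se`, `pointwise`,
#'   `pareto_k`, `n_bad` (shape > 0.7).
#' @export
loo_elpd <- function(log_lik) {
  if (inherits(log_lik, "dcm_fit")) log_lik <- log_lik$pointwise_loglik
  stopifnot(is.matrix(log_lik))
  n <- ncol(log_lik)
  ptw <- numeric(n); kh <- numeric(n)
  for (i in seq_len(n)) {
    ll <- log_lik[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$lw
    kh[i] <- sm$khat
    # elpd_i = log( sum w * p / sum w )
    ptw[i] <- log_sum_exp(lw + ll) - log_sum_exp(lw)
  }
  structure(list(elpd_loo = sum(ptw),
                 se = sqrt(n * stats::var(ptw)),
                 pointwise = ptw, pareto_k = kh,
                 n_bad = sum(kh > 0.7)),
            class = "psis_loo")
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.psis_loo <- function(x, ...) {
  cat("PSIS-LOO: elpd_loo =", format(x$elpd_loo, digits = 6),
      " SE =", format(x$se, digits = 4), "\n")
  if (x$n_bad > 0)
    cat("  warning:", x$n_bad, "observation(s) with Pareto k > 0.7\n")
  invisible(x)
}

#' Compare models by leave-one-out expected log predictive density
#'
#' @param fits a named list of `dcm_fit` objects (or pointwise
#'   log-likelihood matrices) fitted to the same observations.
#' @return data frame of class `elpd_comparison`, sorted best first, with
#'   `elpd_loo`, `se`, and the difference to the best model with its
#'   standard error (from the pointwise differences).
#' @export
elpd_compare <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  loos <- lapply(fits, loo_elpd)
  ns <- vapply(loos, function(l) length(l$pointwise), integer(1))
  if (length(unique(ns)) != 1)
    stop("models were fitted to different observation sets")
  n <- ns[1]
  elpds <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  best <- which.max(elpds)
  out <- data.frame(model = names(fits),
                    elpd_loo = elpds,
                    se = vapply(loos, `[[`, numeric(1), "se"),
                    elpd_diff = elpds - elpds[best],
                    se_diff = vapply(seq_along(loos), function(j) {
                      d <- loos[[j]]$pointwise - loos[[best]]$pointwise
                      sqrt(n * stats::var(d))
                    }, numeric(1)),
                    pareto_k_bad = vapply(loos, `[[`, numeric(1), "n_bad"),
                    row.names = NULL)
  out <- out[order(-out$elpd_loo), ]
  rownames(out) <- NULL
  class(out) <- c("elpd_comparison", "data.frame")
  out
}
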