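# Adaptive random-walk Metropolis sampler with split-Rhat / ESS diagnostics.
# The proposal covariance is adapted during warmup (scaled empirical
# covariance, Haario-style) and frozen for the sampling phase, so the
# post-warmup chain is a valid Markov chain.

mh_sample <- function(logpost, init, chains = 4, iter = 1000, warmup = 1000,
                      seed = 1L, init_jitter = 0.1) {
  d <- length(init)
  if (is.null(names(init))) names(init) <- paste0("p", seq_len(d))
  draws <- vector("list", chains)
  lp_draws <- vector("list", chains)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    with_seed(seed + 1000L * ch, {
      x <- init + stats::rnorm(d, 0, init_jitter)
      lp <- logpost(x)
      tries <- 0
      while (!is.finite(lp) && tries < 100) {
        x <- init + stats::rnorm(d, 0, init_jitter)
        lp <- logpost(x); tries <- tries + 1
      }
      if (!is.finite(lp)) stop("could not find a finite-density start point")
      scale <- 2.38^2 / d
      S <- diag(init_jitter^2, d)
      chS <- chol(S)
      mean_x <- x; cov_x <- diag(1e-6, d); n_ad <- 1
      out <- matrix(NA_real_, iter, d)
      lp_out <- numeric(iter)
      n_acc <- 0; win_acc <- 0
      for (i in seq_len(warmup + iter)) {
        prop <- x + as.numeric(stats::rnorm(d) %*% chS) * sqrt(scale)
        lp_p <- logpost(prop)
        if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp) {
          x <- prop; lp <- lp_p
          if (i > warmup) n_acc <- n_acc + 1 else win_acc <- win_acc + 1
        }
        if (i <= warmup) {
          # running covariance update + global scale tuning (target ~0.23)
          n_ad <- n_ad + 1
          dx <- x - mean_x
          mean_x <- mean_x + dx / n_ad
          cov_x <- cov_x * (n_ad - 2) / (n_ad - 1) + tcrossprod(dx) / n_ad
          if (i %% 50 == 0) {
            scale <- scale * exp(2 * (win_acc / 50 - 0.234))
            scale <- min(max(scale, 1e-8), 1e4)
            win_acc <- 0
            if (i >= 100) {
              S <- cov_x + diag(1e-10 + 1e-6 * mean(diag(cov_x)), d)
              chS <- tryCatch(chol(S), error = function(e) chS)
            }
          }
        } else {
          out[i - warmup, ] <- x
          lp_out[i - warmup] <- lp
        }
      }
      colnames(out) <- names(init)
      draws[[ch]] <- out
      lp_draws[[ch]] <- lp_out
      accept[ch] <- n_acc / iter
    })
  }
  all_draws <- do.call(rbind, draws)
  colnames(all_draws) <- names(init)
  diag_tab <- mcmc_diagnostics(draws)
  list(draws = all_draws,
       chain = rep(seq_len(chains), each = iter),
       lp = unlist(lp_draws),
       accept_rate = accept,
       diagnostics = diag_tab,
       converged = all(diag_tab$rhat < 1.01, na.rm = TRUE))
}

# split-chain Rhat and a crude effective sample size per parameter
mcmc_diagnostics <- function(chain_list) {
  d <- ncol(chain_list[[1]])
  iter <- nrow(chain_list[[1]])
  half <- floor(iter / 2)
  splits <- list()
  for (ch in chain_list) {
    splits <- c(splits, list(ch[seq_len(half), , drop = FALSE],
                             ch[(iter - half + 1):iter, , drop = FALSE]))
  }
  rhat <- numeric(d); ess <- numeric(d)
  for (j in seq_len(d)) {
    mats <- lapply(splits, function(m) m[, j])
    means <- vapply(mats, mean, numeric(1))
    vars <- vapply(mats, stats::var, numeric(1))
    W <- mean(vars)
    B <- half * stats::var(means)
    vhat <- (half - 1) / half * W + B / half
    rhat[j] <- if (W > 0) sqrt(vhat / W) else 1
    # ESS from lag autocorrelations of the pooled (centred) chains
    rho_sum <- 0; n_ok <- 0
    for (m in mats) {
      if (stats::sd(m) == 0) next
      ac <- stats::acf(m, lag.max = min(100, half - 1), plot = FALSE,
                       demean = TRUE)$acf[-1]
      ac <- ac[is.finite(ac)]
      pos <- which(ac < 0.05)
      cut <- if (length(pos)) pos[1] - 1 else length(ac)
      rho_sum <- rho_sum + (if (cut > 0) sum(ac[seq_len(cut)]) else 0)
      n_ok <- n_ok + 1
    }
    if (n_ok == 0) { ess[j] <- NA_real_; next }
    rho_bar <- rho_sum / n_ok
    ess[j] <- length(mats) * half / (1 + 2 * max(rho_bar, 0))
  }
  data.frame(parameter = colnames(chain_list[[1]]), rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}
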