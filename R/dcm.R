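#' Priors for the diachronic causal models
#'
#' Regression coefficients (`alpha`, `eta`, `gamma`, `rho`) and the variance
#' slope `beta` get `Normal(0, coef_sd)` priors; the baseline residual scale
#' `sigma0` gets `Exponential(sigma0_rate)`.  Ratio-type outcomes (values
#' confined to a narrow band, like a vowel-to-segment ratio) use the tighter
#' `Normal(0, 0.5)` / `Exponential(5)` settings.
#'
#' @param outcome_type `"count"` (default) or `"ratio"`.
#' @param coef_sd,sigma0_rate override individual settings.
#' @return a list of class `dcm_priors`.
#' @export
dcm_priors <- function(outcome_type = c("count", "ratio"),
                       coef_sd = NULL, sigma0_rate = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (is.null(coef_sd)) coef_sd <- if (outcome_type == "ratio") 0.5 else 1
  if (is.null(sigma0_rate)) sigma0_rate <- if (outcome_type == "ratio") 5 else 1
  structure(list(outcome_type = outcome_type, coef_sd = coef_sd,
                 sigma0_rate = sigma0_rate),
            class = "dcm_priors")
}

#' Log-likelihood of the linear-confound diachronic model
#'
#' For each node pair `i` the trait change `T_desc - T_anc` is normal with
#' mean `(alpha + eta*H + gamma*Gt + rho*Pt) * dA` and standard deviation
#' `sigma0 + beta*dA`.  `Gt`, `Pt` and the endpoint trait values are latent
#' arguments; by default they are taken at their measurement means
#' (`Gt_MEAN`, `Pt_MEAN` and the table's `T_anc`/`T_desc`).
#'
#' @param params list with `alpha`, `eta`, `gamma`, `rho`, `sigma0`, `beta`
#'   and optional vectors `Gt`, `Pt`, `T_anc`, `T_desc` overriding the
#'   table's columns.
#' @param pair_table a [build_node_pair_table()] result.
#' @return the summed log-likelihood; `-Inf` when any row's standard
#'   deviation `sigma0 + beta*dA` is non-positive.
#' @export
loglik_model_lin <- function(params, pair_table) {
  n <- nrow(pair_table)
  Gt <- if (!is.null(params$Gt)) params$Gt else pair_table$Gt_MEAN
  Pt <- if (!is.null(params$Pt)) params$Pt else pair_table$Pt_MEAN
  Ta <- if (!is.null(params$T_anc)) params$T_anc else pair_table$T_anc
  Td <- if (!is.null(params$T_desc)) params$T_desc else pair_table$T_desc
  if (length(Gt) != n || length(Pt) != n || length(Ta) != n || length(Td) != n)
    stop("dimension mismatch between params and pair_table")
  dA <- pair_table$dA
  sig <- params$sigma0 + params$beta * dA
  if (any(sig <= 0)) return(-Inf)
  mu <- (params$alpha + params$eta * pair_table$H +
           params$gamma * Gt + params$rho * Pt) * dA
  sum(stats::dnorm(Td - Ta, mu, sig, log = TRUE))
}

#' Log-density contribution of the measurement layers
#'
#' The latent quantities of the linear model are tied to their measured
#' summaries: each interior node's latent trait value is
#' `Normal(T_REC, T_SE)` (one shared latent per node; nodes with
#' `T_SE = 0` — leaves and fossilised nodes — are fixed constants and
#' contribute nothing), and each row's latent neighbourhood means are
#' `Gt_i ~ Normal(Gt_MEAN_i, Gt_SD_i)` and `Pt_i ~ Normal(Pt_MEAN_i,
#' Pt_SD_i)` (rows with zero SD fix the latent at the mean).
#'
#' @param params list with optional `T` (named vector of latent node
#'   values), `Gt`, `Pt` (per-row latents).
#' @param reconstruction a [asr_brownian()] result.
#' @param pair_table a [build_node_pair_table()] result.
#' @return the summed log-density of the layers.
#' @export
latent_measurement_layers <- function(params, reconstruction, pair_table) {
  out <- 0
  if (!is.null(params$T)) {
    idx <- match(names(params$T), reconstruction$id)
    if (anyNA(idx)) stop("unknown node ids in params$T")
    se <- reconstruction$T_SE[idx]
    free <- se > 0
    out <- out + sum(stats::dnorm(params$T[free],
                                  reconstruction$T_REC[idx][free],
                                  se[free], log = TRUE))
  }
  for (nm in c("Gt", "Pt")) {
    v <- params[[nm]]
    if (is.null(v)) next
    mcol <- pair_table[[paste0(nm, "_MEAN")]]
    scol <- pair_table[[paste0(nm, "_SD")]]
    free <- scol > 0
    out <- out + sum(stats::dnorm(v[free], mcol[free], scol[free],
                                  log = TRUE))
  }
  out
}

#' Gaussian-process kernels over geographic and phylogenetic distance
#'
#' The geographic kernel is a squared-exponential
#' `amplitude^2 * exp(-delta^2 / (2 * lengthscale^2))` (plus a diagonal
#' jitter), appropriate for smooth spatial similarity; the phylogenetic
#' kernel is an Ornstein-Uhlenbeck (exponential) kernel
#' `amplitude^2 * exp(-delta / lengthscale)`, whose rougher sample paths
#' match the way shared history decays along a tree.  Both yield symmetric
#' positive-definite covariance matrices on any distance matrix.
#'
#' @param delta nonnegative distance (scalar, vector or matrix).
#' @param amplitude,lengthscale kernel hyperparameters (> 0).
#' @param jitter nugget added where `delta == 0` (geographic kernel only).
#' @return covariance value(s) of the same shape as `delta`.
#' @export
gp_kernel_geo <- function(delta, amplitude, lengthscale, jitter = 1e-6) {
  stopifnot(all(delta >= 0), amplitude > 0, lengthscale > 0, jitter >= 0)
  amplitude^2 * exp(-delta^2 / (2 * lengthscale^2)) + jitter * (delta == 0)
}

#' @rdname gp_kernel_geo
#' @export
gp_kernel_phylo <- function(delta, amplitude, lengthscale) {
  stopifnot(all(delta >= 0), amplitude > 0, lengthscale > 0)
  amplitude^2 * exp(-delta / lengthscale)
}

# per-row log-likelihood for the LIN model with the Gt/Pt measurement
# latents marginalised out analytically (they enter the mean linearly with
# independent normal priors, so each row stays normal with inflated sd)
dcm_lin_pointwise <- function(th, dat) {
  sig <- th["sigma0"] + th["beta"] * dat$dA
  if (any(sig <= 0)) return(NULL)
  mu <- (th["alpha"] + th["eta"] * dat$H +
           th["gamma"] * dat$Gt_MEAN + th["rho"] * dat$Pt_MEAN) * dat$dA
  v <- sig^2 + (th["gamma"] * dat$dA * dat$Gt_SD)^2 +
    (th["rho"] * dat$dA * dat$Pt_SD)^2
  stats::dnorm(dat$dT, mu, sqrt(v), log = TRUE)
}

#' Fit a diachronic causal model of trait change
#'
#' The package's core model: ancestor-to-descendant trait changes along the
#' edges of a geo-phylogeny are regressed on the mean humidity experienced
#' along the edge, controlling for geographic proximity (contact/borrowing)
#' and residual phylogenetic similarity (rate/drift), with effects
#' normalised per 1000 years through the multiplicative `dA` term and a
#' residual scale `sigma0 + beta*dA` that may grow with temporal distance.
#'
#' Two variants differ in the confound terms: `variant = "lin"` uses the
#' measured neighbourhood trait means (`gamma*Gt + rho*Pt` inside the
#' `dA`-scaled predictor, with per-row measurement latents that are
#' marginalised analytically); `variant = "gp"` replaces them with latent
#' per-node effects drawn from Gaussian processes over geographic and
#' cophenetic distance (marginalised analytically into a multivariate
#' normal likelihood).  Interior-node trait values with positive
#' reconstruction standard errors are sampled as latent variables by exact
#' Gibbs updates within the Metropolis sweep.
#'
#' Sampling is adaptive random-walk Metropolis (covariance tuned during
#' warmup, frozen for sampling) with split-chain Rhat and effective sample
#' size diagnostics; a fit with any Rhat >= 1.01 is flagged unconverged,
#' never silently returned as good.
#'
#' @param pair_table a [build_node_pair_table()] result.
#' @param variant `"lin"` or `"gp"`.
#' @param confounds character subset of `c("geo", "phylo")`: which confound
#'   terms to include (model-comparison grid of the study design).
#' @param priors a [dcm_priors()] object.
#' @param distances for `variant = "gp"`: list with elements `geo` and/or
#'   `phylo`, distance matrices whose dimnames cover the table's descendant
#'   node ids (see [greatcircle_matrix()], [cophenetic_matrix()]).
#' @param reconstruction optional [asr_brownian()] result; required when
#'   the table carries positive `T_anc_se`/`T_desc_se` so latent node
#'   values can be anchored.
#' @param chains,iter,warmup,seed sampler settings (`iter` post-warmup
#'   draws per chain).
#' @param gp_jitter diagonal nugget for the geographic kernel.
#' @param prior_only if `TRUE`, sample from the priors only (the
#'   likelihood is switched off); used for prior-predictive checks.
#' @return an object of class `dcm_fit`; see [summary.dcm_fit()].
#' @export
fit_dcm <- function(pair_table, variant = c("lin", "gp"),
                    confounds = c("geo", "phylo"), priors = dcm_priors(),
                    distances = NULL, reconstruction = NULL,
                    chains = 4, iter = 1000, warmup = 1000, seed = 1L,
                    gp_jitter = 1e-6, prior_only = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(pair_table, "node_pair_table") ||
              is.data.frame(pair_table))
  confounds <- intersect(confounds, c("geo", "phylo"))
  n <- nrow(pair_table)

  has_latent_T <- any(pair_table$T_anc_se > 0 | pair_table$T_desc_se > 0)
  if (has_latent_T && is.null(reconstruction))
    stop("pair table has reconstructed nodes; supply `reconstruction`")
  if (has_latent_T && variant == "gp")
    stop("latent node values are only supported for variant = 'lin'")

  dat <- list(dT = pair_table$T_desc - pair_table$T_anc,
              dA = pair_table$dA, H = pair_table$H,
              Gt_MEAN = pair_table$Gt_MEAN, Gt_SD = pair_table$Gt_SD,
              Pt_MEAN = pair_table$Pt_MEAN, Pt_SD = pair_table$Pt_SD)
  use_geo <- "geo" %in% confounds
  use_phylo <- "phylo" %in% confounds

  if (variant == "lin") {
    fit <- dcm_fit_lin(dat, pair_table, use_geo, use_phylo, priors,
                       reconstruction, chains, iter, warmup, seed,
                       prior_only)
  } else {
    fit <- dcm_fit_gp(dat, pair_table, use_geo, use_phylo, priors,
                      distances, chains, iter, warmup, seed, gp_jitter,
                      prior_only)
  }
  fit$spec <- list(variant = variant, confounds = confounds,
                   priors = priors, chains = chains, iter = iter,
                   warmup = warmup, seed = seed, n_obs = n)
  fit$converged <- all(fit$diagnostics$rhat < 1.01, na.rm = TRUE)
  class(fit) <- "dcm_fit"
  fit
}

# Blocked Gibbs sampler for the LIN variant.  The regression coefficients
# are conditionally conjugate (exact multivariate-normal Gibbs draw), the
# per-row Gt/Pt measurement latents and any latent interior-node trait
# values are conjugate normals, and only (log sigma0, beta) need a small
# adaptive Metropolis step -- so the sampler mixes well despite the
# deliberately uncentred covariate scaling.
dcm_fit_lin <- function(dat, pair_table, use_geo, use_phylo, priors,
                        reconstruction, chains, iter, warmup, seed,
                        prior_only = FALSE) {
  cs <- priors$coef_sd; rate <- priors$sigma0_rate
  cn <- c("alpha", "eta", if (use_geo) "gamma", if (use_phylo) "rho")
  d_b <- length(cn)
  n <- nrow(pair_table)
  dA <- dat$dA
  gt_free <- use_geo & dat$Gt_SD > 0
  pt_free <- use_phylo & dat$Pt_SD > 0

  has_latent_T <- any(pair_table$T_anc_se > 0 | pair_table$T_desc_se > 0)
  if (has_latent_T) {
    ids <- unique(c(pair_table$anc_id[pair_table$T_anc_se > 0],
                    pair_table$desc_id[pair_table$T_desc_se > 0]))
    ridx <- match(ids, reconstruction$id)
    if (anyNA(ridx)) stop("reconstruction missing latent node(s)")
    prior_m <- reconstruction$T_REC[ridx]
    prior_s <- reconstruction$T_SE[ridx]
    anc_of <- match(pair_table$anc_id, ids)   # NA if fixed
    desc_of <- match(pair_table$desc_id, ids)
  } else ids <- character(0)
  Ta_fix <- pair_table$T_anc; Td_fix <- pair_table$T_desc

  all_draws <- NULL; all_chain <- NULL; all_T <- NULL
  pointwise <- NULL; accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    with_seed(seed + 1000L * ch, {
      # initial state
      b <- stats::setNames(stats::rnorm(d_b, 0, 0.1), cn)
      b["alpha"] <- mean(dat$dT / dA)
      Gt <- dat$Gt_MEAN; Pt <- dat$Pt_MEAN
      s0 <- stats::sd(dat$dT)
      if (!is.finite(s0) || s0 < 0.1) s0 <- max(abs(dat$dT), 0.5)
      ls0 <- log(s0) + stats::rnorm(1, 0, 0.1)
      beta <- stats::rnorm(1, 0, 0.05)
      if (has_latent_T) {
        Tlat <- prior_m + stats::rnorm(length(ids), 0, prior_s)
        Ta <- ifelse(is.na(anc_of), Ta_fix, Tlat[anc_of])
        Td <- ifelse(is.na(desc_of), Td_fix, Tlat[desc_of])
      } else { Ta <- Ta_fix; Td <- Td_fix }
      y <- Td - Ta

      sig_step <- 0.1; win_acc <- 0; n_acc <- 0
      draws <- matrix(NA_real_, iter, d_b + 2)
      colnames(draws) <- c(cn, "sigma0", "beta")
      Tdraws <- if (has_latent_T) matrix(NA_real_, iter, length(ids))
      pw <- matrix(NA_real_, iter, n)
      s_row <- exp(ls0) + beta * dA
      while (any(s_row <= 0)) { beta <- beta / 2; s_row <- exp(ls0) + beta * dA }

      for (i in seq_len(warmup + iter)) {
        w <- if (prior_only) rep(0, n) else 1 / s_row^2
        # (1) exact Gibbs draw of the coefficient block
        X <- cbind(dA, dat$H * dA,
                   if (use_geo) Gt * dA, if (use_phylo) Pt * dA)
        A <- crossprod(X, X * w) + diag(1 / cs^2, d_b)
        chA <- chol(A)
        m_b <- backsolve(chA, forwardsolve(t(chA), crossprod(X, w * y)))
        b[] <- m_b + backsolve(chA, stats::rnorm(d_b))
        mu <- as.numeric(X %*% b)
        # (2) conjugate update of the Gt / Pt measurement latents
        if (any(gt_free)) {
          cc <- b["gamma"] * dA[gt_free]
          r <- y[gt_free] - (mu[gt_free] - cc * Gt[gt_free])
          prec <- 1 / dat$Gt_SD[gt_free]^2 + cc^2 * w[gt_free]
          mn <- (dat$Gt_MEAN[gt_free] / dat$Gt_SD[gt_free]^2 +
                   cc * r * w[gt_free]) / prec
          Gt[gt_free] <- stats::rnorm(sum(gt_free), mn, sqrt(1 / prec))
          X[gt_free, which(cn == "gamma")] <- Gt[gt_free] * dA[gt_free]
          mu <- as.numeric(X %*% b)
        }
        if (any(pt_free)) {
          cc <- b["rho"] * dA[pt_free]
          r <- y[pt_free] - (mu[pt_free] - cc * Pt[pt_free])
          prec <- 1 / dat$Pt_SD[pt_free]^2 + cc^2 * w[pt_free]
          mn <- (dat$Pt_MEAN[pt_free] / dat$Pt_SD[pt_free]^2 +
                   cc * r * w[pt_free]) / prec
          Pt[pt_free] <- stats::rnorm(sum(pt_free), mn, sqrt(1 / prec))
          X[pt_free, which(cn == "rho")] <- Pt[pt_free] * dA[pt_free]
          mu <- as.numeric(X %*% b)
        }
        # (3) adaptive Metropolis on (log sigma0, beta); several substeps
        # since this is the only non-conjugate block
        for (sub in 1:3) {
          prop <- c(ls0, beta) + stats::rnorm(2, 0, sig_step)
          s_prop <- exp(prop[1]) + prop[2] * dA
          if (all(s_prop > 0)) {
            llw <- if (prior_only) 0 else 1
            cur_lp <- llw * sum(stats::dnorm(y, mu, s_row, log = TRUE)) +
              stats::dexp(exp(ls0), rate, log = TRUE) + ls0 +
              stats::dnorm(beta, 0, cs, log = TRUE)
            prop_lp <- llw * sum(stats::dnorm(y, mu, s_prop, log = TRUE)) +
              stats::dexp(exp(prop[1]), rate, log = TRUE) + prop[1] +
              stats::dnorm(prop[2], 0, cs, log = TRUE)
            if (log(stats::runif(1)) < prop_lp - cur_lp) {
              ls0 <- prop[1]; beta <- prop[2]; s_row <- s_prop
              if (i > warmup) n_acc <- n_acc + 1 else win_acc <- win_acc + 1
            }
          }
        }
        if (i <= warmup && i %% 50 == 0) {
          sig_step <- sig_step * exp(2 * (win_acc / 150 - 0.234))
          sig_step <- min(max(sig_step, 1e-6), 10)
          win_acc <- 0
        }
        # (4) exact Gibbs update of latent interior-node trait values
        if (has_latent_T) {
          for (j in seq_along(ids)) {
            prec <- 1 / prior_s[j]^2
            msum <- prior_m[j] / prior_s[j]^2
            ra <- which(anc_of == j)   # node is ancestor: Tj ~ N(Td - mu, s)
            if (length(ra)) {
              prec <- prec + sum(w[ra])
              msum <- msum + sum((Td[ra] - mu[ra]) * w[ra])
            }
            rd <- which(desc_of == j)  # node is descendant: Tj ~ N(Ta + mu, s)
            if (length(rd)) {
              prec <- prec + sum(w[rd])
              msum <- msum + sum((Ta[rd] + mu[rd]) * w[rd])
            }
            Tlat[j] <- stats::rnorm(1, msum / prec, sqrt(1 / prec))
            if (length(ra)) Ta[ra] <- Tlat[j]
            if (length(rd)) Td[rd] <- Tlat[j]
          }
          y <- Td - Ta
        }
        if (i > warmup) {
          k <- i - warmup
          draws[k, ] <- c(b, exp(ls0), beta)
          if (has_latent_T) Tdraws[k, ] <- Tlat
          # pointwise log-likelihood with Gt/Pt marginalised (rows are
          # conditionally independent given theta and the latent T values)
          th <- c(alpha = unname(b["alpha"]), eta = unname(b["eta"]),
                  gamma = if (use_geo) unname(b["gamma"]) else 0,
                  rho = if (use_phylo) unname(b["rho"]) else 0,
                  sigma0 = exp(ls0), beta = beta)
          dat_i <- dat; dat_i$dT <- y
          pw[k, ] <- dcm_lin_pointwise(th, dat_i)
        }
      }
      all_draws <- rbind(all_draws, draws)
      if (has_latent_T) all_T <- rbind(all_T, Tdraws)
      all_chain <- c(all_chain, rep(ch, iter))
      pointwise <- rbind(pointwise, pw)
      accept[ch] <- n_acc / (3 * iter)
    })
  }
  if (has_latent_T) colnames(all_T) <- ids
  list(draws = all_draws, chain = all_chain, accept_rate = accept,
       diagnostics = diag_on(all_draws, all_chain), converged = NULL,
       pointwise_loglik = pointwise, latent_T = all_T)
}

diag_on <- function(draws, chain) {
  chains <- split.data.frame(draws, chain)
  mcmc_diagnostics(chains)
}

dcm_fit_gp <- function(dat, pair_table, use_geo, use_phylo, priors,
                       distances, chains, iter, warmup, seed, gp_jitter,
                       prior_only = FALSE) {
  if ((use_geo && is.null(distances$geo)) ||
      (use_phylo && is.null(distances$phylo)))
    stop("variant 'gp' needs distance matrices for each included confound")
  ids <- pair_table$desc_id
  get_d <- function(m) {
    if (!all(ids %in% rownames(m)))
      stop("distance matrix does not cover all descendant nodes")
    m[ids, ids]
  }
  Dg <- if (use_geo) get_d(distances$geo) else NULL
  Dp <- if (use_phylo) get_d(distances$phylo) else NULL
  ls_mu_g <- if (use_geo) log(stats::median(Dg[Dg > 0])) else NA
  ls_mu_p <- if (use_phylo) log(stats::median(Dp[Dp > 0])) else NA

  cs <- priors$coef_sd; rate <- priors$sigma0_rate
  par_names <- c("alpha", "eta", "log_sigma0", "beta",
                 if (use_geo) c("log_amp_geo", "log_ls_geo"),
                 if (use_phylo) c("log_amp_phylo", "log_ls_phylo"))
  n <- length(dat$dT)
  # centred sampling parameterisation (see dcm_fit_lin)
  Hbar <- mean(dat$H)
  Hc <- dat$H - Hbar

  build_cov <- function(p) {
    sig <- exp(p["log_sigma0"]) + p["beta"] * dat$dA
    if (any(sig <= 0)) return(NULL)
    K <- matrix(0, n, n)
    if (use_geo)
      K <- K + gp_kernel_geo(Dg, exp(p["log_amp_geo"]), exp(p["log_ls_geo"]),
                             jitter = gp_jitter)
    if (use_phylo)
      K <- K + gp_kernel_phylo(Dp, exp(p["log_amp_phylo"]),
                               exp(p["log_ls_phylo"]))
    Sig <- dat$dA * t(dat$dA * K) + diag(sig^2)
    list(Sig = Sig, sig = sig)
  }
  lp <- function(p) {
    cv <- build_cov(p)
    if (is.null(cv)) return(-Inf)
    ch <- tryCatch(chol(cv$Sig), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    mu <- (p["alpha"] + p["eta"] * Hc) * dat$dA
    r <- dat$dT - mu
    z <- forwardsolve(t(ch), r)
    ll <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
    if (prior_only) ll <- 0
    pr <- stats::dnorm(p["alpha"] - p["eta"] * Hbar, 0, cs, log = TRUE) +
      stats::dnorm(p["eta"], 0, cs, log = TRUE) +
      stats::dnorm(p["beta"], 0, cs, log = TRUE) +
      stats::dexp(exp(p["log_sigma0"]), rate, log = TRUE) + p["log_sigma0"]
    if (use_geo)
      pr <- pr + stats::dnorm(exp(p["log_amp_geo"]), 0, 1, log = TRUE) +
        log(2) + p["log_amp_geo"] +
        stats::dnorm(p["log_ls_geo"], ls_mu_g, 1, log = TRUE)
    if (use_phylo)
      pr <- pr + stats::dnorm(exp(p["log_amp_phylo"]), 0, 1, log = TRUE) +
        log(2) + p["log_amp_phylo"] +
        stats::dnorm(p["log_ls_phylo"], ls_mu_p, 1, log = TRUE)
    ll + pr
  }
  init <- stats::setNames(rep(0, length(par_names)), par_names)
  init["alpha"] <- mean(dat$dT / dat$dA)
  init["log_sigma0"] <- log(max(stats::sd(dat$dT), 0.1))
  init["beta"] <- 0
  if (use_geo) { init["log_amp_geo"] <- log(0.5); init["log_ls_geo"] <- ls_mu_g }
  if (use_phylo) { init["log_amp_phylo"] <- log(0.5); init["log_ls_phylo"] <- ls_mu_p }

  raw <- mh_sample(lp, init, chains, iter, warmup, seed)
  S <- nrow(raw$draws)
  # pointwise conditional log-likelihood log p(y_i | y_-i, theta) per draw
  pointwise <- matrix(NA_real_, S, n)
  for (s in seq_len(S)) {
    p <- raw$draws[s, ]
    cv <- build_cov(p)
    mu <- (p["alpha"] + p["eta"] * Hc) * dat$dA
    Prec <- chol2inv(chol(cv$Sig))
    r <- dat$dT - mu
    cond_var <- 1 / diag(Prec)
    cond_mean <- dat$dT - (Prec %*% r) * cond_var
    pointwise[s, ] <- stats::dnorm(dat$dT, cond_mean, sqrt(cond_var),
                                   log = TRUE)
  }
  draws <- raw$draws
  draws[, "alpha"] <- draws[, "alpha"] - draws[, "eta"] * Hbar
  nat_names <- sub("^log_", "", colnames(draws))
  for (j in which(startsWith(colnames(draws), "log_")))
    draws[, j] <- exp(draws[, j])
  colnames(draws) <- nat_names
  list(draws = draws, chain = raw$chain, accept_rate = raw$accept_rate,
       diagnostics = diag_on(draws, raw$chain), converged = NULL,
       pointwise_loglik = pointwise, latent_T = NULL)
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("Diachronic causal model fit (variant ",
      toupper(x$spec$variant), ")\n", sep = "")
  cat("  confounds:",
      if (length(x$spec$confounds)) paste(x$spec$confounds, collapse = " + ")
      else "none", "\n")
  cat("  observations:", x$spec$n_obs, " draws:", nrow(x$draws),
      "(", x$spec$chains, "chains )\n")
  conv <- all(x$diagnostics$rhat < 1.01, na.rm = TRUE)
  cat("  converged:", conv,
      " max Rhat:", format(max(x$diagnostics$rhat), digits = 4), "\n")
  print(coef(x), digits = 3)
  invisible(x)
}

#' Posterior summary of a diachronic model fit
#'
#' @param object a `dcm_fit`.
#' @param prob mass of the central credible interval.
#' @param ... unused.
#' @return data frame with posterior mean, sd, credible bounds, Rhat, ESS.
#' @export
summary.dcm_fit <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  qs <- apply(object$draws, 2, stats::quantile, probs = c(a, 1 - a))
  out <- data.frame(parameter = colnames(object$draws),
                    mean = colMeans(object$draws),
                    sd = apply(object$draws, 2, stats::sd),
                    lower = qs[1, ], upper = qs[2, ],
                    rhat = object$diagnostics$rhat,
                    ess = object$diagnostics$ess,
                    row.names = NULL)
  attr(out, "prob") <- prob
  out
}

#' @export
coef.dcm_fit <- function(object, ...) colMeans(object$draws)

#' @export
as.matrix.dcm_fit <- function(x, ...) x$draws

#' Posterior density plot for model parameters
#'
#' @param x a `dcm_fit`.
#' @param parameters which columns to plot (default: all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.dcm_fit <- function(x, parameters = colnames(x$draws), ...) {
  old <- graphics::par(mfrow = c(ceiling(length(parameters) / 2),
                                 min(2, length(parameters))))
  on.exit(graphics::par(old))
  for (pm in parameters) {
    d <- stats::density(x$draws[, pm])
    graphics::plot(d, main = pm, xlab = pm, ...)
  }
  invisible(x)
}

#' Savage-Dickey density ratio for a point null
#'
#' Bayes factor `BF10 = prior density at 0 / posterior density at 0` for a
#' model parameter; values below 1 support the null.  The posterior density
#' is a Gaussian kernel estimate (Silverman bandwidth) evaluated at 0; when
#' essentially no posterior mass lies near 0 the KDE hits the machine floor
#' and the Bayes factor is reported as a lower bound with `floored = TRUE`.
#'
#' @param fit a `dcm_fit`, or a numeric vector of posterior samples.
#' @param parameter column name of the parameter (ignored when `fit` is a
#'   vector).
#' @param prior_density function evaluating the prior density; when `NULL`
#'   and `fit` is a `dcm_fit`, the fit's own `Normal(0, coef_sd)` prior is
#'   used.
#' @return list of class `savage_dickey`: `bf10`, `prior_density0`,
#'   `posterior_density0`, `floored`.
#' @export
savage_dickey <- function(fit, parameter = "eta", prior_density = NULL) {
  if (inherits(fit, "dcm_fit")) {
    samples <- fit$draws[, parameter]
    if (is.null(prior_density)) {
      cs <- fit$spec$priors$coef_sd
      prior_density <- function(x) stats::dnorm(x, 0, cs)
    }
  } else {
    samples <- as.numeric(fit)
    if (is.null(prior_density)) stop("supply prior_density for raw samples")
  }
  bw <- stats::bw.nrd0(samples)
  post0 <- mean(stats::dnorm(0, samples, bw))
  prior0 <- prior_density(0)
  floored <- post0 <= .Machine$double.xmin
  bf10 <- if (floored) prior0 / .Machine$double.xmin else prior0 / post0
  structure(list(bf10 = bf10, prior_density0 = prior0,
                 posterior_density0 = post0, floored = floored),
            class = "savage_dickey")
}

#' @export
print.savage_dickey <- function(x, ...) {
  cat("Savage-Dickey density ratio\n")
  if (x$floored)
    cat("  BF10 >", format(x$bf10, digits = 4),
        "(no posterior mass near 0; lower bound)\n")
  else cat("  BF10 =", format(x$bf10, digits = 4), "\n")
  cat("  prior density at 0:", format(x$prior_density0, digits = 4),
      " posterior density at 0:", format(x$posterior_density0, digits = 4),
      "\n")
  invisible(x)
}
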