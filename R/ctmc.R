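#' Binarize a continuous variable at a threshold
#'
#' @param values numeric vector (optionally named).
#' @param threshold split point (e.g. the sample mean humidity, or 2.5
#'   tones for a "two or fewer vs three or more" split).
#' @param rule `"le_threshold_is_0"`: values `<= threshold` code as 0;
#'   `"lt_threshold_is_0"`: values `< threshold` code as 0.
#' @return integer 0/1 vector with attributes `threshold` and `rule`;
#'   warns (does not error) if the threshold lies outside the data range.
#' @export
binarize <- function(values, threshold,
                     rule = c("le_threshold_is_0", "lt_threshold_is_0")) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(values), is.numeric(threshold), length(threshold) == 1)
  if (threshold < min(values, na.rm = TRUE) ||
      threshold > max(values, na.rm = TRUE))
    warning("threshold ", threshold, " outside data range [",
            min(values, na.rm = TRUE), ", ", max(values, na.rm = TRUE), "]")
  out <- if (rule == "le_threshold_is_0") as.integer(values > threshold)
         else as.integer(values >= threshold)
  names(out) <- names(values)
  attr(out, "threshold") <- threshold
  attr(out, "rule") <- rule
  out
}

# build the k-state transition probability matrix exp(Q*t)
ctmc_pmat <- function(Q, t) {
  if (t == 0) return(diag(nrow(Q)))
  ape::matexpo(Q * t)
}

# precomputed traversal structure so repeated likelihood evaluations
# (optimisation, stepping-stone sampling) avoid rebuilding edge tables
ctmc_prep <- function(tree, k) {
  nd <- tree$nodes
  ed <- gp_edges(tree)
  child_list <- rep(list(integer(0)), nrow(nd))
  for (i in seq_len(nrow(ed)))
    child_list[[ed$anc[i]]] <- c(child_list[[ed$anc[i]]], i)
  inner_order <- unique(ed$anc[order(ed$age_anc, ed$desc)])
  list(n_node = nrow(nd), ids = nd$id, is_leaf = nd$is_leaf,
       leaves = which(nd$is_leaf), root = nd$node[is.na(nd$parent)],
       edge_anc = ed$anc, edge_desc = ed$desc,
       edge_len = pmax(ed$length, 0),
       child_list = child_list, inner_order = inner_order, k = k,
       fossil_nodes = integer(0))
}

# leaf/fossil partial-likelihood matrix for a prep structure
ctmc_partials <- function(prep, leaf_states, fossils) {
  L <- matrix(0, prep$n_node, prep$k)
  L[cbind(prep$leaves, leaf_states[prep$ids[prep$leaves]])] <- 1
  fossil_inner <- integer(0)
  if (!is.null(fossils)) {
    for (id in names(fossils)) {
      v <- match(id, prep$ids)
      if (is.na(v)) stop("unknown fossil node id: ", id)
      mask <- rep(0, prep$k); mask[fossils[[id]]] <- 1
      if (prep$is_leaf[v]) L[v, ] <- L[v, ] * mask
      else { L[v, ] <- mask; fossil_inner <- c(fossil_inner, v) }
    }
  }
  list(L = L, fossil_inner = fossil_inner)
}

# pruning log-likelihood given precomputed structure; transition matrices
# come from one eigendecomposition of Q per call (exp(lambda * t) cached
# for every edge), with a matexpo fallback for near-defective generators
ctmc_loglik_core <- function(prep, part, Q, root_p) {
  k <- prep$k
  eg <- eigen(Q)
  rc <- tryCatch(rcond(abs(eg$vectors)), error = function(e) 0)
  use_eigen <- is.finite(rc) && rc > 1e-10
  if (use_eigen) {
    V <- eg$vectors
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi)) use_eigen <- FALSE
  }
  if (use_eigen) {
    ex <- exp(outer(eg$values, prep$edge_len))  # k x n_edges, complex
    tprod <- function(kk, Ld) {
      p <- Re(V %*% (ex[, kk] * (Vi %*% Ld)))
      p[p < 0] <- 0
      p
    }
  } else {
    tprod <- function(kk, Ld) {
      as.numeric(ape::matexpo(Q * prep$edge_len[kk]) %*% Ld)
    }
  }
  L <- part$L
  scale_log <- 0
  for (v in prep$inner_order) {
    partial <- rep(1, k)
    for (kk in prep$child_list[[v]])
      partial <- partial * tprod(kk, L[prep$edge_desc[kk], ])
    if (v %in% part$fossil_inner) partial <- partial * L[v, ]
    m <- max(partial)
    if (m <= 0) return(-Inf)
    scale_log <- scale_log + log(m)
    L[v, ] <- partial / m
  }
  lik <- sum(root_p * L[prep$root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + scale_log
}

# stationary distribution of a generator (left null vector)
ctmc_stationary <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- stats::lsfit(A, b, intercept = FALSE)$coefficients
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Log-likelihood of discrete states on a tree under a CTMC
#'
#' Felsenstein pruning with per-edge transition matrices `exp(Q*B)`.
#' Fossilised nodes (leaves or interior) have their partial likelihood
#' restricted to the fossil state.
#'
#' @param tree a [geophylo] object.
#' @param leaf_states integer states in `1..k`, named by leaf id.
#' @param Q a k x k generator (rows sum to 0, off-diagonals >= 0).
#' @param root_distribution numeric vector of length k, or `"stationary"`
#'   to use the stationary distribution of `Q`.
#' @param fossils optional named integer vector: node id -> fixed state.
#' @return the log-likelihood (scalar).
#' @export
ctmc_loglik <- function(tree, leaf_states, Q,
                        root_distribution = "stationary", fossils = NULL) {
  stopifnot(inherits(tree, "geophylo"))
  k <- nrow(Q)
  if (!isTRUE(all.equal(rowSums(Q), rep(0, k), tolerance = 1e-8)) ||
      any(Q[row(Q) != col(Q)] < 0))
    stop("Q is not a valid generator")
  nd <- tree$nodes
  leaves <- which(nd$is_leaf)
  if (!all(nd$id[leaves] %in% names(leaf_states)))
    stop("missing leaf states")
  root_p <- if (identical(root_distribution, "stationary"))
    ctmc_stationary(Q) else root_distribution
  stopifnot(length(root_p) == k)
  prep <- ctmc_prep(tree, k)
  part <- ctmc_partials(prep, leaf_states, fossils)
  ctmc_loglik_core(prep, part, Q, root_p)
}

# generators for the correlated-evolution test on the joint state space
# states: 1=(x=0,y=0), 2=(0,1), 3=(1,0), 4=(1,1)
ctmc_build_independent <- function(r) {
  # r = (qx01, qx10, qy01, qy10)
  Q <- matrix(0, 4, 4)
  Q[1, 3] <- r[1]; Q[2, 4] <- r[1]   # x 0->1
  Q[3, 1] <- r[2]; Q[4, 2] <- r[2]   # x 1->0
  Q[1, 2] <- r[3]; Q[3, 4] <- r[3]   # y 0->1
  Q[2, 1] <- r[4]; Q[4, 3] <- r[4]   # y 1->0
  diag(Q) <- -rowSums(Q)
  Q
}

ctmc_build_dependent <- function(r) {
  # r = (q12, q13, q21, q24, q31, q34, q42, q43)
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- r[1]; Q[1, 3] <- r[2]
  Q[2, 1] <- r[3]; Q[2, 4] <- r[4]
  Q[3, 1] <- r[5]; Q[3, 4] <- r[6]
  Q[4, 2] <- r[7]; Q[4, 3] <- r[8]
  diag(Q) <- -rowSums(Q)
  Q
}

pair_joint_states <- function(pair) {
  x <- pair$x; y <- pair$y
  stopifnot(all(x %in% 0:1), all(y %in% 0:1),
            identical(names(x), names(y)))
  stats::setNames(1L + x * 2L + y, names(x))
}

#' Pagel's test of correlated evolution of two binary traits
#'
#' Fits, on the joint four-state space of two binary leaf traits, the
#' 4-rate independent model (each trait changes at rates that ignore the
#' other) and the 8-rate dependent model (each trait's transition rates may
#' depend on the other's state), by maximum likelihood with multi-start
#' optimisation over log-rates.  `mode = "bayes"` additionally estimates
#' the log marginal likelihood of each model by stepping-stone sampling
#' under independent Uniform(0, `r_max`) rate priors, and reports the Bayes
#' factor for the dependent model.
#'
#' @param tree a [geophylo] object.
#' @param pair a list with elements `x`, `y`: 0/1 vectors named by leaf id
#'   (see [binarize()]), and optionally `fossils`: a list of named vectors
#'   `list(x = c(node_id = state), y = ...)` of fossilised binary states.
#' @param mode `"ml"` or `"bayes"`.
#' @param root_distribution `"stationary"` (of each fitted generator) or a
#'   length-4 probability vector over the joint states.
#' @param n_starts number of optimisation restarts.
#' @param seed seed for restarts and stepping-stone sampling.
#' @param r_max upper bound of the uniform rate prior (bayes mode).
#' @param stones,iter_per_stone stepping-stone settings (bayes mode).
#' @return a list of class `ctmc_test`: `loglik_independent`,
#'   `loglik_dependent`, `rates_independent`, `rates_dependent`, `LR`
#'   (likelihood-ratio statistic), `df = 4`, `p_value` (chi-squared
#'   reference), and in bayes mode `logml_independent`, `logml_dependent`,
#'   `bayes_factor`.
#' @export
pagel_discrete_test <- function(tree, pair, mode = c("ml", "bayes"),
                                root_distribution = "stationary",
                                n_starts = 5, seed = 1L, r_max = 20,
                                stones = 20, iter_per_stone = 400) {
  mode <- match.arg(mode)
  if (length(unique(pair$x)) < 2 || length(unique(pair$y)) < 2)
    stop("a trait is constant across leaves; rates not identifiable")
  js <- pair_joint_states(pair)
  fossils <- NULL
  if (!is.null(pair$fossils)) {
    ids <- union(names(pair$fossils$x), names(pair$fossils$y))
    fx <- pair$fossils$x; fy <- pair$fossils$y
    fossils <- stats::setNames(integer(length(ids)), ids)
    for (id in ids) {
      xs <- if (id %in% names(fx)) fx[[id]] else NA
      ys <- if (id %in% names(fy)) fy[[id]] else NA
      if (is.na(xs) || is.na(ys))
        stop("fossil node ", id, " must fix both traits (joint state space)")
      fossils[[id]] <- 1L + xs * 2L + ys
    }
  }

  prep <- ctmc_prep(tree, 4)
  part <- ctmc_partials(prep, js, fossils)
  root_of <- function(Q) {
    if (identical(root_distribution, "stationary")) ctmc_stationary(Q)
    else root_distribution
  }
  nll <- function(logr, build) {
    Q <- build(exp(logr))
    -ctmc_loglik_core(prep, part, Q, root_of(Q))
  }
  fit_one <- function(build, np) {
    starts <- with_seed(seed, matrix(stats::rnorm(np * n_starts, log(0.5), 1),
                                     n_starts, np))
    best <- NULL
    for (s in seq_len(n_starts)) {
      o <- tryCatch(stats::optim(starts[s, ], nll, build = build,
                                 method = "Nelder-Mead",
                                 control = list(maxit = 600)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("optimisation failed for all starts")
    list(loglik = -best$value, rates = exp(best$par))
  }
  ind <- fit_one(ctmc_build_independent, 4)
  dep <- fit_one(ctmc_build_dependent, 8)
  # nesting: seed the dependent fit from the independent optimum too
  r0 <- ind$rates
  dep_from_ind <- tryCatch(
    stats::optim(log(c(r0[3], r0[1], r0[4], r0[1], r0[2], r0[3],
                       r0[2], r0[4])),
                 nll, build = ctmc_build_dependent,
                 method = "Nelder-Mead", control = list(maxit = 600)),
    error = function(e) NULL)
  if (!is.null(dep_from_ind) && -dep_from_ind$value > dep$loglik)
    dep <- list(loglik = -dep_from_ind$value, rates = exp(dep_from_ind$par))

  LR <- 2 * (dep$loglik - ind$loglik)
  out <- list(loglik_independent = ind$loglik,
              loglik_dependent = dep$loglik,
              rates_independent = stats::setNames(
                ind$rates, c("qx01", "qx10", "qy01", "qy10")),
              rates_dependent = stats::setNames(
                dep$rates, c("q12", "q13", "q21", "q24",
                             "q31", "q34", "q42", "q43")),
              LR = LR, df = 4,
              p_value = stats::pchisq(max(LR, 0), 4, lower.tail = FALSE))
  if (mode == "bayes") {
    ll_of <- function(build) function(r) {
      Q <- build(r)
      ctmc_loglik_core(prep, part, Q, root_of(Q))
    }
    out$logml_independent <- ctmc_stepping_stone(
      ll_of(ctmc_build_independent), 4, r_max, stones, iter_per_stone,
      seed + 11L)
    out$logml_dependent <- ctmc_stepping_stone(
      ll_of(ctmc_build_dependent), 8, r_max, stones, iter_per_stone,
      seed + 12L)
    out$bayes_factor <- exp(out$logml_dependent - out$logml_independent)
  }
  class(out) <- "ctmc_test"
  out
}

#' @export
print.ctmc_test <- function(x, ...) {
  cat("Correlated-evolution CTMC test (4 joint states)\n")
  cat("  logLik independent (4 rates):",
      format(x$loglik_independent, digits = 6), "\n")
  cat("  logLik dependent   (8 rates):",
      format(x$loglik_dependent, digits = 6), "\n")
  cat("  LR =", format(x$LR, digits = 4), " df = 4,  p =",
      format(x$p_value, digits = 3), "\n")
  if (!is.null(x$bayes_factor))
    cat("  stepping-stone Bayes factor (dependent vs independent):",
        format(x$bayes_factor, digits = 4), "\n")
  invisible(x)
}

# stepping-stone estimate of the log marginal likelihood under
# independent Uniform(0, r_max) priors on the rates
ctmc_stepping_stone <- function(ll, np, r_max, stones, iter, seed) {
  betas <- (seq(0, stones) / stones)^(1 / 0.3)  # Beta(0.3, 1) quantile path
  logml <- 0
  with_seed(seed, {
    r <- rep(0.5, np)
    cur_ll <- ll(r)
    for (j in seq_len(stones)) {
      b0 <- betas[j]; b1 <- betas[j + 1]
      samples <- numeric(iter)
      for (i in seq_len(iter)) {
        prop <- r * exp(stats::rnorm(np, 0, 0.4))
        if (all(prop < r_max)) {
          prop_ll <- ll(prop)
          # uniform prior on rates + log-scale proposal Jacobian
          acc <- b0 * (prop_ll - cur_ll) + sum(log(prop) - log(r))
          if (log(stats::runif(1)) < acc) { r <- prop; cur_ll <- prop_ll }
        }
        samples[i] <- cur_ll
      }
      m <- max(samples)
      logml <- logml + (b1 - b0) * m +
        log(mean(exp((b1 - b0) * (samples - m))))
    }
  })
  logml
}

#' Evolutionary correlation of two continuous traits under Brownian motion
#'
#' Estimates the cross-trait correlation of a bivariate Brownian process on
#' the tree: leaf vectors are whitened by the Cholesky factor of the
#' phylogenetic covariance (after removing the GLS root state, or a
#' fossilised root value), and `r` is the correlation of the whitened
#' residuals — the maximum-likelihood evolutionary correlation.
#' `mode = "bayes"` samples `(root states, rates, r)` by MCMC with a
#' uniform prior on `r`, returning a credible interval and optionally a
#' stepping-stone Bayes factor against the `r = 0` model.
#'
#' @param tree a [geophylo] object.
#' @param x,y trait column names.
#' @param root_fossil optional named list, e.g. `list(x = 2)`: fixes the
#'   root state of a trait instead of estimating it.
#' @param mode `"ml"` or `"bayes"`.
#' @param chains,iter,warmup,seed MCMC settings (bayes mode).
#' @param bayes_factor if `TRUE` (bayes mode), stepping-stone BF vs `r = 0`.
#' @param stones,iter_per_stone stepping-stone settings.
#' @return a list of class `brownian_cor`: `r`, `interval` (95%),
#'   `loglik`, and in bayes mode `draws`, `bayes_factor`.
#' @export
brownian_correlation <- function(tree, x = "trait", y = "humidity",
                                 root_fossil = NULL, mode = c("ml", "bayes"),
                                 chains = 2, iter = 1000, warmup = 500,
                                 seed = 1L, bayes_factor = FALSE,
                                 stones = 20, iter_per_stone = 400) {
  mode <- match.arg(mode)
  xv <- gp_trait(tree, x, leaves_only = TRUE)
  yv <- gp_trait(tree, y, leaves_only = TRUE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) stop("constant trait")
  C <- ape::vcv(tree$phy)
  xv <- xv[rownames(C)]; yv <- yv[rownames(C)]
  n <- length(xv)
  Lc <- t(chol(C))
  whiten <- function(v, mu) forwardsolve(Lc, v - mu)
  gls_mean <- function(v) {
    Ci_v <- forwardsolve(Lc, v); Ci_1 <- forwardsolve(Lc, rep(1, n))
    sum(Ci_1 * Ci_v) / sum(Ci_1^2)
  }
  mux <- if (!is.null(root_fossil$x)) root_fossil$x else gls_mean(xv)
  muy <- if (!is.null(root_fossil$y)) root_fossil$y else gls_mean(yv)
  u <- whiten(xv, mux); v <- whiten(yv, muy)
  r_ml <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))

  biv_ll <- function(r, sx, sy) {
    # whitened pairs are iid bivariate normal with covariance S
    S <- matrix(c(sx^2, r * sx * sy, r * sx * sy, sy^2), 2)
    det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (det_s <= 0) return(-Inf)
    Si <- solve(S)
    q <- Si[1, 1] * sum(u^2) + 2 * Si[1, 2] * sum(u * v) + Si[2, 2] * sum(v^2)
    # |kron(S, C)| = |S|^n |C|^2
    -n * log(2 * pi) - n / 2 * log(det_s) - q / 2 - 2 * sum(log(diag(Lc)))
  }
  sx_ml <- sqrt(mean(u^2)); sy_ml <- sqrt(mean(v^2))
  out <- list(r = r_ml,
              interval = tanh(atanh(r_ml) + c(-1, 1) * 1.96 / sqrt(n - 3)),
              loglik = biv_ll(r_ml, sx_ml, sy_ml))
  if (mode == "bayes") {
    lp <- function(par) {
      # par = (atanh r, log sx, log sy)
      r <- tanh(par[1]); sx <- exp(par[2]); sy <- exp(par[3])
      if (abs(r) >= 1) return(-Inf)
      biv_ll(r, sx, sy) + log(1 - r^2) + par[2] + par[3] +
        stats::dnorm(par[2], 0, 2, log = TRUE) +
        stats::dnorm(par[3], 0, 2, log = TRUE)
    }
    fit <- mh_sample(lp, init = c(atanh(r_ml), log(sx_ml), log(sy_ml)),
                     chains = chains, iter = iter, warmup = warmup,
                     seed = seed)
    r_draws <- tanh(fit$draws[, 1])
    out$draws <- r_draws
    out$r <- mean(r_draws)
    out$interval <- stats::quantile(r_draws, c(0.025, 0.975), names = FALSE)
    out$diagnostics <- fit$diagnostics
    if (bayes_factor) {
      ll_full <- function(par) lp(par)
      ll_null <- function(par) {
        sx <- exp(par[1]); sy <- exp(par[2])
        biv_ll(0, sx, sy) + par[1] + par[2] +
          stats::dnorm(par[1], 0, 2, log = TRUE) +
          stats::dnorm(par[2], 0, 2, log = TRUE)
      }
      # stepping stone needs likelihood/prior separation; use posterior
      # power path on the likelihood part only
      ml_full <- ss_generic(function(p) biv_ll(tanh(p[1]), exp(p[2]), exp(p[3])),
                            function(p) log(1 - tanh(p[1])^2) + p[2] + p[3] +
                              stats::dnorm(p[2], 0, 2, log = TRUE) +
                              stats::dnorm(p[3], 0, 2, log = TRUE) - log(2),
                            init = c(atanh(r_ml), log(sx_ml), log(sy_ml)),
                            stones = stones, iter = iter_per_stone,
                            seed = seed + 5L)
      ml_null <- ss_generic(function(p) biv_ll(0, exp(p[1]), exp(p[2])),
                            function(p) p[1] + p[2] +
                              stats::dnorm(p[1], 0, 2, log = TRUE) +
                              stats::dnorm(p[2], 0, 2, log = TRUE),
                            init = c(log(sx_ml), log(sy_ml)),
                            stones = stones, iter = iter_per_stone,
                            seed = seed + 6L)
      out$bayes_factor <- exp(ml_full - ml_null)
    }
  }
  class(out) <- "brownian_cor"
  out
}

#' @export
print.brownian_cor <- function(x, ...) {
  cat("Brownian evolutionary correlation\n")
  cat("  r =", format(x$r, digits = 4), " 95% interval [",
      format(x$interval[1], digits = 4), ",",
      format(x$interval[2], digits = 4), "]\n")
  if (!is.null(x$bayes_factor))
    cat("  Bayes factor vs r = 0:", format(x$bayes_factor, digits = 4), "\n")
  invisible(x)
}

# generic stepping-stone: log marginal likelihood of exp(loglik) under
# exp(logprior), sampling by random-walk MH along the power path
ss_generic <- function(loglik, logprior, init, stones = 20, iter = 400,
                       seed = 1L, step = 0.3) {
  betas <- (seq(0, stones) / stones)^(1 / 0.3)
  logml <- 0
  with_seed(seed, {
    p <- init
    cur_ll <- loglik(p); cur_lp <- logprior(p)
    for (j in seq_len(stones)) {
      b0 <- betas[j]; b1 <- betas[j + 1]
      samples <- numeric(iter)
      for (i in seq_len(iter)) {
        prop <- p + stats::rnorm(length(p), 0, step)
        prop_ll <- loglik(prop); prop_lp <- logprior(prop)
        if (is.finite(prop_ll) && is.finite(prop_lp)) {
          acc <- b0 * (prop_ll - cur_ll) + (prop_lp - cur_lp)
          if (log(stats::runif(1)) < acc) {
            p <- prop; cur_ll <- prop_ll; cur_lp <- prop_lp
          }
        }
        samples[i] <- cur_ll
      }
      m <- max(samples)
      logml <- logml + (b1 - b0) * m +
        log(mean(exp((b1 - b0) * (samples - m))))
    }
  })
  logml
}
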