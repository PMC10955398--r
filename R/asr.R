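#' Brownian-motion ancestral state reconstruction with root fossilisation
#'
#' Computes, for every interior node, the conditional mean (`T_REC`) and
#' standard deviation (`T_SE`) of a continuous trait under Brownian motion,
#' given the observed leaf values and, optionally, a fossilised root value.
#' The computation is exact Gaussian conditioning, implemented as a linear
#' belief-propagation (upward/downward message passing) sweep over the tree
#' rather than by assembling the dense phylogenetic covariance; the dense
#' construction serves as an independent oracle in the test suite.  The
#' Brownian rate is profiled out by maximum likelihood from the leaves (and
#' fossil, if given).  Optional bounds are applied by truncating each node's
#' conditional normal distribution.
#'
#' @param tree a [geophylo] object.
#' @param trait name of the trait column; all leaves must carry values.
#' @param root_fossil optional known root value (e.g. a linguistic
#'   reconstruction such as two tones for a proto-language); the root is
#'   then reported with `T_SE = 0`.
#' @param bounds optional length-2 numeric `c(lower, upper)`; conditional
#'   distributions are truncated to this interval (e.g. `c(0, 12)` tones).
#' @param rate optional fixed Brownian rate (variance per ky); estimated by
#'   maximum likelihood when `NULL`.
#' @return a data frame of class `node_reconstruction` with columns `id`,
#'   `T_REC`, `T_SE`, `is_leaf`, `fossil`; attributes `method`, `rate`,
#'   `bounds`.
#' @export
asr_brownian <- function(tree, trait = "trait", root_fossil = NULL,
                         bounds = NULL, rate = NULL) {
  stopifnot(inherits(tree, "geophylo"))
  nd <- tree$nodes
  y_all <- gp_trait(tree, trait)
  leaves <- which(nd$is_leaf)
  y <- y_all[leaves]
  if (anyNA(y))
    stop("missing leaf values for: ",
         paste(nd$id[leaves][is.na(y)], collapse = ", "))
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
    if (!is.null(root_fossil) &&
        (root_fossil < bounds[1] || root_fossil > bounds[2]))
      stop("root fossil outside bounds")
  }
  root <- nd$node[is.na(nd$parent)]
  n_node <- nrow(nd)
  ed <- gp_edges(tree)

  if (is.null(rate)) rate <- asr_ml_rate(tree, y, root_fossil)

  # --- upward pass: message from each node's subtree, in rate units ---
  # (mean m, pseudo-variance v in units of the rate; v = 0 for leaves)
  m_up <- rep(NA_real_, n_node); v_up <- rep(NA_real_, n_node)
  m_up[leaves] <- y; v_up[leaves] <- 0
  children <- split(seq_len(nrow(ed)), ed$anc)
  post_edges <- order(ed$age_anc, ed$desc)  # tipward ancestors last
  inner_order <- unique(ed$anc[post_edges])  # youngest ancestors first
  for (v in inner_order) {
    ks <- children[[as.character(v)]]
    prec <- 1 / (v_up[ed$desc[ks]] + pmax(ed$length[ks], 0))
    v_up[v] <- 1 / sum(prec)
    m_up[v] <- sum(prec * m_up[ed$desc[ks]]) * v_up[v]
  }

  # --- downward pass: message from outside each node's subtree ---
  # stored as precision (pr) and precision-weighted mean (pm); flat = 0,0
  pr_dn <- rep(0, n_node); pm_dn <- rep(0, n_node)
  if (!is.null(root_fossil)) { pr_dn[root] <- Inf; pm_dn[root] <- root_fossil }
  pre <- rev(seq_along(post_edges))  # rootward ancestors first
  for (k in post_edges[order(-ed$age_anc[post_edges], ed$desc[post_edges])]) {
    v <- ed$anc[k]; c <- ed$desc[k]
    sibs <- setdiff(children[[as.character(v)]], k)
    if (is.infinite(pr_dn[v])) {
      at_v_m <- pm_dn[v]; at_v_v <- 0
    } else {
      prec <- pr_dn[v]; pm <- pm_dn[v] * ifelse(pr_dn[v] > 0, 1, 0)
      pmean <- if (pr_dn[v] > 0) pm_dn[v] else 0
      prec_sum <- prec
      num <- prec * pmean
      if (length(sibs)) {
        sp <- 1 / (v_up[ed$desc[sibs]] + pmax(ed$length[sibs], 0))
        prec_sum <- prec_sum + sum(sp)
        num <- num + sum(sp * m_up[ed$desc[sibs]])
      }
      if (prec_sum == 0) { at_v_m <- NA_real_; at_v_v <- Inf }
      else { at_v_m <- num / prec_sum; at_v_v <- 1 / prec_sum }
    }
    b <- max(ed$length[k], 0)
    if (is.infinite(at_v_v)) { pr_dn[c] <- 0; pm_dn[c] <- 0 }
    else if (at_v_v + b == 0) { pr_dn[c] <- Inf; pm_dn[c] <- at_v_m }
    else { pr_dn[c] <- 1 / (at_v_v + b); pm_dn[c] <- at_v_m }
  }

  # --- combine into marginals ---
  T_REC <- rep(NA_real_, n_node); T_SE <- rep(NA_real_, n_node)
  fossil <- rep(FALSE, n_node)
  for (v in seq_len(n_node)) {
    if (nd$is_leaf[v]) { T_REC[v] <- y_all[v]; T_SE[v] <- 0; next }
    if (v == root && !is.null(root_fossil)) {
      T_REC[v] <- root_fossil; T_SE[v] <- 0; fossil[v] <- TRUE; next
    }
    ks <- children[[as.character(v)]]
    prec <- 1 / (v_up[ed$desc[ks]] + pmax(ed$length[ks], 0))
    num <- sum(prec * m_up[ed$desc[ks]])
    den <- sum(prec)
    if (is.infinite(pr_dn[v])) { T_REC[v] <- pm_dn[v]; T_SE[v] <- 0; next }
    if (pr_dn[v] > 0) { num <- num + pr_dn[v] * pm_dn[v]; den <- den + pr_dn[v] }
    T_REC[v] <- num / den
    T_SE[v] <- sqrt(rate / den)
  }

  if (!is.null(bounds)) {
    idx <- which(T_SE > 0)
    if (length(idx)) {
      tm <- truncnorm_moments(T_REC[idx], T_SE[idx], bounds[1], bounds[2])
      T_REC[idx] <- tm$mean; T_SE[idx] <- tm$sd
    }
  }

  out <- data.frame(id = nd$id, T_REC = T_REC, T_SE = T_SE,
                    is_leaf = nd$is_leaf, fossil = fossil,
                    stringsAsFactors = FALSE)
  structure(out, method = "exact_gaussian", rate = rate, bounds = bounds,
            class = c("node_reconstruction", "data.frame"))
}

# ML Brownian rate from leaf data (dense GLS; leaves only, so small)
asr_ml_rate <- function(tree, y, root_fossil = NULL) {
  C <- ape::vcv(tree$phy)
  y <- y[rownames(C)]
  n <- length(y)
  Ci <- solve(C)
  if (is.null(root_fossil)) {
    one <- rep(1, n)
    mu <- as.numeric((one %*% Ci %*% y) / (one %*% Ci %*% one))
  } else mu <- root_fossil
  r <- y - mu
  as.numeric(r %*% Ci %*% r) / n
}

# mean and sd of Normal(mu, sd) truncated to [lo, hi] (vectorised)
truncnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  Z <- pmax(Z, .Machine$double.xmin)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sd * (da - db) / Z
  v <- sd^2 * (1 + (ifelse(is.finite(a), a * da, 0) -
                      ifelse(is.finite(b), b * db, 0)) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

#' Pagel's lambda by maximum likelihood
#'
#' Phylogenetic signal of a continuous leaf trait: the off-diagonal entries
#' of the Brownian phylogenetic covariance are multiplied by `lambda` in
#' `[0, 1]` and `lambda` is optimised jointly with the root state and rate
#' (both profiled out in closed form).  `lambda = 1` is plain Brownian
#' motion, `lambda = 0` is an iid-normal (star) model.
#'
#' @param tree a [geophylo] object with at least 4 leaves carrying values.
#' @param trait trait column name.
#' @param profile_points number of lambda grid points in the returned
#'   log-likelihood profile.
#' @return a list with `lambda_hat`, `loglik`, `profile` (data frame of
#'   `lambda`, `loglik`), `root`, `rate`.
#' @export
pagels_lambda <- function(tree, trait = "trait", profile_points = 21) {
  stopifnot(inherits(tree, "geophylo"))
  nd <- tree$nodes
  y <- gp_trait(tree, trait, leaves_only = TRUE)
  if (length(y) < 4) stop("need at least 4 leaves with values")
  if (anyNA(y)) stop("missing leaf values")
  if (stats::sd(y) == 0) stop("trait is constant across leaves; lambda undefined")
  C <- ape::vcv(tree$phy)
  y <- y[rownames(C)]
  n <- length(y)
  Cd <- diag(diag(C))

  ll <- function(lambda) {
    Cl <- lambda * C + (1 - lambda) * Cd
    ch <- chol(Cl)
    logdet <- 2 * sum(log(diag(ch)))
    Ci_y <- backsolve(ch, forwardsolve(t(ch), y))
    Ci_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    mu <- sum(Ci_y) / sum(Ci_1)
    r <- y - mu
    q <- sum(r * backsolve(ch, forwardsolve(t(ch), r)))
    s2 <- q / n
    -0.5 * (n * log(2 * pi * s2) + logdet + n)
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
  # guard against boundary optima
  cand <- c(opt$maximum, 0, 1)
  vals <- vapply(cand, ll, numeric(1))
  best <- which.max(vals)
  lambda_hat <- cand[best]

  grid <- seq(0, 1, length.out = profile_points)
  prof <- data.frame(lambda = grid,
                     loglik = vapply(grid, ll, numeric(1)))
  Cl <- lambda_hat * C + (1 - lambda_hat) * Cd
  Ci <- solve(Cl)
  one <- rep(1, n)
  mu <- as.numeric((one %*% Ci %*% y) / (one %*% Ci %*% one))
  s2 <- as.numeric((y - mu) %*% Ci %*% (y - mu)) / n
  list(lambda_hat = lambda_hat, loglik = vals[best], profile = prof,
       root = mu, rate = s2)
}
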