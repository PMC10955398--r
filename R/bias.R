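#' Type-I error inflation of naive leaf regressions under a null model
#'
#' Simulates trait histories on the tree under the null model (no
#' environmental effect; increments scale linearly with branch length),
#' then, for each replicate, fits an ordinary least squares regression of
#' the leaf trait on leaf humidity and records the slope and its two-sided
#' t-test p-value.  On a tree with deep shared history and spatially
#' clustered humidity the fraction of "significant" slopes greatly exceeds
#' the nominal level — the genealogical bias that motivates diachronic
#' modelling.
#'
#' @param tree a [geophylo] with a `humidity` column (at least at leaves).
#' @param n_datasets number of null replicates.
#' @param alpha significance level for the slope test.
#' @param seed integer seed.
#' @param config optional [sim_config()] controlling the null trait
#'   generator (root value, error scale, variance scaling); tree-shape
#'   fields are ignored.
#' @return a list of class `bias_study`: `slopes`, `p_values`,
#'   `significant` (logical), `rate` (fraction significant), `alpha`,
#'   `n_datasets`, `seed`.
#' @export
type1_error_study <- function(tree, n_datasets = 100, alpha = 0.05,
                              seed = 1L, config = NULL) {
  stopifnot(inherits(tree, "geophylo"), n_datasets >= 1,
            alpha > 0, alpha < 1)
  nd <- tree$nodes
  if (!"humidity" %in% names(nd)) stop("tree has no humidity column")
  h <- nd$humidity[nd$is_leaf]
  if (sum(nd$is_leaf) < 3) stop("need at least 3 leaves")
  if (is.null(config)) config <- sim_config(n_tips = sum(nd$is_leaf))
  slopes <- numeric(n_datasets); pvals <- numeric(n_datasets)
  for (r in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    sim <- simulate_traits_null(tree, cfg, name = ".null_trait")
    tv <- sim$nodes$.null_trait[sim$nodes$is_leaf]
    fit <- summary(stats::lm(tv ~ h))$coefficients
    slopes[r] <- fit["h", "Estimate"]
    pvals[r] <- fit["h", "Pr(>|t|)"]
  }
  structure(list(slopes = slopes, p_values = pvals,
                 significant = pvals < alpha,
                 rate = mean(pvals < alpha),
                 alpha = alpha, n_datasets = n_datasets, seed = seed),
            class = "bias_study")
}

#' @export
print.bias_study <- function(x, ...) {
  cat("Null-model leaf regression study:", x$n_datasets, "replicates\n")
  cat("  significant at alpha =", x$alpha, ":",
      sum(x$significant), "(", format(100 * x$rate, digits = 3), "% )\n")
  ci <- stats::binom.test(sum(x$significant), x$n_datasets)$conf.int
  cat("  95% binomial CI for the rate: [",
      format(ci[1], digits = 3), ",", format(ci[2], digits = 3), "]\n")
  invisible(x)
}

#' Node importance for the leaf-level regression slope
#'
#' For each node, a perturbed copy of the leaf data is created in which
#' `delta` is added to the trait of every leaf descending from that node
#' (for a leaf, just itself); the leaf OLS of trait on humidity is refit
#' and the importance is the absolute change in the fitted slope.  Nodes
#' whose perturbation can swing the cross-sectional slope are the ones
#' whose (possibly accidental) early history drives the synchronic
#' correlation.  Perturbing the root shifts every leaf equally and leaves
#' the slope unchanged.
#'
#' @param tree a [geophylo] object.
#' @param trait,humidity names of the leaf trait and humidity columns.
#' @param delta perturbation added to descendant leaf traits (default 1).
#' @return a data frame of class `node_importance` with columns `id`,
#'   `n_desc_leaves`, `importance`, `rank` (1 = most important), sorted by
#'   rank; attribute `slope0` is the unperturbed slope.
#' @export
node_importance <- function(tree, trait = "trait", humidity = "humidity",
                            delta = 1) {
  stopifnot(inherits(tree, "geophylo"))
  nd <- tree$nodes
  leaves <- which(nd$is_leaf)
  tv <- nd[[trait]][leaves]
  h <- nd[[humidity]][leaves]
  if (anyNA(tv) || anyNA(h)) stop("missing leaf trait/humidity values")
  slope_of <- function(y) {
    stats::cov(h, y) / stats::var(h)
  }
  slope0 <- slope_of(tv)

  # leaf sets per node, via one rootward sweep
  desc_leaves <- vector("list", nrow(nd))
  for (l in leaves) desc_leaves[[l]] <- l
  ed <- gp_edges(tree)
  for (k in order(ed$age_anc, ed$desc))
    desc_leaves[[ed$anc[k]]] <- c(desc_leaves[[ed$anc[k]]],
                                  desc_leaves[[ed$desc[k]]])

  imp <- vapply(seq_len(nrow(nd)), function(v) {
    y <- tv
    sel <- match(desc_leaves[[v]], leaves)
    y[sel] <- y[sel] + delta
    abs(slope_of(y) - slope0)
  }, numeric(1))

  out <- data.frame(id = nd$id,
                    n_desc_leaves = lengths(desc_leaves),
                    importance = imp, stringsAsFactors = FALSE)
  out$rank <- rank(-out$importance, ties.method = "min")
  out <- out[order(out$rank, out$id), ]
  rownames(out) <- NULL
  structure(out, slope0 = slope0, delta = delta,
            class = c("node_importance", "data.frame"))
}

#' Summarise a node-importance table
#'
#' Reports the distribution of importances, the top-ranked nodes, and the
#' fraction of nodes above a threshold.  What counts as "highly important"
#' is a report parameter, not a fixed definition.
#'
#' @param table a [node_importance()] result.
#' @param top_k how many top nodes to list.
#' @param threshold nodes with importance strictly above this count as
#'   "high"; default is the 90th percentile of the importances.
#' @return a list with `quantiles`, `top` (data frame), `threshold`,
#'   `n_above`, `frac_above`.
#' @export
summarize_importance <- function(table, top_k = 8, threshold = NULL) {
  stopifnot(inherits(table, "node_importance"))
  if (is.null(threshold))
    threshold <- stats::quantile(table$importance, 0.9, names = FALSE)
  above <- table$importance > threshold
  list(quantiles = stats::quantile(table$importance,
                                   c(0, 0.25, 0.5, 0.75, 0.9, 1)),
       top = utils::head(table, top_k),
       threshold = threshold,
       n_above = sum(above),
       frac_above = mean(above))
}
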