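# shared fixture builders (everything generated in code; no data files)

# two-leaf cherry with root age 1
cherry_tree <- function() {
  load_geophylo("(A:1,B:1)R;",
                data.frame(id = c("A", "B", "R"),
                           parent = c("R", "R", NA),
                           age = c(0, 0, 1),
                           lat = c(0, 1, 0.5), lon = c(0, 0, 0)))
}

# 4-taxon tree used in hand-computed examples: ((A:1,B:1)C:1,D:2)R;
hand_tree <- function(with_data = TRUE) {
  nodes <- data.frame(id = c("A", "B", "D", "R", "C"),
                      parent = c("C", "C", "R", NA, "R"),
                      age = c(0, 0, 0, 2, 1),
                      lat = c(0, 1, 3, 0, 0),
                      lon = c(11, 11, 10, 10, 11))
  if (with_data) {
    nodes$trait <- c(4, 2, 1, 2, 3)
    nodes$humidity <- c(0.014, 0.016, 0.008, 0.010, 0.012)
  }
  load_geophylo("((A:1,B:1)C:1,D:2)R;", nodes)
}

# star tree with n leaves at age 0, unit branches, iid humidity
star_tree <- function(n = 100, seed = 1) {
  phy <- ape::stree(n, "star")
  phy$edge.length <- rep(1, n)
  phy$node.label <- "r"
  nodes <- data.frame(id = c(phy$tip.label, "r"),
                      parent = c(rep("r", n), NA),
                      age = c(rep(0, n), 1),
                      lat = 0, lon = 0)
  g <- geophylo(phy, nodes)
  set.seed(seed)
  h <- stats::setNames(rnorm(n + 1, 0.015, 0.002), g$nodes$id)
  geophylocausal:::gp_set_trait(g, "humidity", h)
}

# random geo-phylo with all fields, small
small_geophylo <- function(n_tips = 10, seed = 1, model = "null") {
  simulate_geophylo(sim_config(n_tips = n_tips, seed = seed,
                               trait = list(model = model)))
}

# simulate discrete states down the tree under generator Q (k states)
simulate_ctmc_states <- function(tree, Q, root_state = 1, seed = 1) {
  set.seed(seed)
  nd <- tree$nodes
  ed <- geophylocausal:::gp_edges(tree)
  ord <- geophylocausal:::edges_preorder(tree)
  s <- integer(nrow(nd))
  s[nd$node[is.na(nd$parent)]] <- root_state
  for (k in ord) {
    P <- ape::matexpo(Q * max(ed$length[k], 0))
    s[ed$desc[k]] <- sample(seq_len(nrow(Q)), 1, prob = P[s[ed$anc[k]], ])
  }
  stats::setNames(s, nd$id)
}

# dense-covariance Brownian ASR oracle: condition jointly on leaves
# (and optionally a fossilised root) using the full node-node covariance
asr_dense_oracle <- function(tree, trait = "trait", root_fossil = NULL,
                             rate) {
  nd <- tree$nodes
  D <- ape::dist.nodes(tree$phy)
  root <- nd$node[is.na(nd$parent)]
  depth <- D[root, ]
  Cshared <- (outer(depth, depth, "+") - D) / 2
  leaves <- which(nd$is_leaf)
  y <- nd[[trait]][leaves]
  S <- rate * Cshared
  if (!is.null(root_fossil)) {
    free <- setdiff(seq_len(nrow(nd)), c(leaves, root))
    mu0 <- rep(root_fossil, nrow(nd))
    Sll <- S[leaves, leaves]
    Sfl <- S[free, leaves, drop = FALSE]
    m <- mu0[free] + Sfl %*% solve(Sll, y - mu0[leaves])
    V <- S[free, free] - Sfl %*% solve(Sll, t(Sfl))
  } else {
    # flat root prior: GLS root mean, then condition the centred process
    Sll <- S[leaves, leaves]
    one <- rep(1, length(leaves))
    iS <- solve(Sll)
    mu_hat <- as.numeric((one %*% iS %*% y) / (one %*% iS %*% one))
    free <- setdiff(seq_len(nrow(nd)), leaves)
    # conditional of [free | leaves] under mean mu_hat plus root-mean
    # uncertainty propagated through the joint covariance
    Sfl <- S[free, leaves, drop = FALSE]
    A <- Sfl %*% iS
    m <- mu_hat + A %*% (y - mu_hat)
    V <- S[free, free] - A %*% t(Sfl) +
      (1 - A %*% one) %*% t(1 - A %*% one) / as.numeric(one %*% iS %*% one)
  }
  list(ids = nd$id[free], mean = as.numeric(m),
       sd = unname(sqrt(pmax(diag(V), 0))))
}

# closed-form OLS slope of y on x
ols_slope <- function(x, y) stats::cov(x, y) / stats::var(x)
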