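#' Configuration for synthetic geo-phylogenetic data
#'
#' Bundles every knob of the synthetic-data generators.  Defaults emulate a
#' Bantu-scale study system: a 200-tip time-calibrated tree with crown age
#' 5 ky, Brownian dispersal at sub-continental scale, and a smooth specific
#' humidity field (around 0.015 kg/kg with a north--south gradient) sampled
#' at node locations, so that humidity inherits very high phylogenetic
#' signal from the dispersal process.
#'
#' @param n_tips number of extant leaves (>= 3).
#' @param crown_age root age in ky before present.
#' @param birth_rate Yule speciation rate (1/ky); topology is conditioned on
#'   `n_tips` and rescaled to `crown_age`, so this mostly shapes node ages.
#' @param dispersal_sd Brownian dispersal standard deviation, degrees per
#'   sqrt(ky), applied independently to latitude and longitude.
#' @param root_lat,root_lon root location (decimal degrees).
#' @param founder_jump `NULL`, or a list as returned by [founder_jump()]:
#'   one early edge receives a fixed latitudinal displacement, producing the
#'   two-cluster "founder" pattern in leaf locations and hence in humidity.
#' @param humidity list: `base` (kg/kg), `grad_lat`, `grad_lon` (kg/kg per
#'   degree), `drift` (kg/kg per ky of age), `noise_sd` (kg/kg).
#' @param trait list: `model` ("null" or "causal"), `root` (root trait
#'   value; 2 by default, a two-tone proto-language), `sd` (null-model error
#'   scale per unit branch length), `variance_scaling` ("linear_B": the
#'   increment sd is `sd * B`; "sqrt_B": standard Brownian `sd * sqrt(B)`),
#'   `params` (causal-model generative parameters `alpha`, `eta`, `gamma`,
#'   `rho`, `sigma0`, `beta`), `geo_radius_km` and `phylo_radius` (ky)
#'   defining the neighbourhoods the causal generator conditions on.
#' @param seed integer seed; every generator is a pure function of its
#'   inputs and this seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 200,
                       crown_age = 5,
                       birth_rate = 1,
                       dispersal_sd = 0.5,
                       root_lat = -2,
                       root_lon = 12,
                       founder_jump = NULL,
                       humidity = list(base = 0.015, grad_lat = 2e-4,
                                       grad_lon = 0, drift = 0,
                                       noise_sd = 2e-4),
                       trait = list(model = "null", root = 2, sd = 1,
                                    variance_scaling = "linear_B",
                                    params = list(alpha = 0, eta = 0.5,
                                                  gamma = 0, rho = 0,
                                                  sigma0 = 0.5, beta = 0.05),
                                    geo_radius_km = 500,
                                    phylo_radius = 0.5),
                       seed = 1L) {
  stopifnot(n_tips >= 3, crown_age > 0, birth_rate > 0, dispersal_sd >= 0)
  hum_def <- list(base = 0.015, grad_lat = 2e-4, grad_lon = 0, drift = 0,
                  noise_sd = 2e-4)
  humidity <- utils::modifyList(hum_def, humidity)
  trait_def <- list(model = "null", root = 2, sd = 1,
                    variance_scaling = "linear_B",
                    params = list(alpha = 0, eta = 0.5, gamma = 0, rho = 0,
                                  sigma0 = 0.5, beta = 0.05),
                    geo_radius_km = 500, phylo_radius = 0.5)
  trait <- utils::modifyList(trait_def, trait)
  stopifnot(trait$variance_scaling %in% c("linear_B", "sqrt_B"),
            trait$model %in% c("null", "causal"))
  structure(list(n_tips = as.integer(n_tips), crown_age = crown_age,
                 birth_rate = birth_rate, dispersal_sd = dispersal_sd,
                 root_lat = root_lat, root_lon = root_lon,
                 founder_jump = founder_jump, humidity = humidity,
                 trait = trait, seed = as.integer(seed)),
            class = "sim_config")
}

#' Founder-jump settings
#'
#' @param depth_quantile edges whose ancestor age is at or above this
#'   quantile of interior-node ages are candidates for the jump.
#' @param jump_deg latitudinal displacement (degrees) added on the jump edge.
#' @return a list for the `founder_jump` slot of [sim_config()].
#' @export
founder_jump <- function(depth_quantile = 0.8, jump_deg = 15) {
  list(depth_quantile = depth_quantile, jump_deg = jump_deg)
}

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a time-calibrated Yule tree
#'
#' Pure-birth topology conditioned on the number of tips, rescaled so the
#' crown (root) age equals `config$crown_age`; tips sit at age 0.
#'
#' @param config a [sim_config()].
#' @return a [geophylo] object without locations (`lat`/`lon` are `NA`).
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  phy <- with_seed(config$seed, ape::rphylo(config$n_tips, config$birth_rate, 0))
  depth <- ape::node.depth.edgelength(phy)  # distance from root
  scale <- config$crown_age / max(depth)
  phy$edge.length <- phy$edge.length * scale
  depth <- depth * scale
  phy$tip.label <- sprintf("t%d", seq_len(config$n_tips))
  phy$node.label <- sprintf("n%d", seq_len(phy$Nnode))
  age <- config$crown_age - depth
  age[abs(age) < 1e-12] <- 0
  labels <- c(phy$tip.label, phy$node.label)
  nodes <- data.frame(id = labels, parent = NA_character_,
                      age = age, lat = NA_real_, lon = NA_real_,
                      stringsAsFactors = FALSE)
  geophylo(phy, nodes)
}

# indices of edges in root-to-tip order (decreasing ancestor age)
edges_preorder <- function(tree) {
  ed <- gp_edges(tree)
  order(-ed$age_anc, ed$desc)
}

# number of leaves descending from each node
subtree_leaf_counts <- function(tree) {
  n_all <- nrow(tree$nodes)
  counts <- as.integer(tree$nodes$is_leaf)
  ed <- gp_edges(tree)
  ord <- order(ed$age_anc, ed$desc)  # tipward edges first
  for (k in ord) counts[ed$anc[k]] <- counts[ed$anc[k]] + counts[ed$desc[k]]
  counts
}

#' Simulate Brownian dispersal of node locations
#'
#' Locations evolve by a Brownian walk on raw latitude/longitude down each
#' edge (per-axis sd `dispersal_sd * sqrt(B)`).  If a founder jump is
#' configured, the candidate edge (ancestor age at or above the configured
#' quantile of interior ages) whose subtree is closest to half the leaves
#' additionally receives a fixed latitudinal displacement, seeding the
#' two-cluster phenomenon that makes naive cross-sectional regressions
#' anti-conservative.  Latitudes are clamped at the poles.
#'
#' @param tree a [geophylo] object (locations are overwritten).
#' @param config a [sim_config()].
#' @return the tree with `lat`/`lon` filled for every node.
#' @export
simulate_dispersal <- function(tree, config) {
  stopifnot(inherits(tree, "geophylo"), inherits(config, "sim_config"))
  nd <- tree$nodes
  ed <- gp_edges(tree)
  ord <- edges_preorder(tree)
  root <- nd$node[is.na(nd$parent)]

  jump_edge <- NA_integer_
  if (!is.null(config$founder_jump)) {
    inner_ages <- nd$age[!nd$is_leaf & nd$node != root]
    thr <- stats::quantile(inner_ages, config$founder_jump$depth_quantile,
                           names = FALSE)
    counts <- subtree_leaf_counts(tree)
    cand <- which(ed$age_anc >= thr & !nd$is_leaf[ed$desc])
    if (length(cand)) {
      target <- config$n_tips / 2
      jump_edge <- cand[which.min(abs(counts[ed$desc[cand]] - target))]
    }
  }

  lat <- rep(NA_real_, nrow(nd)); lon <- rep(NA_real_, nrow(nd))
  lat[root] <- config$root_lat; lon[root] <- config$root_lon
  with_seed(config$seed + 1L, {
    for (k in ord) {
      s <- config$dispersal_sd * sqrt(max(ed$length[k], 0))
      lat[ed$desc[k]] <- lat[ed$anc[k]] + stats::rnorm(1, 0, s)
      lon[ed$desc[k]] <- lon[ed$anc[k]] + stats::rnorm(1, 0, s)
      if (!is.na(jump_edge) && k == jump_edge)
        lat[ed$desc[k]] <- lat[ed$desc[k]] + config$founder_jump$jump_deg
    }
  })
  nd$lat <- pmin(90, pmax(-90, lat))
  nd$lon <- pmin(180, pmax(-180, lon))
  tree$nodes <- nd
  tree
}

#' Simulate node-level humidity from a smooth space-time field
#'
#' Humidity at each node is a deterministic smooth function of its location
#' and age plus iid observation noise:
#' `h = base + grad_lat*(lat - root_lat) + grad_lon*(lon - root_lon) +
#' drift*age + Normal(0, noise_sd)`.  Because locations themselves evolve on
#' the tree, the resulting humidity values carry very high phylogenetic
#' signal even though humidity is not "inherited".
#'
#' @param tree a [geophylo] with locations.
#' @param config a [sim_config()].
#' @return the tree with a `humidity` trait column.
#' @export
simulate_humidity <- function(tree, config) {
  stopifnot(inherits(tree, "geophylo"), inherits(config, "sim_config"))
  nd <- tree$nodes
  if (any(is.na(nd$lat))) stop("locations must be simulated first")
  hp <- config$humidity
  h <- hp$base + hp$grad_lat * (nd$lat - config$root_lat) +
    hp$grad_lon * (nd$lon - config$root_lon) + hp$drift * nd$age
  h <- h + with_seed(config$seed + 2L, stats::rnorm(nrow(nd), 0, hp$noise_sd))
  gp_set_trait(tree, "humidity", stats::setNames(h, nd$id))
}

#' Simulate trait evolution under the null (no-environment) model
#'
#' Root-to-tip recursion `T_desc = T_anc + eps * B` with
#' `eps ~ Normal(0, sd)` independently per edge: the increment standard
#' deviation scales *linearly* with branch length `B` — the convention the
#' bias diagnostic ([type1_error_study()]) is defined on — not with
#' `sqrt(B)`; set `trait$variance_scaling = "sqrt_B"` for standard
#' Brownian motion.
#' Zero-length edges copy the ancestor value exactly.
#'
#' @param tree a [geophylo] object.
#' @param config a [sim_config()].
#' @param name name of the trait column to write (default `"trait"`).
#' @return the tree with the simulated trait at every node.
#' @export
simulate_traits_null <- function(tree, config, name = "trait") {
  stopifnot(inherits(tree, "geophylo"), inherits(config, "sim_config"))
  nd <- tree$nodes
  ed <- gp_edges(tree)
  ord <- edges_preorder(tree)
  root <- nd$node[is.na(nd$parent)]
  tv <- rep(NA_real_, nrow(nd))
  tv[root] <- config$trait$root
  sc <- config$trait$variance_scaling
  with_seed(config$seed + 3L, {
    for (k in ord) {
      B <- max(ed$length[k], 0)
      s <- if (sc == "linear_B") config$trait$sd * B
           else config$trait$sd * sqrt(B)
      tv[ed$desc[k]] <- tv[ed$anc[k]] + if (s > 0) stats::rnorm(1, 0, s) else 0
    }
  })
  gp_set_trait(tree, name, stats::setNames(tv, nd$id))
}

#' Simulate trait evolution with a direct environment effect
#'
#' Generative counterpart of the diachronic causal model: edges are
#' processed root-to-tip in order of ancestor age, and each increment is
#' `T_desc - T_anc ~ Normal((alpha + eta*H + gamma*Gt + rho*Pt) * dA,
#' sigma0 + beta*dA)` where `H` is the ancestor/descendant mean humidity
#' divided by its uncentred sample SD over positive-length edges (the same
#' scaling [build_node_pair_table()] applies, so generative and inferred
#' coefficients share a scale), and `Gt`/`Pt` are the mean trait of the
#' already-simulated geographic and phylogenetic neighbourhoods of the
#' descendant node (zero contribution where the neighbourhood is empty).
#' Zero-length edges copy the ancestor value.
#'
#' @param tree a [geophylo] with locations and a humidity column.
#' @param config a [sim_config()] with `trait$model = "causal"`.
#' @param name trait column name to write.
#' @return the tree with the simulated trait at every node.
#' @export
simulate_traits_causal <- function(tree, config, name = "trait") {
  stopifnot(inherits(tree, "geophylo"), inherits(config, "sim_config"))
  nd <- tree$nodes
  if (!"humidity" %in% names(nd)) stop("humidity must be simulated first")
  ed <- gp_edges(tree)
  pp <- config$trait$params
  dA <- pmax(ed$length, 0)
  if (any(pp$sigma0 + pp$beta * dA <= 0 & dA > 0))
    stop("sigma0 + beta*dA <= 0 for some edge; configuration rejected")

  h <- nd$humidity
  H_raw <- (h[ed$anc] + h[ed$desc]) / 2
  sdH <- stats::sd(H_raw[dA > 0])
  H <- if (isTRUE(sdH > 0)) H_raw / sdH else H_raw

  coph <- cophenetic_matrix(tree)
  geo <- greatcircle_matrix(tree)
  ord <- edges_preorder(tree)
  root <- nd$node[is.na(nd$parent)]
  tv <- rep(NA_real_, nrow(nd))
  tv[root] <- config$trait$root

  with_seed(config$seed + 4L, {
    for (k in ord) {
      if (dA[k] <= 0) { tv[ed$desc[k]] <- tv[ed$anc[k]]; next }
      t_desc <- ed$age_desc[k]
      # geographic neighbourhood: fully-simulated contemporaneous lineages
      Gt <- 0
      cross <- which(ed$age_anc > t_desc & ed$age_desc <= t_desc)
      cross <- setdiff(cross, k)
      cross <- cross[!is.na(tv[ed$desc[cross]])]
      if (length(cross)) {
        within <- geo[ed$desc[k], ed$desc[cross]] <= config$trait$geo_radius_km
        cross <- cross[within]
        if (length(cross)) {
          p <- (ed$age_anc[cross] - t_desc) / (ed$age_anc[cross] - ed$age_desc[cross])
          Gt <- mean(tv[ed$anc[cross]] + p * (tv[ed$desc[cross]] - tv[ed$anc[cross]]))
        }
      }
      # phylogenetic neighbourhood: simulated nodes within cophenetic radius
      Pt <- 0
      nb <- which(coph[ed$desc[k], ] < config$trait$phylo_radius &
                    !is.na(tv) & seq_len(nrow(nd)) != ed$desc[k] &
                    seq_len(nrow(nd)) != ed$anc[k])
      if (length(nb)) Pt <- mean(tv[nb])
      mu <- (pp$alpha + pp$eta * H[k] + pp$gamma * Gt + pp$rho * Pt) * dA[k]
      sg <- pp$sigma0 + pp$beta * dA[k]
      tv[ed$desc[k]] <- tv[ed$anc[k]] + stats::rnorm(1, mu, sg)
    }
  })
  gp_set_trait(tree, name, stats::setNames(tv, nd$id))
}

#' Simulate a complete synthetic geo-phylogenetic dataset
#'
#' Composes [simulate_tree()], [simulate_dispersal()],
#' [simulate_humidity()] and the trait generator selected by
#' `config$trait$model` into one call.
#'
#' @param config a [sim_config()].
#' @return a [geophylo] with locations, `humidity` and `trait` columns.
#' @export
simulate_geophylo <- function(config) {
  tree <- simulate_tree(config)
  tree <- simulate_dispersal(tree, config)
  tree <- simulate_humidity(tree, config)
  if (config$trait$model == "causal") simulate_traits_causal(tree, config)
  else simulate_traits_null(tree, config)
}
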