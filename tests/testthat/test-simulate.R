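test_that("simulated Yule trees have the requested size and crown age", {
  cfg <- sim_config(n_tips = 3, seed = 1)
  g <- simulate_tree(cfg)
  expect_equal(sum(g$nodes$is_leaf), 3)
  expect_equal(sum(!g$nodes$is_leaf), 2)
  expect_equal(nrow(geophylocausal:::gp_edges(g)), 4)
  # all root-to-tip paths equal the crown age after rescaling
  cfg2 <- sim_config(n_tips = 40, crown_age = 7.5, seed = 2)
  g2 <- simulate_tree(cfg2)
  depth <- ape::node.depth.edgelength(g2$phy)
  expect_equal(unname(depth[seq_len(40)]), rep(7.5, 40), tolerance = 1e-9)
  expect_equal(max(g2$nodes$age), 7.5, tolerance = 1e-9)
})

test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(n_tips = 12, seed = 99,
                    founder_jump = founder_jump())
  a <- simulate_geophylo(cfg)
  b <- simulate_geophylo(cfg)
  expect_identical(ape::write.tree(a$phy), ape::write.tree(b$phy))
  expect_identical(a$nodes, b$nodes)
  cfg2 <- cfg; cfg2$seed <- 100L
  c <- simulate_geophylo(cfg2)
  expect_false(identical(a$nodes$trait, c$nodes$trait))
})

test_that("zero dispersal keeps every node at the root location", {
  cfg <- sim_config(n_tips = 8, dispersal_sd = 0, seed = 5)
  g <- simulate_dispersal(simulate_tree(cfg), cfg)
  expect_true(all(g$nodes$lat == cfg$root_lat))
  expect_true(all(g$nodes$lon == cfg$root_lon))
})

test_that("per-edge dispersal displacement variance scales with branch length", {
  # Monte-Carlo: replicate dispersal on a fixed tree, check var ~ sd^2 * B
  cfg <- sim_config(n_tips = 6, dispersal_sd = 0.8, seed = 7)
  tr <- simulate_tree(cfg)
  ed <- geophylocausal:::gp_edges(tr)
  k <- which.max(ed$length)  # longest edge for best signal
  disp <- replicate(800, {
    cfg2 <- cfg; cfg2$seed <- sample.int(1e6, 1)
    g <- simulate_dispersal(tr, cfg2)
    g$nodes$lat[ed$desc[k]] - g$nodes$lat[ed$anc[k]]
  })
  expect_equal(stats::var(disp), cfg$dispersal_sd^2 * ed$length[k],
               tolerance = 0.15)
})

test_that("a founder jump produces separable leaf clusters", {
  sep <- function(cfg) {
    g <- simulate_dispersal(simulate_tree(cfg), cfg)
    xy <- cbind(g$nodes$lat, g$nodes$lon)[g$nodes$is_leaf, ]
    km <- stats::kmeans(xy, 2, nstart = 5)
    km$betweenss / km$totss
  }
  set.seed(1)
  with_jump <- vapply(1:6, function(s)
    sep(sim_config(n_tips = 80, seed = s, founder_jump = founder_jump())),
    numeric(1))
  without <- vapply(1:6, function(s)
    sep(sim_config(n_tips = 80, seed = s)), numeric(1))
  expect_gt(mean(with_jump), mean(without))
  expect_gt(mean(with_jump), 0.8)  # jump separates most spatial variance
})

test_that("humidity follows the configured field and inherits tree signal", {
  # constant field, no noise -> identical humidity everywhere
  cfg <- sim_config(n_tips = 10, seed = 3,
                    humidity = list(grad_lat = 0, grad_lon = 0, drift = 0,
                                    noise_sd = 0))
  g <- simulate_humidity(simulate_dispersal(simulate_tree(cfg), cfg), cfg)
  expect_equal(stats::sd(g$nodes$humidity), 0)
  # strong latitude gradient, vanishing noise -> |r| with latitude near 1
  cfg2 <- sim_config(n_tips = 60, seed = 4,
                     humidity = list(noise_sd = 1e-9))
  g2 <- simulate_humidity(simulate_dispersal(simulate_tree(cfg2), cfg2), cfg2)
  expect_gt(abs(stats::cor(g2$nodes$humidity, g2$nodes$lat)), 0.95)
})

test_that("simulated humidity has high phylogenetic signal under founder jumps", {
  lams <- vapply(1:3, function(s) {
    cfg <- sim_config(n_tips = 120, seed = 10 + s,
                      founder_jump = founder_jump())
    g <- simulate_humidity(simulate_dispersal(simulate_tree(cfg), cfg), cfg)
    pagels_lambda(g, "humidity")$lambda_hat
  }, numeric(1))
  expect_true(all(lams > 0.9))
})

test_that("null traits follow the linear-in-B error rule exactly", {
  # zero-length edge copies the ancestor; root value appears unchanged
  tab <- data.frame(id = c("A", "B", "R"), parent = c("R", "R", NA),
                    age = c(1, 0, 1), lat = 0, lon = 0)  # A's edge B = 0
  tr <- load_geophylo("(A:0,B:1)R;", tab)
  cfg <- sim_config(n_tips = 3, seed = 2)
  for (s in 1:5) {
    cfg$seed <- s
    g <- simulate_traits_null(tr, cfg)
    expect_equal(g$nodes$trait[g$nodes$id == "A"],
                 g$nodes$trait[g$nodes$id == "R"])
    expect_equal(g$nodes$trait[g$nodes$id == "R"], 2)
  }
})

test_that("null-model increment sd matches the branch length (not sqrt)", {
  tab <- data.frame(id = c("A", "B", "R"), parent = c("R", "R", NA),
                    age = c(0, 0, 2), lat = 0, lon = 0)
  tr <- load_geophylo("(A:2,B:2)R;", tab)
  cfg <- sim_config(n_tips = 3)
  incs <- vapply(1:4000, function(s) {
    cfg$seed <- s
    g <- simulate_traits_null(tr, cfg)
    g$nodes$trait[g$nodes$id == "A"] - 2
  }, numeric(1))
  expect_equal(stats::sd(incs), 2, tolerance = 0.05)    # sd = B = 2
  # sqrt_B option gives standard Brownian sd = sqrt(2)
  cfg$trait$variance_scaling <- "sqrt_B"
  incs2 <- vapply(1:4000, function(s) {
    cfg$seed <- s
    g <- simulate_traits_null(tr, cfg)
    g$nodes$trait[g$nodes$id == "A"] - 2
  }, numeric(1))
  expect_equal(stats::sd(incs2), sqrt(2), tolerance = 0.05)
})

test_that("causal generator collapses to pure noise when all effects vanish", {
  cfg <- sim_config(n_tips = 3, seed = 6,
                    trait = list(model = "causal",
                                 params = list(alpha = 0, eta = 0, gamma = 0,
                                               rho = 0, sigma0 = 0.4,
                                               beta = 0)))
  tab <- data.frame(id = c("A", "B", "R"), parent = c("R", "R", NA),
                    age = c(0, 0, 1), lat = c(0, 1, 0), lon = 0)
  tr <- load_geophylo("(A:1,B:1)R;", tab)
  tr <- simulate_humidity(tr, cfg)
  incs <- vapply(1:4000, function(s) {
    cfg$seed <- s
    g <- simulate_traits_causal(tr, cfg)
    g$nodes$trait[g$nodes$id == "A"] - 2
  }, numeric(1))
  expect_equal(mean(incs), 0, tolerance = 0.03)
  expect_equal(stats::sd(incs), 0.4, tolerance = 0.02)
})

test_that("causal increment means follow (eta * H) * dA", {
  # single edge, eta = 1, others 0: mean change = H_z * dA
  cfg <- sim_config(n_tips = 3, seed = 8,
                    trait = list(model = "causal",
                                 params = list(alpha = 0, eta = 1, gamma = 0,
                                               rho = 0, sigma0 = 0.3,
                                               beta = 0)))
  tab <- data.frame(id = c("A", "B", "R"), parent = c("R", "R", NA),
                    age = c(0, 0, 1), lat = c(0, 4, 2), lon = 0)
  tr <- load_geophylo("(A:1,B:1)R;", tab)
  tr <- simulate_humidity(tr, cfg)
  h <- tr$nodes$humidity
  ed <- geophylocausal:::gp_edges(tr)
  Hraw <- (h[ed$anc] + h[ed$desc]) / 2
  Hz <- Hraw / stats::sd(Hraw)
  kA <- which(ed$desc_id == "A")
  incs <- vapply(1:3000, function(s) {
    cfg$seed <- s
    g <- simulate_traits_causal(tr, cfg)
    g$nodes$trait[g$nodes$id == "A"] - 2
  }, numeric(1))
  expect_equal(mean(incs), Hz[kA] * 1, tolerance = 0.05 * max(1, abs(Hz[kA])))
})

test_that("stronger eta raises the leaf-level trait-humidity correlation", {
  cors <- vapply(c(0, 0.5, 2), function(eta) {
    cfg <- sim_config(n_tips = 60, seed = 11, founder_jump = founder_jump(),
                      trait = list(model = "causal",
                                   params = list(alpha = 0, eta = eta,
                                                 gamma = 0, rho = 0,
                                                 sigma0 = 0.5, beta = 0.05)))
    g <- simulate_geophylo(cfg)
    leaves <- g$nodes$is_leaf
    stats::cor(g$nodes$trait[leaves], g$nodes$humidity[leaves])
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("invalid variance configurations are rejected", {
  cfg <- sim_config(n_tips = 6, seed = 1,
                    trait = list(model = "causal",
                                 params = list(alpha = 0, eta = 0, gamma = 0,
                                               rho = 0, sigma0 = 0.1,
                                               beta = -1)))
  g <- simulate_humidity(simulate_dispersal(simulate_tree(cfg), cfg), cfg)
  expect_error(simulate_traits_causal(g, cfg), "rejected")
})
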