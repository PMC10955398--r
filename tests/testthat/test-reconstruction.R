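test_that("a fossilised root is returned exactly with zero standard error", {
  tr <- cherry_tree()
  tr <- geophylocausal:::gp_set_trait(tr, "trait", c(A = 1, B = 3))
  rec <- asr_brownian(tr, "trait", root_fossil = 2.5)
  expect_equal(rec$T_REC[rec$id == "R"], 2.5)
  expect_equal(rec$T_SE[rec$id == "R"], 0)
  expect_true(all(rec$T_SE[rec$is_leaf] == 0))
})

test_that("a chain node's conditional mean is the precision-weighted average", {
  # root(fossil r) -b1-> A -> leaves y2 (b2), y3 (b3):
  # T_REC(A) = (r/b1 + y2/b2 + y3/b3) / (1/b1 + 1/b2 + 1/b3)
  r <- 2; b1 <- 1.5; b2 <- 0.5; b3 <- 2; y2 <- 4; y3 <- 1
  nw <- sprintf("((L2:%g,L3:%g)A:%g)R;", b2, b3, b1)
  # ages: put A at b2 and shift so the youngest leaf sits at 0
  ages <- c(L2 = 0, L3 = b2 - b3, R = b1 + b2, A = b2)
  ages <- ages - min(ages)
  tab <- data.frame(id = names(ages), parent = c("A", "A", NA, "R"),
                    age = unname(ages), lat = 0, lon = 0)
  tr <- load_geophylo(nw, tab)
  tr <- geophylocausal:::gp_set_trait(tr, "trait", c(L2 = y2, L3 = y3))
  rec <- asr_brownian(tr, "trait", root_fossil = r)
  expected <- (r / b1 + y2 / b2 + y3 / b3) / (1 / b1 + 1 / b2 + 1 / b3)
  expect_equal(rec$T_REC[rec$id == "A"], expected, tolerance = 1e-10)
})

test_that("belief propagation equals dense Gaussian conditioning on small trees", {
  for (seed in 1:4) {
    n <- sample(4:8, 1)
    g <- small_geophylo(n, seed = seed)
    # fossilised root
    rec <- asr_brownian(g, "trait", root_fossil = 2)
    oracle <- asr_dense_oracle(g, "trait", root_fossil = 2,
                               rate = attr(rec, "rate"))
    idx <- match(oracle$ids, rec$id)
    expect_equal(rec$T_REC[idx], oracle$mean, tolerance = 1e-8)
    expect_equal(rec$T_SE[idx], oracle$sd, tolerance = 1e-8)
    # free root
    rec2 <- asr_brownian(g, "trait")
    oracle2 <- asr_dense_oracle(g, "trait", rate = attr(rec2, "rate"))
    idx2 <- match(oracle2$ids, rec2$id)
    expect_equal(rec2$T_REC[idx2], oracle2$mean, tolerance = 1e-8)
    expect_equal(rec2$T_SE[idx2], oracle2$sd, tolerance = 1e-8)
  }
})

test_that("wide bounds converge to the unbounded reconstruction", {
  g <- small_geophylo(8, seed = 11)
  rec <- asr_brownian(g, "trait", root_fossil = 2)
  recb <- asr_brownian(g, "trait", root_fossil = 2, bounds = c(-1e4, 1e4))
  expect_equal(recb$T_REC, rec$T_REC, tolerance = 1e-6)
  expect_equal(recb$T_SE, rec$T_SE, tolerance = 1e-6)
  # tight bounds shrink the spread of the truncated (free) nodes
  rect <- asr_brownian(g, "trait", root_fossil = 2, bounds = c(0, 4))
  free <- rect$T_SE > 0 | (!rect$is_leaf & !rect$fossil)
  expect_true(all(rect$T_REC[free] >= 0 & rect$T_REC[free] <= 4))
  expect_true(all(rect$T_SE <= rec$T_SE + 1e-12))
  expect_error(asr_brownian(g, "trait", root_fossil = 9, bounds = c(0, 4)),
               "outside bounds")
})

test_that("missing leaf values are refused", {
  tr <- cherry_tree()
  tr <- geophylocausal:::gp_set_trait(tr, "trait", c(A = 1))
  expect_error(asr_brownian(tr, "trait"), "B")
})

test_that("Pagel's lambda separates tree-generated from iid traits", {
  hi <- vapply(1:8, function(s) {
    g <- simulate_geophylo(sim_config(n_tips = 150, seed = 20 + s,
                                      trait = list(variance_scaling = "sqrt_B")))
    pagels_lambda(g, "trait")$lambda_hat
  }, numeric(1))
  lo <- vapply(1:8, function(s) {
    g <- simulate_tree(sim_config(n_tips = 150, seed = 40 + s))
    set.seed(1000 + s)
    v <- stats::setNames(rnorm(nrow(g$nodes)), g$nodes$id)
    g <- geophylocausal:::gp_set_trait(g, "trait", v)
    pagels_lambda(g, "trait")$lambda_hat
  }, numeric(1))
  expect_gte(mean(hi > 0.8), 0.9)
  expect_gte(mean(lo < 0.2), 0.9)
  expect_true(all(hi >= 0 & hi <= 1) && all(lo >= 0 & lo <= 1))
})

test_that("lambda profile endpoints match plain-Brownian and iid likelihoods", {
  g <- small_geophylo(20, seed = 9)
  pl <- pagels_lambda(g, "trait", profile_points = 3)
  y <- g$nodes$trait[g$nodes$is_leaf]
  names(y) <- g$nodes$id[g$nodes$is_leaf]
  C <- ape::vcv(g$phy); y <- y[rownames(C)]
  n <- length(y)
  gls_ll <- function(Cl) {
    iS <- solve(Cl)
    mu <- sum(iS %*% y) / sum(iS)
    s2 <- as.numeric((y - mu) %*% iS %*% (y - mu)) / n
    -0.5 * (n * log(2 * pi * s2) + determinant(Cl)$modulus[1] + n)
  }
  expect_equal(pl$profile$loglik[1], gls_ll(diag(diag(C))), tolerance = 1e-6)
  expect_equal(pl$profile$loglik[3], gls_ll(C), tolerance = 1e-6)
})

test_that("our lambda estimate agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  # Brownian signal plus iid measurement noise puts the optimum strictly
  # inside (0, 1), where both implementations search the same domain
  g <- simulate_geophylo(sim_config(n_tips = 80, seed = 13,
                                    trait = list(variance_scaling = "sqrt_B")))
  y <- stats::setNames(g$nodes$trait[g$nodes$is_leaf],
                       g$nodes$id[g$nodes$is_leaf])
  set.seed(99)
  y <- y + rnorm(length(y), 0, 1)
  g <- geophylocausal:::gp_set_trait(g, "noisy", y)
  pl <- pagels_lambda(g, "noisy")
  ps <- phytools::phylosig(g$phy, y, method = "lambda")
  expect_gt(pl$lambda_hat, 0.05)
  expect_lt(pl$lambda_hat, 0.95)
  expect_equal(pl$lambda_hat, ps$lambda, tolerance = 0.02)
  expect_equal(pl$loglik, ps$logL, tolerance = 1e-3)
})

test_that("constant traits make lambda undefined, with an explicit error", {
  g <- simulate_tree(sim_config(n_tips = 6, seed = 2))
  v <- stats::setNames(rep(1, nrow(g$nodes)), g$nodes$id)
  g <- geophylocausal:::gp_set_trait(g, "trait", v)
  expect_error(pagels_lambda(g, "trait"), "constant")
})

make_grid <- function(f, years = seq(0, 1000, length.out = 5),
                      lats = seq(-10, 10, length.out = 5),
                      lons = seq(5, 25, length.out = 5)) {
  g <- expand.grid(year = years, lat = lats, lon = lons)
  g$humidity <- f(g$year, g$lat, g$lon)
  g
}

test_that("the spline field reproduces linear fields almost perfectly", {
  grid <- make_grid(function(y, la, lo) 0.01 + 1e-6 * y + 2e-4 * la - 1e-4 * lo)
  f <- suppressWarnings(fit_humidity_field(grid))
  expect_gt(f$rsq_cv, 0.999)
  q <- data.frame(year = c(111, 777), lat = c(-3.2, 7.7), lon = c(6.5, 19.1))
  expect_equal(predict(f, q),
               0.01 + 1e-6 * q$year + 2e-4 * q$lat - 1e-4 * q$lon,
               tolerance = 1e-6)
})

test_that("a constant field predicts constantly", {
  grid <- make_grid(function(y, la, lo) rep(0.013, length(y)))
  f <- suppressWarnings(fit_humidity_field(grid))
  q <- data.frame(year = runif(20, 0, 1000), lat = runif(20, -10, 10),
                  lon = runif(20, 5, 25))
  expect_equal(predict(f, q), rep(0.013, 20), tolerance = 1e-9)
})

test_that("the spline interpolator beats trilinear on a smooth nonlinear field", {
  truth <- function(y, la, lo)
    0.012 + 0.004 * sin(la / 4) * cos(lo / 6) + 1e-6 * y * cos(la / 8)
  grid <- make_grid(truth, years = seq(0, 1000, length.out = 7),
                    lats = seq(-10, 10, length.out = 7),
                    lons = seq(5, 25, length.out = 7))
  f <- suppressWarnings(fit_humidity_field(grid, k = c(6, 6, 6)))
  b <- bilinear_baseline(grid)
  set.seed(5)
  q <- data.frame(year = runif(300, 0, 1000), lat = runif(300, -10, 10),
                  lon = runif(300, 5, 25))
  tv <- truth(q$year, q$lat, q$lon)
  r2 <- function(p) 1 - sum((tv - p)^2) / sum((tv - mean(tv))^2)
  expect_gte(r2(predict(f, q)), r2(predict(b, q)))
})

test_that("trilinear interpolation is exact at grid points and cell centres", {
  grid <- make_grid(function(y, la, lo) 0.01 + 1e-5 * y + 1e-3 * la)
  b <- bilinear_baseline(grid)
  # grid-point queries reproduce grid values exactly
  sub <- grid[sample.int(nrow(grid), 30), ]
  expect_equal(predict(b, sub), sub$humidity, tolerance = 1e-12)
  # symmetric-cell midpoint equals the mean of the 8 corners
  ys <- sort(unique(grid$year))[1:2]; las <- sort(unique(grid$lat))[1:2]
  los <- sort(unique(grid$lon))[1:2]
  corners <- grid[grid$year %in% ys & grid$lat %in% las & grid$lon %in% los, ]
  mid <- data.frame(year = mean(ys), lat = mean(las), lon = mean(los))
  expect_equal(predict(b, mid), mean(corners$humidity), tolerance = 1e-12)
  expect_error(predict(b, data.frame(year = -5, lat = 0, lon = 10)),
               "outside")
})

test_that("node humidity evaluation matches direct field evaluation", {
  grid <- make_grid(function(y, la, lo) 0.01 + 2e-4 * la,
                    years = seq(-6000, 2000, length.out = 5))
  f <- suppressWarnings(fit_humidity_field(grid))
  g <- small_geophylo(12, seed = 6)
  h <- humidity_at_nodes(f, g, ref_year_tree = 2000, year_unit = "CE")
  direct <- predict(f, data.frame(year = 2000 - 1000 * g$nodes$age,
                                  lat = g$nodes$lat, lon = g$nodes$lon))
  expect_equal(unname(h), direct)
  # purely spatial field: same place, different ages -> equal values
  tab <- data.frame(id = c("A", "B", "R"), parent = c("R", "R", NA),
                    age = c(0, 1, 2), lat = 3, lon = 12)
  tr <- load_geophylo("(A:2,B:1)R;", tab)
  hh <- humidity_at_nodes(f, tr)
  expect_equal(unname(hh[1]), unname(hh[2]), tolerance = 1e-6)
})
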