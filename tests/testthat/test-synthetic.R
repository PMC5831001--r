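test_that("lattice geography has the declared shape and queen adjacency", {
  g3 <- make_lattice(sim_config(rows = 3, cols = 3, seed = 1))
  expect_equal(nrow(g3$districts), 9)
  counts <- table(c(g3$adjacency$district_id_a, g3$adjacency$district_id_b))
  centre <- g3$districts$district_id[g3$districts$row == 2 &
                                       g3$districts$col == 2]
  expect_equal(unname(counts[[centre]]), 8)

  line <- make_lattice(sim_config(rows = 1, cols = 9, seed = 1))
  cl <- table(c(line$adjacency$district_id_a, line$adjacency$district_id_b))
  ends <- line$districts$district_id[line$districts$col %in% c(1, 9)]
  expect_true(all(cl[ends] == 1))

  # adjacency is symmetric and irreflexive for arbitrary sizes
  set.seed(2)
  for (rep in 1:3) {
    r <- sample(3:6, 1); c <- sample(3:6, 1)
    g <- make_lattice(sim_config(rows = r, cols = c, seed = rep))
    expect_false(any(g$adjacency$district_id_a == g$adjacency$district_id_b))
    key <- paste(pmin(g$adjacency$district_id_a, g$adjacency$district_id_b),
                 pmax(g$adjacency$district_id_a, g$adjacency$district_id_b))
    expect_false(anyDuplicated(key) > 0)
    # exhaustive oracle on the count of edges: inner grid formula
    expect_equal(nrow(g$adjacency),
                 r * (c - 1) + c * (r - 1) + 2 * (r - 1) * (c - 1))
  }
  expect_error(sim_config(rows = 2, cols = 2, seed = 1), "at least 9")
})

test_that("smoothing controls the spatial autocorrelation of covariates", {
  lag_corr <- function(radius, seed = 202) {
    cfg <- sim_config(rows = 20, cols = 20, smoothing_radius = radius,
                      gradient = 0, seed = seed)
    geo <- make_lattice(cfg)
    covs <- make_clustered_covariates(geo, cfg)
    w <- build_weights(geo$districts, "binary_contiguity",
                       adjacency = geo$adjacency)
    cor(covs$cov1, spatial_lag(w, covs$cov1)$lag)
  }
  expect_lt(abs(lag_corr(0)), 0.2)   # iid field: near-zero lag correlation
  expect_gt(lag_corr(3), 0.5)        # smoothed field: strong clustering
})

test_that("generation is bit-stable under the seed", {
  cfg <- sim_config(rows = 4, cols = 4, seed = 99)
  a <- simulate_districts(cfg)
  b <- simulate_districts(cfg)
  expect_identical(a$attributes, b$attributes)
  expect_identical(a$lifetables, b$lifetables)
  c <- simulate_districts(sim_config(rows = 4, cols = 4, seed = 100))
  expect_false(identical(a$attributes$outcome, c$attributes$outcome))
})

test_that("the outcome follows the declared generating process", {
  cfg0 <- sim_config(rows = 4, cols = 4, beta = 0, noise_sd = 0,
                     gradient = 0, seed = 5)
  geo <- make_lattice(cfg0)
  covs <- make_clustered_covariates(geo, cfg0)
  expect_equal(make_outcome(geo, covs, cfg0)$outcome, rep(0, 16))

  cfg1 <- sim_config(rows = 4, cols = 4, beta = c(2, -1, 0.5), noise_sd = 0,
                     seed = 5)
  covs1 <- make_clustered_covariates(geo, cfg1)
  y1 <- make_outcome(geo, covs1, cfg1)
  X <- as.matrix(covs1[paste0("cov", 1:3)])
  expect_equal(y1$outcome, as.numeric(X %*% c(2, -1, 0.5)), tolerance = 1e-12)

  # autoregressive case against a direct dense solve of the SAR system
  cfg2 <- sim_config(rows = 4, cols = 4, rho = 0.6, seed = 5)
  covs2 <- make_clustered_covariates(geo, cfg2)
  y2 <- make_outcome(geo, covs2, cfg2)
  w <- build_weights(geo$districts, "binary_contiguity",
                     adjacency = geo$adjacency)
  # the rho = 0 run with the same seed yields the same X beta + eps,
  # so the dense solve of (I - rho W) y = X beta + eps is an oracle
  y0 <- make_outcome(geo, covs2,
                     sim_config(rows = 4, cols = 4, rho = 0, seed = 5))$outcome
  expect_equal(y2$outcome, as.numeric(solve(diag(16) - 0.6 * w$W, y0)),
               tolerance = 1e-10)
  # dependence inflates outcome variance
  expect_gt(var(y2$outcome), var(make_outcome(geo, covs2,
    sim_config(rows = 4, cols = 4, rho = 0, seed = 5))$outcome))
})

test_that("generated life tables link frailty monotonically to mortality", {
  g <- make_lattice(sim_config(rows = 3, cols = 3, seed = 3))
  # frailty 1 everywhere: identical premature mortality in all districts
  lt <- make_lifetables(g$districts, frailty = 1)
  pm <- premature_mortality(lt)
  expect_equal(length(unique(round(pm$premature_mortality, 9))), 2)  # one per sex

  # doubled frailty in one district strictly raises its outcome
  fr <- rep(1, 9); fr[5] <- 2
  pm2 <- premature_mortality(make_lifetables(g$districts, frailty = fr))
  male <- dplyr::filter(pm2, sex == "male")
  expect_gt(male$premature_mortality[male$district_id == g$districts$district_id[5]],
            max(male$premature_mortality[male$district_id != g$districts$district_id[5]]))

  # premature mortality matches the closed-form survival product
  a <- 5e-5; b <- 0.09; ages <- 0:89
  H <- (a / b) * (exp(b * (ages + 1)) - exp(b * ages))
  qx <- 1 - exp(-1 * H)
  expected <- 100000 * (1 - prod(1 - qx[ages < 70]))
  expect_equal(male$premature_mortality[1], expected, tolerance = 1e-9)

  expect_error(make_lifetables(g$districts, frailty = -1), "positive")
  expect_error(make_lifetables(g$districts, a = 0), "positive")
})
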