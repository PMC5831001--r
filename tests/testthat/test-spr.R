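test_that("an empty baseline passes the outcome through as residuals", {
  d <- tibble::tibble(district_id = letters[1:6], y = rnorm(6))
  br <- baseline_residuals(d, "y")
  expect_identical(br$residual, d$y)
  # intercept-only baseline: deviations from the mean
  bi <- baseline_residuals(d, "y", covariates = "(Intercept)")
  expect_equal(bi$residual, d$y - mean(d$y), tolerance = 1e-10)
})

test_that("pattern measurement handles constant and identity residuals", {
  cfg <- sim_config(rows = 4, cols = 4, seed = 31)
  geo <- make_lattice(cfg)
  # constant residuals: geo-dimension slopes are exactly 0; the lag
  # regressor is then constant too, so lag dimensions are skipped
  const <- tibble::tibble(district_id = geo$districts$district_id, residual = 5)
  pat <- suppressMessages(
    measure_patterns(const, geo$districts, adjacency = geo$adjacency,
                     centre = c(0, 0)))
  geo_dims <- c("northness", "westness", "centrality", "urbanity")
  expect_equal(pat$coefficient[pat$dimension %in% geo_dims], rep(0, 4),
               tolerance = 1e-10)
  skipped <- attr(pat, "skipped")
  expect_setequal(skipped$dimension, c("contiguity", "proximity"))
  expect_true(all(skipped$reason == "zero-variance regressor"))

  # residuals identical to the northing: northness slope is exactly 1
  ident <- tibble::tibble(district_id = geo$districts$district_id,
                          residual = geo$districts$northing_km)
  pat2 <- measure_patterns(ident, geo$districts, dimensions = "northness")
  expect_equal(pat2$coefficient, 1, tolerance = 1e-10)
})

test_that("pattern slopes match the long-hand normal-equations oracle", {
  # 8-district toy with a hand-computable contiguity lag
  d <- tibble::tibble(district_id = letters[1:8],
                      easting_km = c(0, 1, 2, 3, 0, 1, 2, 3),
                      northing_km = c(0, 0, 0, 0, 1, 1, 1, 1),
                      area_km2 = 1, population = 10)
  adj <- tibble::tibble(district_id_a = c("a", "b", "c", "e", "f", "g", "a", "b", "c", "d"),
                        district_id_b = c("b", "c", "d", "f", "g", "h", "e", "f", "g", "h"))
  set.seed(13)
  res <- tibble::tibble(district_id = d$district_id, residual = rnorm(8))
  # equal populations make urbanity degenerate here; it is skipped
  pat <- suppressMessages(
    measure_patterns(res, d, adjacency = adj, centre = c(0, 0)))

  w <- build_weights(d, "binary_contiguity", adjacency = adj)
  lag <- as.numeric(w$W %*% res$residual)
  oracle <- ols_hc1_oracle(cbind(1, lag), res$residual)
  row <- pat[pat$dimension == "contiguity", ]
  expect_equal(row$coefficient, oracle$beta[2], tolerance = 1e-10)
  expect_equal(row$robust_se, oracle$se[2], tolerance = 1e-10)

  orc_n <- ols_hc1_oracle(cbind(1, d$northing_km), res$residual)
  expect_equal(pat$coefficient[pat$dimension == "northness"], orc_n$beta[2],
               tolerance = 1e-10)
})

test_that("decline reproduces published-style ratios and guards tiny baselines", {
  expect_equal(round(decline(0.0078, 0.0005), 1), 93.6)
  expect_equal(round(decline(1.9100, -0.0562), 1), 102.9)
  expect_equal(decline(0.42, 0.42), 0)
  expect_warning(d <- decline(c(1, 0), c(0.5, 0.2)), "guard")
  expect_equal(d, c(50, NA))
})

test_that("replay mode reproduces declines from a printed coefficient table", {
  path <- system.file("extdata", "gb_pattern_coefficients.csv",
                      package = "spatrec")
  out <- replay_declines(read.csv(path))
  expect_equal(nrow(out), 12)
  male_north <- out$decline_rounded[out$dimension == "northness" &
                                      out$sex == "male"]
  expect_equal(male_north, 93.6)
})

test_that("using the baseline model as the full model gives zero declines", {
  cfg <- sim_config(rows = 5, cols = 5, seed = 17)
  geo <- make_lattice(cfg)
  covs <- make_clustered_covariates(geo, cfg)
  y <- make_outcome(geo, covs, cfg)
  d <- dplyr::left_join(covs, y, by = "district_id")
  rep <- run_spr(d, geo$districts, outcome = "outcome",
                 covariates = "cov1", baseline_covariates = "cov1",
                 adjacency = geo$adjacency, centre = c(0, 0))
  declines <- tibble::as_tibble(rep)$decline
  expect_equal(declines[!is.na(declines)],
               rep(0, sum(!is.na(declines))), tolerance = 1e-8)
})

test_that("declines are invariant to positive rescaling of outcome and geography", {
  base <- run_regime(101, rows = 8, cols = 8, noise = 0.3)
  cfg <- sim_config(rows = 8, cols = 8, smoothing_radius = 2, noise_sd = 0.3,
                    gradient = 0.5, seed = 101)
  geo <- make_lattice(cfg)
  covs <- make_clustered_covariates(geo, cfg)
  y <- make_outcome(geo, covs, cfg)
  d <- dplyr::left_join(covs, y, by = "district_id") |>
    dplyr::mutate(outcome = outcome * 1000)  # rescale the outcome
  geo_scaled <- dplyr::mutate(geo$districts,
                              easting_km = easting_km * 3,
                              northing_km = northing_km * 3)
  rep2 <- run_spr(d, geo_scaled, outcome = "outcome",
                  covariates = paste0("cov", 1:3),
                  adjacency = geo$adjacency, centre = c(0, 0))
  t1 <- tibble::as_tibble(base); t2 <- tibble::as_tibble(rep2)
  expect_equal(t2$decline, t1$decline, tolerance = 1e-6)
})

test_that("enriched residual sum of squares never exceeds the baseline's", {
  for (seed in 1:5) {
    rep <- run_regime(seed, rows = 6, cols = 6, noise = 0.5)
    g <- glance(rep)
    expect_lte(g$ss_enriched, g$ss_baseline + 1e-10)
  }
})

test_that("a noiseless generating model leaves no enriched pattern", {
  cfg <- sim_config(rows = 6, cols = 6, smoothing_radius = 2, noise_sd = 0,
                    gradient = 0.5, seed = 53)
  geo <- make_lattice(cfg)
  covs <- make_clustered_covariates(geo, cfg)
  y <- make_outcome(geo, covs, cfg)
  d <- dplyr::left_join(covs, y, by = "district_id")
  rep <- suppressMessages(
    run_spr(d, geo$districts, outcome = "outcome",
            covariates = paste0("cov", 1:3),
            adjacency = geo$adjacency, centre = c(0, 0)))
  t <- tibble::as_tibble(rep)
  geo_dims <- c("northness", "westness", "centrality", "urbanity")
  expect_equal(t$enriched_coefficient[t$dimension %in% geo_dims],
               rep(0, 4), tolerance = 1e-7)
})

test_that("outlier exclusion re-runs both passes on the retained set", {
  cfg <- sim_config(rows = 6, cols = 6, noise_sd = 0.1, seed = 71)
  geo <- make_lattice(cfg)
  covs <- make_clustered_covariates(geo, cfg)
  y <- make_outcome(geo, covs, cfg)
  d <- dplyr::left_join(covs, y, by = "district_id")
  d$outcome[10] <- d$outcome[10] + 25  # gross planted outlier
  rep <- run_spr(d, geo$districts, outcome = "outcome",
                 covariates = paste0("cov", 1:3), adjacency = geo$adjacency,
                 centre = c(0, 0), exclude_outliers = TRUE)
  dropped <- attr(rep, "fits")$all$dropped_outliers
  expect_true(d$district_id[10] %in% dropped$district_id)
  expect_equal(unique(tibble::as_tibble(rep)$baseline_n),
               36 - nrow(dropped))
  # identical to running manually on the retained set
  keep <- !d$district_id %in% dropped$district_id
  manual <- run_spr(d[keep, ], geo$districts,
                    outcome = "outcome", covariates = paste0("cov", 1:3),
                    adjacency = dplyr::filter(
                      geo$adjacency,
                      district_id_a %in% d$district_id[keep],
                      district_id_b %in% d$district_id[keep]),
                    centre = c(0, 0))
  expect_equal(tibble::as_tibble(rep)$decline,
               tibble::as_tibble(manual)$decline, tolerance = 1e-10)
})

test_that("subset runs rebuild weights inside the subset only", {
  cfg <- sim_config(rows = 6, cols = 6, seed = 83)
  geo <- make_lattice(cfg)
  covs <- make_clustered_covariates(geo, cfg)
  y <- make_outcome(geo, covs, cfg)
  d <- dplyr::left_join(covs, y, by = "district_id")
  south <- geo$districts$district_id[geo$districts$row <= 3]
  rep_sub <- run_spr(d, geo$districts, outcome = "outcome",
                     covariates = paste0("cov", 1:3),
                     adjacency = geo$adjacency, centre = c(0, 0),
                     subset_ids = south)
  manual <- run_spr(d[d$district_id %in% south, ],
                    geo$districts[geo$districts$district_id %in% south, ],
                    outcome = "outcome", covariates = paste0("cov", 1:3),
                    adjacency = dplyr::filter(geo$adjacency,
                                              district_id_a %in% south,
                                              district_id_b %in% south),
                    centre = c(0, 0))
  expect_equal(tibble::as_tibble(rep_sub)$baseline_coefficient,
               tibble::as_tibble(manual)$baseline_coefficient,
               tolerance = 1e-12)
  expect_equal(unique(tibble::as_tibble(rep_sub)$baseline_n), length(south))
})

test_that("residual excess ranking orders districts by unexplained mortality", {
  # all-zero residuals: empty ranking
  line <- tibble::tibble(district_id = c("a", "b", "c"),
                         y = c(0, 1, 2), x = c(0, 1, 2))
  f0 <- fit_ols(line, "y", "x")
  expect_equal(nrow(rank_residual_excess(f0)), 0)

  # planted excess district tops the list, invariant to input order
  set.seed(91)
  d <- tibble::tibble(district_id = sprintf("d%02d", 1:20),
                      x = rnorm(20))
  d$y <- 2 * d$x + rnorm(20, sd = 0.3)
  d$y[4] <- d$y[4] + 10
  rk <- rank_residual_excess(fit_ols(d, "y", "x"))
  expect_equal(rk$district_id[1], "d04")
  expect_equal(rk$tail[1], "excess")
  shuffled <- d[sample(20), ]
  rk2 <- rank_residual_excess(fit_ols(shuffled, "y", "x"))
  expect_equal(rk2$district_id, rk$district_id)
})

test_that("reports expose tidy, glance, table and plot surfaces", {
  rep <- run_regime(7, rows = 5, cols = 5, noise = 0.3)
  t <- tidy(rep)
  expect_s3_class(t, "tbl_df")
  expect_true(all(c("dimension", "baseline_coefficient",
                    "enriched_coefficient", "decline") %in% names(t)))
  wide <- report_table(rep)
  expect_equal(nrow(wide), 6)
  expect_true("decline_all" %in% names(wide))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
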