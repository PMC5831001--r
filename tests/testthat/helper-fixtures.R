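# Fixture builders and independent oracles shared across tests.

# single-year life table with a constant conditional death probability
const_lifetable <- function(qx, ages = 0:69, id = "A", sex = "male") {
  tibble::tibble(district_id = id, sex = sex,
                 age_start = ages, age_end = ages + 1, qx = qx)
}

# brute-force survivorship oracle: explicit per-interval loop
survival_loop_oracle <- function(qx, cohort = 100000) {
  s <- numeric(length(qx) + 1)
  s[1] <- cohort
  for (k in seq_along(qx)) s[k + 1] <- s[k] * (1 - qx[k])
  s
}

# three districts on a line, A-B and B-C adjacent
line_geography <- function() {
  list(
    districts = tibble::tibble(
      district_id = c("A", "B", "C"),
      easting_km = c(0, 1, 2), northing_km = 0,
      area_km2 = 1, population = 100),
    adjacency = tibble::tibble(district_id_a = c("A", "B"),
                               district_id_b = c("B", "C")))
}

# long-hand OLS + HC1 sandwich oracle, written directly from the
# normal equations: beta = (X'X)^-1 X'y,
# V = (X'X)^-1 X' diag(e^2) X (X'X)^-1 * n/(n-k)
ols_hc1_oracle <- function(X, y) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  e <- as.numeric(y - X %*% beta)
  n <- nrow(X); k <- ncol(X)
  meat <- t(X) %*% diag(e^2) %*% X
  V <- XtX_inv %*% meat %*% XtX_inv * n / (n - k)
  list(beta = as.numeric(beta), se = unname(sqrt(diag(V))), residuals = e)
}

# tiny attribute table with the GB block columns filled with arbitrary
# but valid shares, n districts
gb_attribute_fixture <- function(n, seed = 1) {
  set.seed(seed)
  blocks <- spatrec::gb_blocks()
  d <- tibble::tibble(district_id = sprintf("d%03d", seq_len(n)),
                      population = round(runif(n, 5000, 500000)))
  for (b in blocks) {
    k <- length(b$columns)
    shares <- matrix(stats::rexp(n * k), n, k)
    shares <- 100 * shares / rowSums(shares)
    for (i in seq_len(k)) d[[b$columns[i]]] <- shares[, i]
  }
  d$mean_income <- runif(n, 15000, 60000)  # not a share
  d$benefit_claimants <- runif(n, 2, 25)
  d
}

# run the generator + engine once for a given regime; returns tidy report
run_regime <- function(seed, rho = 0, smoothing = 2, noise = 0.05,
                       gradient = 0.5, rows = 20, cols = 20) {
  cfg <- sim_config(rows = rows, cols = cols, smoothing_radius = smoothing,
                    noise_sd = noise, gradient = gradient, rho = rho,
                    seed = seed)
  geo <- make_lattice(cfg)
  covs <- make_clustered_covariates(geo, cfg)
  y <- make_outcome(geo, covs, cfg)
  d <- dplyr::left_join(covs, y, by = "district_id")
  run_spr(d, geo$districts, outcome = "outcome",
          covariates = paste0("cov", seq_len(cfg$n_covariates)),
          adjacency = geo$adjacency, centre = c(0, 0))
}
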