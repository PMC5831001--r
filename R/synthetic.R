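#' Configuration for the synthetic-geography generator
#'
#' Defines a rectangular lattice of districts together with the
#' data-generating process for covariates and outcome. Spatial structure
#' can enter through two distinct causal channels, mirroring the
#' distinction the pattern-recognition procedure is built to probe:
#' *clustering* (covariates smoothed across neighbouring districts, so
#' the outcome inherits their spatial pattern) and *dependence* (the
#' outcome of each district feeds into its neighbours' through a
#' simultaneous autoregressive term with parameter `rho`).
#'
#' Defaults describe the package's reference study regime: a 20 x 20
#' lattice at 10 km spacing, three covariates smoothed over a radius of
#' 2 lattice steps with a north-south gradient tilt of 0.5 sd, unit
#' effect sizes, outcome noise sd 0.2 and no dependence (`rho = 0`).
#'
#' @param rows,cols Lattice dimensions (`rows * cols` between 9 and 2500;
#'   the autoregressive solve is dense).
#' @param spacing_km Centroid spacing in kilometres.
#' @param n_covariates Number of covariate columns.
#' @param smoothing_radius Chebyshev radius (in lattice steps) of the
#'   moving-average smoothing of each covariate field; 0 gives i.i.d.
#'   columns.
#' @param beta Effect size per covariate (recycled to `n_covariates`).
#' @param noise_sd Standard deviation of the i.i.d. outcome noise.
#' @param gradient Strength of a north-south tilt added to each
#'   covariate (in sd of northing); 0 disables it.
#' @param rho Simultaneous autoregressive dependence parameter,
#'   `|rho| < 1`; 0 disables dependence.
#' @param seed Integer master seed (mandatory); all draws flow from it
#'   through named streams, so regeneration is bit-stable.
#' @return A `sim_config` list.
#' @export
sim_config <- function(rows = 20, cols = 20, spacing_km = 10,
                       n_covariates = 3, smoothing_radius = 2,
                       beta = 1, noise_sd = 0.2, gradient = 0.5,
                       rho = 0, seed) {
  if (missing(seed)) abort("sim_config() requires an explicit seed")
  if (rows < 1 || cols < 1 || rows * cols < 9) {
    abort("lattice must have at least 9 districts")
  }
  if (rows * cols > 2500) abort("lattice capped at 2500 districts")
  if (abs(rho) >= 1) abort("|rho| must be < 1")
  if (smoothing_radius < 0) abort("smoothing_radius must be >= 0")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 spacing_km = spacing_km,
                 n_covariates = as.integer(n_covariates),
                 smoothing_radius = as.integer(smoothing_radius),
                 beta = rep_len(beta, n_covariates),
                 noise_sd = noise_sd, gradient = gradient,
                 rho = rho, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate the lattice geography
#'
#' Places `rows * cols` districts on a regular grid: centroids at
#' `spacing_km` intervals, unit areas, log-normal populations (meanlog
#' 10, sdlog 0.5, a realistic district-scale spread around ~22,000) and
#' queen adjacency (any of the up to eight surrounding cells).
#'
#' @param cfg A [sim_config()].
#' @return A list with tibbles `districts` (`district_id`, `row`, `col`,
#'   `easting_km`, `northing_km`, `area_km2`, `population`) and
#'   `adjacency` (edge list, each unordered pair once).
#' @export
make_lattice <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- tidyr::expand_grid(row = seq_len(cfg$rows), col = seq_len(cfg$cols))
  n <- nrow(grid)
  pop <- with_stream_seed(cfg$seed, "population", rlnorm(n, 10, 0.5))
  districts <- grid |>
    dplyr::mutate(
      district_id = sprintf("d%04d", dplyr::row_number()),
      easting_km = (.data$col - 1) * cfg$spacing_km,
      northing_km = (.data$row - 1) * cfg$spacing_km,
      area_km2 = 1,
      population = pop) |>
    dplyr::relocate("district_id")
  # queen adjacency: Chebyshev distance 1 on the grid
  idx <- function(r, c) (r - 1L) * cfg$cols + c
  edges <- list()
  for (r in seq_len(cfg$rows)) {
    for (c in seq_len(cfg$cols)) {
      i <- idx(r, c)
      for (dr in -1:1) {
        for (dc in -1:1) {
          r2 <- r + dr; c2 <- c + dc
          if ((dr != 0 || dc != 0) && r2 >= 1 && r2 <= cfg$rows &&
              c2 >= 1 && c2 <= cfg$cols) {
            j <- idx(r2, c2)
            if (j > i) edges[[length(edges) + 1L]] <- c(i, j)
          }
        }
      }
    }
  }
  em <- do.call(rbind, edges)
  adjacency <- tibble::tibble(
    district_id_a = districts$district_id[em[, 1]],
    district_id_b = districts$district_id[em[, 2]])
  list(districts = districts, adjacency = adjacency)
}

#' Generate spatially clustered covariates
#'
#' Each covariate starts as an i.i.d. standard-normal field over the
#' lattice and is smoothed by a moving average over the Chebyshev
#' neighbourhood of radius `smoothing_radius` (radius 0 leaves it
#' i.i.d.), then tilted by `gradient` times the standardized northing.
#' Smoothing induces the spatial clustering channel; the tilt gives the
#' covariates — and hence the outcome — a north-south divide.
#'
#' @param geo A [make_lattice()] result.
#' @inheritParams make_lattice
#' @return A tibble `district_id`, `cov1` ... `covK`.
#' @export
make_clustered_covariates <- function(geo, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- geo$districts
  n <- nrow(d)
  r <- cfg$smoothing_radius
  north_std <- as.numeric(scale(d$northing_km))
  out <- tibble::tibble(district_id = d$district_id)
  for (j in seq_len(cfg$n_covariates)) {
    z <- with_stream_seed(cfg$seed, paste0("covariate", j), rnorm(n))
    x <- if (r > 0) {
      vapply(seq_len(n), function(i) {
        nb <- abs(d$row - d$row[i]) <= r & abs(d$col - d$col[i]) <= r
        mean(z[nb])
      }, numeric(1))
    } else {
      z
    }
    out[[paste0("cov", j)]] <- x + cfg$gradient * north_std
  }
  out
}

#' Generate the outcome
#'
#' With `rho = 0` the outcome is the linear signal plus i.i.d. noise,
#' `y = X beta + eps`. With `rho != 0` the outcome solves the
#' simultaneous autoregressive system `y = rho W y + X beta + eps`, i.e.
#' `y = (I - rho W)^{-1} (X beta + eps)`, with `W` the row-standardized
#' queen-contiguity weights — genuine spatial dependence that no set of
#' covariates can fully absorb.
#'
#' @param geo A [make_lattice()] result.
#' @param covariates A [make_clustered_covariates()] tibble.
#' @inheritParams make_lattice
#' @return A tibble `district_id`, `outcome`.
#' @export
make_outcome <- function(geo, covariates, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- geo$districts
  X <- as.matrix(covariates[paste0("cov", seq_len(cfg$n_covariates))])
  eta <- as.numeric(X %*% cfg$beta)
  eps <- with_stream_seed(cfg$seed, "outcome", rnorm(nrow(d), 0, cfg$noise_sd))
  y <- if (cfg$rho == 0) {
    eta + eps
  } else {
    w <- build_weights(d, "binary_contiguity", adjacency = geo$adjacency,
                       row_standardize = TRUE)
    A <- diag(nrow(d)) - cfg$rho * w$W
    if (abs(det(A)) < .Machine$double.eps) {
      abort("(I - rho W) is singular; cannot solve the autoregressive system")
    }
    as.numeric(solve(A, eta + eps))
  }
  tibble::tibble(district_id = d$district_id, outcome = y)
}

#' Generate per-district life tables from a Gompertz hazard
#'
#' Single-year conditional death probabilities follow a Gompertz
#' baseline hazard `a * exp(b * age)`, scaled per district by a frailty
#' factor: `qx(age) = 1 - exp(-frailty * H(age))` with `H` the hazard
#' integral over the year. Higher frailty strictly raises every `qx`
#' and hence premature mortality, so the link between a district's
#' frailty and its standardized outcome is monotone. The same schedule
#' is produced for both sexes, with the female hazard scaled by
#' `female_factor`.
#'
#' @param districts Geography tibble with `district_id`.
#' @param frailty Per-district positive frailty factors (recycled;
#'   default 1 everywhere, i.e. identical districts).
#' @param ages Integer vector of single-year interval starts (default
#'   `0:89`).
#' @param a,b Gompertz level and shape, both positive (defaults 5e-5 and
#'   0.09, a human-like schedule giving roughly 15% mortality by 70).
#' @param female_factor Multiplier on the female hazard (default 0.65).
#' @return A life-table tibble (`district_id`, `sex`, `age_start`,
#'   `age_end`, `qx`) accepted by [premature_mortality()].
#' @export
make_lifetables <- function(districts, frailty = 1, ages = 0:89,
                            a = 5e-5, b = 0.09, female_factor = 0.65) {
  if (a <= 0 || b <= 0) abort("Gompertz parameters a and b must be positive")
  if (any(frailty <= 0)) abort("frailty factors must be positive")
  ids <- as.character(districts$district_id)
  frailty <- rep_len(frailty, length(ids))
  H <- (a / b) * (exp(b * (ages + 1)) - exp(b * ages))
  purrr::map2(ids, frailty, function(id, f) {
    tidyr::expand_grid(sex = c("male", "female"), age_start = ages) |>
      dplyr::mutate(
        district_id = id,
        age_end = .data$age_start + 1L,
        qx = pmin(1, 1 - exp(-f * ifelse(.data$sex == "female",
                                         female_factor, 1) *
                               H[match(.data$age_start, ages)])))
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("district_id", "sex", "age_start", "age_end", "qx")
}

#' Simulate a complete input bundle with known ground truth
#'
#' One-stop generator: lattice geography, clustered covariates, outcome,
#' and life tables whose frailty is a monotone function of the outcome
#' (`frailty = exp(0.25 * standardized outcome)`), so the life-table
#' pipeline and the regression pipeline see the same spatial story.
#'
#' @inheritParams make_lattice
#' @return A list: `districts`, `adjacency`, `attributes` (covariates +
#'   `outcome` + `population`), `lifetables` and `truth` (`beta`, `rho`,
#'   `seed`, config echo).
#' @export
simulate_districts <- function(cfg) {
  geo <- make_lattice(cfg)
  covs <- make_clustered_covariates(geo, cfg)
  y <- make_outcome(geo, covs, cfg)
  frailty <- exp(0.25 * as.numeric(scale(y$outcome)))
  lts <- make_lifetables(geo$districts, frailty = frailty)
  attributes_tbl <- covs |>
    dplyr::left_join(y, by = "district_id") |>
    dplyr::left_join(dplyr::select(geo$districts, "district_id", "population"),
                     by = "district_id")
  list(districts = geo$districts, adjacency = geo$adjacency,
       attributes = attributes_tbl, lifetables = lts,
       truth = list(beta = cfg$beta, rho = cfg$rho, seed = cfg$seed,
                    config = unclass(cfg)))
}
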