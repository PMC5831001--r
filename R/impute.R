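#' Stochastic imputation of missing mean income
#'
#' Missing values of a covariate (in the Great Britain analysis, mean
#' district income) are replaced by the mean of `n_draws` stochastic
#' imputations. A single donor linear model is fitted on the complete
#' rows, regressing the incomplete column on the supplied donor
#' covariates; each imputation is the donor prediction plus residual
#' noise drawn from a normal with the donor fit's residual standard
#' deviation. Parameter uncertainty of the donor fit is not re-drawn.
#'
#' @param table District data frame.
#' @param column Name of the column with missing values (default
#'   `"mean_income"`).
#' @param donors Character vector of complete covariate columns used in
#'   the donor regression (for the Great Britain analysis: the remaining
#'   socioeconomic shares plus population density).
#' @param n_draws Number of stochastic imputations averaged per missing
#'   value (default 100).
#' @param seed Integer seed; required, so the completed column is fully
#'   reproducible.
#' @param noise If `FALSE`, draws are noiseless and the imputed value is
#'   the deterministic donor prediction.
#' @return The completed tibble, with a logical `<column>_imputed` flag
#'   column; the per-district imputation log (prediction, residual sd,
#'   draws used) is attached as attribute `"imputation_log"` and
#'   retrievable with [imputation_log()].
#' @export
impute_income <- function(table, column = "mean_income", donors,
                          n_draws = 100, seed, noise = TRUE) {
  assert_columns(table, c(column, donors), "table")
  if (missing(seed)) abort("impute_income() requires an explicit seed")
  v <- table[[column]]
  miss <- is.na(v)
  flag_col <- paste0(column, "_imputed")
  out <- dplyr::mutate(tibble::as_tibble(table), !!flag_col := miss)
  if (!any(miss)) {
    attr(out, "imputation_log") <- tibble::tibble(
      district_id = character(), prediction = numeric(),
      residual_sd = numeric(), imputed_value = numeric(),
      n_draws = integer())
    return(out)
  }
  if (all(miss)) abort(sprintf("all values of %s are missing; no donor rows", column))
  donor_rows <- table[!miss, , drop = FALSE]
  donor_fit <- fit_ols(donor_rows, column, covariates = donors)
  sigma <- quiet_perfect_fit(summary(donor_fit$fit)$sigma)
  if (!noise) sigma <- 0

  pred_df <- as.data.frame(table[miss, donors, drop = FALSE], check.names = FALSE)
  mu <- as.numeric(predict(donor_fit$fit, newdata = pred_df))

  imputed <- with_stream_seed(seed, "impute_income", {
    vapply(mu, function(m) mean(m + rnorm(n_draws, 0, sigma)), numeric(1))
  })
  v[miss] <- imputed
  out[[column]] <- v
  attr(out, "imputation_log") <- tibble::tibble(
    district_id = as.character(table$district_id[miss]),
    prediction = mu, residual_sd = sigma,
    imputed_value = imputed, n_draws = as.integer(n_draws))
  out
}

#' Retrieve the imputation log of a completed table
#' @param table A tibble returned by [impute_income()].
#' @return The log tibble (possibly zero rows).
#' @export
imputation_log <- function(table) {
  attr(table, "imputation_log") %||%
    tibble::tibble(district_id = character(), prediction = numeric(),
                   residual_sd = numeric(), imputed_value = numeric(),
                   n_draws = integer())
}

#' Exclude districts by name or population floor
#'
#' Drops districts whose small populations make their standardized
#' mortality unreliable — for Great Britain, the City of London and the
#' Isles of Scilly — and/or any district below a population floor. Each
#' drop is logged with its reason; naming a district that is not present
#' warns rather than errors.
#'
#' @param table District data frame with `district_id` (and `population`
#'   if a floor is used).
#' @param ids Character vector of district ids to drop.
#' @param min_population Drop districts with population strictly below
#'   this floor (default 0, i.e. none).
#' @return The filtered tibble; the exclusion log (district_id, reason)
#'   is attached as attribute `"exclusion_log"` and retrievable with
#'   [exclusion_log()].
#' @export
exclude_districts <- function(table, ids = character(), min_population = 0) {
  assert_columns(table, "district_id", "table")
  ids <- as.character(ids)
  absent <- setdiff(ids, as.character(table$district_id))
  if (length(absent) > 0L) {
    warn(sprintf("exclusion rule names absent district(s): %s",
                 paste(absent, collapse = ", ")))
  }
  named <- as.character(table$district_id) %in% ids
  low <- if (min_population > 0) {
    assert_columns(table, "population", "table")
    !is.na(table$population) & table$population < min_population
  } else {
    rep(FALSE, nrow(table))
  }
  log <- tibble::tibble(
    district_id = as.character(table$district_id[named | low]),
    reason = dplyr::case_when(
      named[named | low] ~ "named exclusion",
      .default = sprintf("population below floor %s", min_population)))
  out <- tibble::as_tibble(table)[!(named | low), , drop = FALSE]
  attr(out, "exclusion_log") <- log
  out
}

#' Retrieve the exclusion log of a filtered table
#' @param table A tibble returned by [exclude_districts()].
#' @return The log tibble (possibly zero rows).
#' @export
exclusion_log <- function(table) {
  attr(table, "exclusion_log") %||%
    tibble::tibble(district_id = character(), reason = character())
}
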