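#' Baseline residuals (step 1)
#'
#' The pattern-recognition procedure starts from a stripped-down baseline
#' model that excludes the covariates of theoretical interest. With an
#' entirely empty baseline the residuals are identical to the outcome
#' variable; otherwise they are the OLS residuals of the baseline fit.
#'
#' @inheritParams fit_ols
#' @param covariates Baseline covariate names; `character()` (the
#'   default) means the empty baseline. The special name `"(Intercept)"`
#'   requests an intercept-only baseline, whose residuals are deviations
#'   from the (weighted) mean.
#' @return A tibble with `district_id` and `residual`, in input row order.
#' @export
baseline_residuals <- function(data, outcome, covariates = character(),
                               weights = NULL, se_type = "HC1") {
  assert_columns(data, outcome, "data")
  ids <- if ("district_id" %in% names(data)) {
    as.character(data$district_id)
  } else {
    as.character(seq_len(nrow(data)))
  }
  if (length(covariates) == 0L) {
    return(tibble::tibble(district_id = ids,
                          residual = as.numeric(data[[outcome]])))
  }
  fit <- fit_ols(data, outcome, covariates = setdiff(covariates, "(Intercept)"),
                 weights = weights, se_type = se_type)
  tibble::tibble(district_id = ids, residual = unname(residuals(fit)))
}

#' Measure the strength of spatial patterns in a residual vector
#'
#' For each requested spatial dimension, fits one univariate OLS of the
#' residuals on an intercept plus that dimension's regressor and records
#' the slope with its heteroskedasticity-robust standard error — the
#' pattern's strength. The geography dimensions (northness, westness,
#' centrality, urbanity) use deterministic regressors; contiguity and
#' proximity use the spatial lag of the residual vector itself under,
#' respectively, row-standardized queen-contiguity and inverse-distance
#' weights, so the regressor is the average residual of neighbouring
#' districts. Districts with an undefined lag (no neighbours) are
#' dropped from that dimension's regression only. A zero-variance
#' regressor cannot identify a slope; the dimension is skipped with a
#' logged reason.
#'
#' @param residuals A tibble with `district_id` and `residual` (as
#'   returned by [baseline_residuals()]).
#' @param districts Geography data frame (see [spatial_regressors]).
#' @param dimensions Subset of `c("northness", "westness", "centrality",
#'   "contiguity", "proximity", "urbanity")`.
#' @param adjacency Edge list for the contiguity dimension.
#' @param centre Centre point for the centrality dimension.
#' @param lag_values Optional tibble (`district_id`, `value`) to lag for
#'   contiguity/proximity instead of the residual vector itself.
#' @param weights Optional per-district regression weights, aligned with
#'   `residuals` rows.
#' @param row_standardize Use row-standardized (neighbourhood-average)
#'   spatial weights; set `FALSE` for unstandardized sums.
#' @inheritParams fit_ols
#' @return A tibble with one row per measured dimension: `dimension`,
#'   `coefficient`, `robust_se`, `statistic`, `p.value`, `n`,
#'   `significant` (at 0.05 on the robust normal approximation) and
#'   `stars`. Skipped dimensions are recorded in attribute `"skipped"`.
#' @export
measure_patterns <- function(residuals, districts,
                             dimensions = spr_dimensions(),
                             adjacency = NULL, centre = NULL,
                             lag_values = NULL, weights = NULL,
                             row_standardize = TRUE, se_type = "HC1") {
  assert_columns(residuals, c("district_id", "residual"), "residuals")
  dimensions <- match.arg(dimensions, spr_dimensions(), several.ok = TRUE)
  districts <- dplyr::semi_join(tibble::as_tibble(districts),
                                residuals, by = "district_id")
  districts <- districts[match(residuals$district_id, districts$district_id), ]
  if (anyNA(districts$district_id)) {
    abort("geography is missing districts present in the residual vector")
  }

  lag_source <- if (is.null(lag_values)) {
    setNames(residuals$residual, residuals$district_id)
  } else {
    assert_columns(lag_values, c("district_id", "value"), "lag_values")
    setNames(lag_values$value, as.character(lag_values$district_id))
  }

  regressor <- function(dim) {
    switch(dim,
      northness = northness(districts)$northness,
      westness = westness(districts)$westness,
      centrality = centrality(districts, centre)$centrality,
      urbanity = urbanity(districts)$urbanity,
      contiguity = {
        if (is.null(adjacency)) abort("contiguity dimension requires an adjacency edge list")
        w <- build_weights(districts, "binary_contiguity", adjacency = adjacency,
                           row_standardize = row_standardize)
        spatial_lag(w, lag_source)$lag
      },
      proximity = {
        w <- build_weights(districts, "inverse_distance",
                           row_standardize = row_standardize)
        spatial_lag(w, lag_source)$lag
      })
  }

  rows <- list()
  skipped <- tibble::tibble(dimension = character(), reason = character())
  for (dim in dimensions) {
    x <- regressor(dim)
    keep <- !is.na(x)
    if (sum(keep) < 3L) {
      skipped <- dplyr::add_row(skipped, dimension = dim,
                                reason = "fewer than 3 usable districts")
      inform(sprintf("skipping dimension '%s': fewer than 3 usable districts", dim))
      next
    }
    if (isTRUE(all.equal(var(x[keep]), 0)) || var(x[keep]) == 0) {
      skipped <- dplyr::add_row(skipped, dimension = dim,
                                reason = "zero-variance regressor")
      inform(sprintf("skipping dimension '%s': zero-variance regressor", dim))
      next
    }
    d <- tibble::tibble(residual = residuals$residual[keep],
                        .regressor = x[keep])
    fit <- fit_ols(d, "residual", covariates = ".regressor",
                   weights = if (!is.null(weights)) weights[keep],
                   se_type = se_type)
    tt <- tidy(fit)
    slope <- tt[tt$term == ".regressor", ]
    rows[[dim]] <- tibble::tibble(
      dimension = dim,
      coefficient = slope$estimate,
      robust_se = slope$std.error,
      statistic = slope$statistic,
      p.value = slope$p.value,
      n = sum(keep),
      significant = slope$p.value < 0.05,
      stars = slope$stars)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' The six measurable spatial dimensions
#' @return Character vector of dimension names.
#' @export
spr_dimensions <- function() {
  c("northness", "westness", "centrality", "contiguity", "proximity", "urbanity")
}

#' Percent decline of a spatial pattern (step 5)
#'
#' `100 * (1 - enriched / baseline)`: how much of a pattern's baseline
#' strength the covariate-enriched model accounts for. The statistic can
#' exceed 100% when the enriched slope flips sign, and is invariant to
#' any common positive rescaling of the outcome or of the dimension's
#' regressor. Baselines with absolute value at or below `guard` leave
#' the ratio undefined; those entries return `NA` with a warning.
#'
#' @param baseline,enriched Numeric vectors of pattern slopes (recycled
#'   to common length).
#' @param guard Magnitude guard on the baseline (default `1e-12`; scale
#'   it with the outcome if the outcome's unit is far from 1).
#' @return Numeric vector of percent declines.
#' @examples
#' decline(0.0078, 0.0005)  # 93.6 after 1-dp rounding
#' decline(1.9100, -0.0562) # sign flip: exceeds 100
#' @export
decline <- function(baseline, enriched, guard = 1e-12) {
  stopifnot(is.numeric(baseline), is.numeric(enriched), guard >= 0)
  n <- max(length(baseline), length(enriched))
  baseline <- rep_len(baseline, n)
  enriched <- rep_len(enriched, n)
  undef <- is.na(baseline) | abs(baseline) <= guard
  if (any(undef)) {
    warn(sprintf("%d baseline coefficient(s) within the magnitude guard; decline undefined there",
                 sum(undef)))
  }
  out <- 100 * (1 - enriched / baseline)
  out[undef] <- NA_real_
  out
}

#' Replay declines from an already-estimated coefficient table
#'
#' Consumes a table of baseline/enriched pattern slopes (for example a
#' transcribed published table) and computes the decline column, without
#' re-estimating anything.
#'
#' @param coefficients A data frame with columns `dimension`,
#'   `baseline_coefficient`, `enriched_coefficient` and optionally `sex`
#'   or other grouping columns, which are carried through.
#' @inheritParams decline
#' @return The input tibble plus `decline` (full precision) and
#'   `decline_rounded` (one decimal of a percent, the conventional
#'   reporting precision).
#' @export
replay_declines <- function(coefficients, guard = 1e-12) {
  assert_columns(coefficients,
                 c("dimension", "baseline_coefficient", "enriched_coefficient"),
                 "coefficients")
  coefficients |>
    tibble::as_tibble() |>
    dplyr::mutate(
      decline = decline(.data$baseline_coefficient,
                        .data$enriched_coefficient, guard = guard),
      decline_rounded = round(.data$decline, 1))
}

#' Run the five-step spatial pattern recognition procedure
#'
#' Executes, separately for each group (typically sex): (1) baseline
#' residuals from a stripped-down model — identical to the outcome when
#' the baseline is empty; (2) univariate pattern regressions of those
#' residuals on each spatial dimension; (3) the covariate-enriched OLS
#' fit; (4) the same pattern regressions on the enriched residuals, with
#' contiguity/proximity lags recomputed from the enriched residual
#' vector; (5) the percent decline of each pattern. Options reproduce the
#' usual robustness variants: a subset of districts (weights matrices are
#' rebuilt within the subset, so lags never borrow information across its
#' border), population-weighted estimation, and exclusion of outliers
#' flagged on the enriched fit (both passes are then re-run on the
#' retained set).
#'
#' @param data District attribute data frame: `district_id`, the outcome
#'   column, covariate columns, optionally a grouping column (`by`) and
#'   `population`.
#' @param districts Geography data frame (`district_id`, `easting_km`,
#'   `northing_km`, `area_km2`, `population`).
#' @param outcome Name of the outcome column (e.g. premature mortality).
#' @param covariates Covariate names for the enriched model, or an
#'   [spr_block] list (flattened in declared order, references omitted).
#' @param baseline_covariates Covariates of the baseline model; empty by
#'   default (empty baseline: residuals = outcome).
#' @param by Optional grouping column name (e.g. `"sex"`); the whole
#'   procedure runs independently within each group.
#' @param subset_ids Optional district ids restricting the analysis.
#' @param population_weights Weight all regressions by district
#'   population (from `districts`).
#' @param exclude_outliers Drop districts flagged by [flag_outliers()] on
#'   the enriched fit, then re-run both passes.
#' @param outlier_cutoff Studentized-residual cutoff (default 2.5).
#' @param lag_of `"residuals"` (default) lags the enriched residual
#'   vector in step 4; `"outcome"` lags the observed outcome instead.
#' @param guard Decline magnitude guard, see [decline()].
#' @inheritParams measure_patterns
#' @return An `spr_report`: a tibble with one row per dimension and
#'   group holding baseline and enriched coefficients, robust SEs,
#'   significance, n and the decline; fits and options are attached and
#'   available through [glance()], [report_table()] and [autoplot()].
#' @export
run_spr <- function(data, districts, outcome, covariates,
                    baseline_covariates = character(),
                    dimensions = spr_dimensions(),
                    adjacency = NULL, centre = NULL, by = NULL,
                    subset_ids = NULL, population_weights = FALSE,
                    exclude_outliers = FALSE, outlier_cutoff = 2.5,
                    row_standardize = TRUE, se_type = "HC1",
                    lag_of = c("residuals", "outcome"), guard = 1e-12) {
  lag_of <- match.arg(lag_of)
  assert_columns(data, c("district_id", outcome), "data")
  assert_columns(districts, "district_id", "districts")
  if (inherits(covariates, "spr_block") ||
      (is.list(covariates) && all(vapply(covariates, inherits, TRUE, "spr_block")))) {
    if (inherits(covariates, "spr_block")) covariates <- list(covariates)
    covariates <- unlist(lapply(covariates,
                                function(b) setdiff(b$columns, b$reference)))
  }
  data <- tibble::as_tibble(data)
  districts <- tibble::as_tibble(districts)
  groups <- if (is.null(by)) {
    list(all = data)
  } else {
    assert_columns(data, by, "data")
    split(data, data[[by]])
  }

  run_group <- function(g, label) {
    if (!is.null(subset_ids)) {
      g <- dplyr::filter(g, .data$district_id %in% subset_ids)
    }
    assert_unique_ids(g$district_id,
                      sprintf("district_id (group %s)", label))
    geo <- districts[match(g$district_id, districts$district_id), ]
    if (anyNA(geo$district_id)) {
      missing <- setdiff(g$district_id, districts$district_id)
      abort(sprintf("geography missing for district(s): %s",
                    paste(head(missing, 5L), collapse = ", ")))
    }
    adj <- if (!is.null(adjacency)) {
      dplyr::filter(adjacency,
                    .data$district_id_a %in% g$district_id,
                    .data$district_id_b %in% g$district_id)
    }
    w <- if (population_weights) as.numeric(geo$population)

    pass <- function(g, geo, adj, w) {
      enriched_fit <- fit_ols(g, outcome, covariates = covariates,
                              weights = w, se_type = se_type)
      base_res <- baseline_residuals(g, outcome,
                                     covariates = baseline_covariates,
                                     weights = w, se_type = se_type)
      base_fit <- if (length(baseline_covariates) > 0L) {
        fit_ols(g, outcome,
                covariates = setdiff(baseline_covariates, "(Intercept)"),
                weights = w, se_type = se_type)
      }
      enr_res <- tibble::tibble(district_id = as.character(g$district_id),
                                residual = unname(residuals(enriched_fit)))
      lag_vals <- if (lag_of == "outcome") {
        tibble::tibble(district_id = as.character(g$district_id),
                       value = as.numeric(g[[outcome]]))
      }
      base_pat <- measure_patterns(base_res, geo, dimensions,
                                   adjacency = adj, centre = centre,
                                   weights = w,
                                   row_standardize = row_standardize,
                                   se_type = se_type)
      enr_pat <- measure_patterns(enr_res, geo, dimensions,
                                  adjacency = adj, centre = centre,
                                  lag_values = lag_vals, weights = w,
                                  row_standardize = row_standardize,
                                  se_type = se_type)
      list(enriched_fit = enriched_fit, base_fit = base_fit,
           base_pat = base_pat, enr_pat = enr_pat,
           base_res = base_res, enr_res = enr_res)
    }

    p <- pass(g, geo, adj, w)
    dropped <- tibble::tibble(district_id = character())
    if (exclude_outliers) {
      flags <- flag_outliers(p$enriched_fit, cutoff = outlier_cutoff)
      if (any(flags$outlier)) {
        dropped <- dplyr::filter(flags, .data$outlier)["district_id"]
        keep <- !flags$outlier
        g <- g[keep, ]
        geo <- geo[keep, ]
        if (!is.null(adj)) {
          adj <- dplyr::filter(adj,
                               .data$district_id_a %in% g$district_id,
                               .data$district_id_b %in% g$district_id)
        }
        if (!is.null(w)) w <- w[keep]
        p <- pass(g, geo, adj, w)
      }
    }

    strengths <- dplyr::full_join(
      dplyr::rename_with(p$base_pat, ~paste0("baseline_", .x), -"dimension"),
      dplyr::rename_with(p$enr_pat, ~paste0("enriched_", .x), -"dimension"),
      by = "dimension") |>
      dplyr::mutate(
        group = label,
        decline = {
          d <- rep(NA_real_, dplyr::n())
          ok <- !is.na(.data$baseline_coefficient) &
            abs(.data$baseline_coefficient) > guard &
            !is.na(.data$enriched_coefficient)
          d[ok] <- 100 * (1 - .data$enriched_coefficient[ok] /
                            .data$baseline_coefficient[ok])
          d
        },
        .before = 1)
    list(strengths = strengths, fits = list(
      enriched = p$enriched_fit, baseline = p$base_fit,
      enriched_residuals = p$enr_res, baseline_residuals = p$base_res,
      dropped_outliers = dropped))
  }

  runs <- purrr::imap(groups, run_group)
  report <- purrr::map(runs, "strengths") |>
    dplyr::bind_rows() |>
    dplyr::relocate("group", "dimension", "baseline_coefficient",
                    "baseline_robust_se", "enriched_coefficient",
                    "enriched_robust_se", "decline")
  structure(report,
            class = c("spr_report", class(report)),
            fits = purrr::map(runs, "fits"),
            options = list(outcome = outcome,
                           covariates = covariates,
                           baseline_covariates = baseline_covariates,
                           dimensions = dimensions, by = by,
                           subset_ids = subset_ids,
                           population_weights = population_weights,
                           exclude_outliers = exclude_outliers,
                           outlier_cutoff = outlier_cutoff,
                           row_standardize = row_standardize,
                           se_type = se_type, lag_of = lag_of,
                           guard = guard))
}

#' Rank districts by unexplained residual
#'
#' Orders districts by the residual of the enriched fit — the outcome
#' variation the covariates leave unexplained — largest excess first.
#' Both tails are reported; exactly-zero residuals carry no excess and
#' are omitted.
#'
#' @param fit An [fit_ols()] object (typically the enriched fit, pulled
#'   from a report via `attr(report, "fits")`).
#' @param scale Multiplier applied to residuals before ranking (e.g.
#'   convert a per-100,000 outcome to percentage points with `1e-3`).
#' @param tol Residuals with absolute value at or below `tol` are
#'   treated as exactly zero.
#' @return A tibble `district_id`, `residual`, `tail`
#'   (`"excess"`/`"deficit"`), `rank` (1 = largest excess).
#' @export
rank_residual_excess <- function(fit, scale = 1, tol = 1e-12) {
  stopifnot(inherits(fit, "spr_fit"))
  r <- residuals(fit) * scale
  out <- tibble::tibble(district_id = names(r), residual = as.numeric(r)) |>
    dplyr::filter(abs(.data$residual) > tol) |>
    dplyr::arrange(dplyr::desc(.data$residual)) |>
    dplyr::mutate(tail = ifelse(.data$residual > 0, "excess", "deficit"),
                  rank = dplyr::row_number())
  out
}

#' @export
print.spr_report <- function(x, ...) {
  cat("<spr_report> spatial pattern declines\n")
  print(report_table(x), n = Inf)
  invisible(x)
}

#' Reporting table of a pattern report
#'
#' Wide layout with one row per dimension and, per group, the observed
#' (baseline-residual) slope, the enriched-residual slope and the
#' decline, at conventional reporting precision (4 decimals for slopes,
#' 1 decimal of a percent for declines). Use [tidy()] for full precision.
#'
#' @param report An [run_spr()] report.
#' @return A tibble.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "spr_report"))
  tibble::as_tibble(report) |>
    dplyr::transmute(
      .data$dimension, .data$group,
      observed = round(.data$baseline_coefficient, 4),
      residual = round(.data$enriched_coefficient, 4),
      decline = round(.data$decline, 1)) |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("observed", "residual", "decline"),
                       names_glue = "{.value}_{group}")
}

#' @describeIn run_spr Long-format report rows as a plain tibble.
#' @param x,object An `spr_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.spr_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @describeIn run_spr One row per group summarising the enriched fit
#'   (adjusted R-squared, n, terms) and the sum-of-squares reduction
#'   from baseline to enriched residuals.
#' @exportS3Method generics::glance
glance.spr_report <- function(x, ...) {
  fits <- attr(x, "fits")
  purrr::imap(fits, function(f, g) {
    gl <- glance(f$enriched)
    ss_base <- sum(f$baseline_residuals$residual^2)
    ss_enr <- sum(f$enriched_residuals$residual^2)
    tibble::tibble(group = g, nobs = gl$nobs,
                   adj.r.squared = gl$adj.r.squared,
                   r.squared = gl$r.squared,
                   ss_baseline = ss_base, ss_enriched = ss_enr,
                   n_outliers_dropped = nrow(f$dropped_outliers))
  }) |>
    dplyr::bind_rows()
}

#' @describeIn run_spr Bar chart of declines by dimension and group.
#' @exportS3Method ggplot2::autoplot
autoplot.spr_report <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$dimension, .data$decline,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "decline of spatial pattern (%)",
                  fill = NULL) +
    ggplot2::coord_flip()
}
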