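#' Ordinary least squares with heteroskedasticity-robust standard errors
#'
#' Fits the district-level linear model by (optionally
#' population-weighted) OLS and attaches a sandwich-form
#' heteroskedasticity-consistent covariance for inference. The default
#' flavour is HC1, the small-sample scaled sandwich
#' \eqn{(X'X)^{-1} X' \mathrm{diag}(e^2) X (X'X)^{-1} \cdot n/(n-k)}
#' common in applied econometrics; HC0-HC3 are selectable. Coefficient
#' point estimates and residuals do not depend on the flavour.
#'
#' @param data District data frame; must contain `outcome` and any
#'   covariate columns, and usually `district_id`.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names
#'   (intercept always added), or `NULL` with `design` supplied.
#' @param design An [build_design()] `spr_design` object; overrides
#'   `covariates`.
#' @param weights Optional non-negative per-district weights (e.g.
#'   population), aligned with `data` rows.
#' @param se_type One of `"HC0"`, `"HC1"`, `"HC2"`, `"HC3"`.
#' @return An `spr_fit` object; use [tidy()] for the coefficient table,
#'   [glance()] for fit statistics, `residuals()` for per-district
#'   residuals in input order.
#' @examples
#' d <- tibble::tibble(district_id = letters[1:3], y = c(0, 1, 2), x = c(0, 1, 2))
#' tidy(fit_ols(d, "y", "x"))
#' @export
fit_ols <- function(data, outcome, covariates = NULL, design = NULL,
                    weights = NULL, se_type = c("HC1", "HC0", "HC2", "HC3")) {
  se_type <- match.arg(se_type)
  assert_columns(data, outcome, "data")
  y <- as.numeric(data[[outcome]])
  if (!is.null(design)) {
    stopifnot(inherits(design, "spr_design"))
    X <- design$X
  } else {
    covariates <- covariates %||% character()
    assert_columns(data, covariates, "data")
    X <- cbind(`(Intercept)` = rep(1, nrow(data)))
    for (cn in covariates) X <- cbind(X, as.numeric(data[[cn]]))
    colnames(X) <- c("(Intercept)", covariates)
  }
  n <- length(y)
  k <- ncol(X)
  if (n <= k) {
    abort(sprintf("n = %d observations cannot identify %d coefficients", n, k))
  }
  qx <- qr(X)
  if (qx$rank < k) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1):k]]
    abort(sprintf("design is rank deficient; linearly dependent column(s): %s",
                  paste(dep, collapse = ", ")))
  }
  if (!is.null(weights)) {
    if (length(weights) != n) abort("weights length must match rows of data")
    if (any(weights < 0)) abort("weights must be non-negative")
  }

  df <- as.data.frame(X[, -1, drop = FALSE], check.names = FALSE)
  df[[".outcome"]] <- y
  fml <- if (ncol(X) > 1L) {
    reformulate(sprintf("`%s`", colnames(X)[-1]), response = ".outcome")
  } else {
    .outcome ~ 1
  }
  df[[".w"]] <- weights %||% rep(1, n)
  fit <- lm(fml, data = df, weights = .w)
  vc <- quiet_perfect_fit(sandwich::vcovHC(fit, type = se_type))

  structure(list(
    fit = fit,
    vcov = vc,
    se_type = se_type,
    terms = colnames(X),
    n = n, k = k,
    weighted = !is.null(weights),
    district_id = if ("district_id" %in% names(data)) {
      as.character(data$district_id)
    } else {
      as.character(seq_len(n))
    }), class = "spr_fit")
}

#' @export
residuals.spr_fit <- function(object, ...) {
  setNames(as.numeric(resid(object$fit)), object$district_id)
}

#' @export
coef.spr_fit <- function(object, ...) {
  setNames(as.numeric(coef(object$fit)), object$terms)
}

#' Robust standard errors of an `spr_fit`
#' @param fit An [fit_ols()] object.
#' @return Named numeric vector of sandwich standard errors.
#' @export
robust_se <- function(fit) {
  stopifnot(inherits(fit, "spr_fit"))
  setNames(sqrt(diag(fit$vcov)), fit$terms)
}

#' @export
print.spr_fit <- function(x, ...) {
  cat(sprintf("<spr_fit> n = %d, %d terms, %s robust SEs%s\n",
              x$n, x$k, x$se_type, if (x$weighted) ", weighted" else ""))
  print(tidy(x), n = min(x$k, 10))
  invisible(x)
}

#' @describeIn fit_ols Coefficients with robust standard errors; stars
#'   use a two-sided normal approximation at the 0.05 (`*`) and 0.01
#'   (`**`) levels.
#' @param x,object An `spr_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.spr_fit <- function(x, ...) {
  est <- coef(x)
  se <- robust_se(x)
  z <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(term = x$terms, estimate = as.numeric(est),
                 std.error = as.numeric(se), statistic = as.numeric(z),
                 p.value = as.numeric(p), stars = stars_from_p(p))
}

#' @describeIn fit_ols One-row fit summary (R-squared, adjusted
#'   R-squared, residual sigma, n, number of terms, SE flavour).
#' @exportS3Method generics::glance
glance.spr_fit <- function(x, ...) {
  s <- quiet_perfect_fit(summary(x$fit))
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, nobs = x$n, df = x$k, se_type = x$se_type,
                 weighted = x$weighted)
}

#' @describeIn fit_ols Residual-versus-fitted diagnostic plot.
#' @exportS3Method ggplot2::autoplot
autoplot.spr_fit <- function(object, ...) {
  d <- tibble::tibble(fitted = as.numeric(stats::fitted(object$fit)),
                      residual = as.numeric(resid(object$fit)))
  ggplot2::ggplot(d, ggplot2::aes(.data$fitted, .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fitted value", y = "residual")
}

#' Flag outlying districts of a fit
#'
#' Default rule: a district is an outlier when the absolute externally
#' studentized residual exceeds `cutoff` (default 2.5). Districts whose
#' studentized residual is undefined (an exact-fit model leaves nothing
#' to studentize) are never flagged.
#'
#' @param fit An [fit_ols()] object.
#' @param cutoff Positive threshold; `Inf` flags nothing.
#' @return A tibble with `district_id`, `studentized` and logical
#'   `outlier`.
#' @export
flag_outliers <- function(fit, cutoff = 2.5) {
  stopifnot(inherits(fit, "spr_fit"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0) {
    abort("cutoff must be a positive number")
  }
  rs <- suppressWarnings(rstudent(fit$fit))
  # exact fits leave only floating-point dust: nothing to studentize
  e <- as.numeric(resid(fit$fit))
  tiny <- abs(e) <= 1e-10 * max(abs(as.numeric(stats::fitted(fit$fit))), 1)
  rs[!is.finite(rs) | tiny] <- 0
  tibble::tibble(district_id = fit$district_id,
                 studentized = as.numeric(rs),
                 outlier = abs(rs) > cutoff)
}
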