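# internal helpers shared across modules

# Deterministic per-purpose seed derived from one master seed, so every
# stochastic stage (populations, each covariate field, outcome noise,
# imputation draws) has its own named stream and regeneration is bit-stable.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  expr
}

# two-sided normal-approximation stars on robust t-ratios:
# "**" at the 0.01 level, "*" at 0.05
stars_from_p <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", .default = "")
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_unique_ids <- function(ids, what = "district_id") {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate %s value(s): %s", what,
                  paste(head(dup, 5L), collapse = ", ")))
  }
  invisible(ids)
}

# summary.lm warns on exact fits ("essentially perfect fit"); degenerate
# fixtures hit this legitimately, so muffle just that warning
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
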