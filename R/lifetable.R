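#' Validate a life table
#'
#' A life table is a tibble with one row per age interval for each
#' district and sex, giving the conditional probability `qx` of dying
#' before the end of the interval for someone alive at its start.
#' Intervals must be contiguous, non-overlapping, strictly increasing and
#' start at age 0; every `qx` must lie in \[0, 1\].
#'
#' @param lt A data frame with columns `district_id`, `sex`, `age_start`,
#'   `age_end`, `qx`.
#' @return The input, invisibly, if valid; otherwise an error naming the
#'   offending district/sex/interval.
#' @export
validate_lifetable <- function(lt) {
  assert_columns(lt, c("district_id", "sex", "age_start", "age_end", "qx"),
                 "life table")
  bad_sex <- setdiff(unique(lt$sex), c("male", "female"))
  if (length(bad_sex) > 0L) {
    abort(sprintf("sex must be 'male' or 'female'; found: %s",
                  paste(bad_sex, collapse = ", ")))
  }
  check_group <- function(g) {
    g <- dplyr::arrange(g, .data$age_start)
    lab <- sprintf("district %s, sex %s", g$district_id[1], g$sex[1])
    if (g$age_start[1] != 0) {
      abort(sprintf("%s: intervals must start at age 0 (first starts at %s)",
                    lab, g$age_start[1]))
    }
    if (any(g$age_end <= g$age_start)) {
      i <- which(g$age_end <= g$age_start)[1]
      abort(sprintf("%s: interval [%s, %s) is not strictly increasing",
                    lab, g$age_start[i], g$age_end[i]))
    }
    if (nrow(g) > 1L && any(g$age_start[-1] != g$age_end[-nrow(g)])) {
      i <- which(g$age_start[-1] != g$age_end[-nrow(g)])[1]
      abort(sprintf("%s: gap or overlap between interval ending %s and interval starting %s",
                    lab, g$age_end[i], g$age_start[i + 1]))
    }
    if (any(is.na(g$qx) | g$qx < 0 | g$qx > 1)) {
      i <- which(is.na(g$qx) | g$qx < 0 | g$qx > 1)[1]
      abort(sprintf("%s: qx = %s on interval [%s, %s) is outside [0, 1]",
                    lab, g$qx[i], g$age_start[i], g$age_end[i]))
    }
    g
  }
  lt |>
    dplyr::group_by(.data$district_id, .data$sex) |>
    dplyr::group_walk(~check_group(.x), .keep = TRUE)
  invisible(lt)
}

#' Survivorship of an artificial cohort
#'
#' Runs a standardized artificial cohort through the age-specific death
#' probabilities of each district and sex: `s_0 = cohort_size` and
#' `s_{k+1} = s_k * (1 - qx_k)`. Fractional survivors are retained; no
#' rounding is applied at any step.
#'
#' @inheritParams validate_lifetable
#' @param cohort_size Size of the artificial cohort (default 100,000).
#' @return A tibble with columns `district_id`, `sex`, `age` (interval
#'   boundaries, starting at 0) and `survivors`; one row per boundary, so
#'   each district/sex contributes one more row than it has intervals.
#' @examples
#' lt <- tibble::tibble(district_id = "A", sex = "male",
#'                      age_start = 0:69, age_end = 1:70, qx = 0.01)
#' tail(cohort_survival(lt), 1)  # 100000 * 0.99^70
#' @export
cohort_survival <- function(lt, cohort_size = 100000) {
  validate_lifetable(lt)
  stopifnot(is.numeric(cohort_size), cohort_size >= 0)
  lt |>
    dplyr::group_by(.data$district_id, .data$sex) |>
    dplyr::arrange(.data$age_start, .by_group = TRUE) |>
    dplyr::reframe(age = c(.data$age_start[1], .data$age_end),
                   survivors = cohort_size * cumprod(c(1, 1 - .data$qx)))
}

#' Premature mortality of a standardized cohort
#'
#' Number of members of an artificial cohort who die before a threshold
#' age, computed from the life-table survivorship curve. Because the
#' cohort is standardized, two districts with identical `qx` schedules get
#' identical values regardless of their real population age structure.
#'
#' @inheritParams cohort_survival
#' @param threshold_age Age below which a death counts as premature
#'   (default 70; 60 and 75 are common robustness choices). Must coincide
#'   with an interval boundary of every life table; no within-interval
#'   interpolation is performed.
#' @return A tibble with columns `district_id`, `sex`,
#'   `premature_mortality` (deaths before `threshold_age` per
#'   `cohort_size`) and `threshold_age`.
#' @export
premature_mortality <- function(lt, threshold_age = 70, cohort_size = 100000) {
  surv <- cohort_survival(lt, cohort_size = cohort_size)
  out <- surv |>
    dplyr::group_by(.data$district_id, .data$sex) |>
    dplyr::summarise(
      premature_mortality = {
        hit <- which(.data$age == threshold_age)
        if (length(hit) == 0L) {
          abort(sprintf(
            paste0("threshold_age %s is not an interval boundary for district %s, sex %s; ",
                   "supply single-year tables or a threshold on a boundary ",
                   "(no interpolation is performed)"),
            threshold_age, dplyr::cur_group()$district_id, dplyr::cur_group()$sex))
        }
        cohort_size - .data$survivors[hit]
      },
      .groups = "drop") |>
    dplyr::mutate(threshold_age = threshold_age)
  out
}
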