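#' Define a covariate block
#'
#' Socioeconomic covariates enter the enriched model in blocks. A
#' compositional block is a set of shares that (with its reference
#' category) exhausts the district population — e.g. highest educational
#' qualification broken into five categories. The reference category is
#' omitted from the design to avoid exact collinearity with the
#' intercept; the remaining categories enter in the declared order.
#'
#' @param name Block name.
#' @param columns Character vector of column names, in design order. For
#'   a compositional block this lists every category including the
#'   reference.
#' @param reference Name of the omitted reference category (must be one
#'   of `columns`), or `NULL` for a non-compositional block.
#' @param compositional Is the block an exhaustive share decomposition?
#'   Defaults to `TRUE` when a reference is given.
#' @return An `spr_block` list.
#' @export
spr_block <- function(name, columns, reference = NULL,
                      compositional = !is.null(reference)) {
  stopifnot(is.character(name), is.character(columns), length(columns) > 0L)
  if (!is.null(reference) && !reference %in% columns) {
    abort(sprintf("block '%s': reference category '%s' is not among its columns",
                  name, reference))
  }
  structure(list(name = name, columns = columns, reference = reference,
                 compositional = compositional),
            class = "spr_block")
}

#' Great Britain covariate block specification
#'
#' The five socioeconomic blocks used for the Great Britain analysis:
#' income and poverty (mean income, benefit-claimant share), highest
#' educational qualification (5 categories), employment by economic
#' sector (18 categories), socioeconomic status (8 categories) and ethnic
#' composition (5 categories). Reference categories — entry-level
#' qualification, other sector, not working and other ethnicity — are
#' omitted, so the full design holds 2 + 4 + 17 + 7 + 4 = 34 covariate
#' columns plus the intercept.
#'
#' @return A named list of [spr_block] objects.
#' @export
gb_blocks <- function() {
  list(
    income_poverty = spr_block(
      "income_poverty", c("mean_income", "benefit_claimants")),
    education = spr_block(
      "education",
      c("entry_level", "gcse_dg", "gcse_ac", "a_level", "higher_education"),
      reference = "entry_level"),
    sector = spr_block(
      "sector",
      c("agriculture", "mining", "manufacturing", "gas_electricity", "water",
        "construction", "retail", "transport", "hospitality",
        "information_technology", "finance", "real_estate",
        "academic_science", "administration", "public_administration",
        "education_sector", "health", "other_sector"),
      reference = "other_sector"),
    status = spr_block(
      "status",
      c("higher_managerial", "lower_managerial", "intermediate_occupations",
        "small_employers", "lower_supervisory", "semi_routine",
        "routine", "not_working"),
      reference = "not_working"),
    ethnicity = spr_block(
      "ethnicity",
      c("mixed", "asian", "black", "white", "other_ethnicity"),
      reference = "other_ethnicity"))
}

#' Build a regression design matrix from covariate blocks
#'
#' Assembles an intercept column plus each selected block's
#' non-reference categories, in block order then declared category
#' order, so the column layout is deterministic. A compositional block
#' without an omitted reference would be exactly collinear with the
#' intercept; this is refused before any fitting.
#'
#' @param table District attribute data frame containing the block
#'   columns (shares on a 0-100 scale for compositional blocks).
#' @param blocks A list of [spr_block] objects (default: none, giving an
#'   intercept-only design).
#' @return An `spr_design` list: `X` (numeric matrix, first column the
#'   intercept), `terms` (column names) and `blocks`.
#' @export
build_design <- function(table, blocks = list()) {
  if (inherits(blocks, "spr_block")) blocks <- list(blocks)
  terms <- "(Intercept)"
  cols <- list(rep(1, nrow(table)))
  for (b in blocks) {
    stopifnot(inherits(b, "spr_block"))
    if (b$compositional && is.null(b$reference)) {
      abort(sprintf(
        "block '%s' is compositional but omits no reference category; its shares sum to a constant and the design would be collinear",
        b$name))
    }
    use <- setdiff(b$columns, b$reference)
    assert_columns(table, use, sprintf("block '%s'", b$name))
    for (cn in use) {
      terms <- c(terms, cn)
      cols[[length(cols) + 1L]] <- as.numeric(table[[cn]])
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  structure(list(X = X, terms = terms, blocks = blocks), class = "spr_design")
}

#' Validate district attribute shares against a block specification
#'
#' Checks that every compositional block's shares lie in \[0, 100\] and
#' that the shares present for one district sum to at most 100 (plus
#' tolerance) — the omitted reference category absorbs the remainder.
#'
#' @inheritParams build_design
#' @param tolerance Slack on the 100% row-sum bound (default 0.5, in
#'   percentage points, allowing for published rounding).
#' @return The input, invisibly, if valid.
#' @export
validate_district_table <- function(table, blocks, tolerance = 0.5) {
  if (inherits(blocks, "spr_block")) blocks <- list(blocks)
  for (b in blocks) {
    if (!b$compositional) next
    present <- intersect(b$columns, names(table))
    for (cn in present) {
      v <- table[[cn]]
      ok <- is.na(v) | (v >= 0 & v <= 100)
      if (!all(ok)) {
        abort(sprintf("block '%s': column %s has share(s) outside [0, 100]",
                      b$name, cn))
      }
    }
    rs <- rowSums(as.matrix(table[present]), na.rm = TRUE)
    if (any(rs > 100 + tolerance)) {
      i <- which(rs > 100 + tolerance)[1]
      abort(sprintf("block '%s': shares for district %s sum to %.2f > 100",
                    b$name, table$district_id[i], rs[i]))
    }
  }
  invisible(table)
}
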