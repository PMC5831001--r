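#' Build a spatial weights matrix
#'
#' Constructs district-by-district spatial weights under one of two
#' schemes: `binary_contiguity` (w_ij = 1 iff districts i and j are
#' physically adjacent) or `inverse_distance` (w_ij = 1 / d_ij, the
#' inverse of the Euclidean distance between centroids, with no distance
#' cutoff). Row standardization rescales each non-empty row to sum to 1,
#' so the spatial lag becomes a neighbourhood average; rows of districts
#' with no neighbours stay all-zero and are flagged as islands.
#'
#' @param districts A data frame with columns `district_id`, `easting_km`,
#'   `northing_km` (projected centroid coordinates in kilometres).
#' @param scheme `"binary_contiguity"` or `"inverse_distance"`.
#' @param adjacency For the binary scheme, an edge list: a data frame with
#'   columns `district_id_a`, `district_id_b`, each unordered adjacent
#'   pair listed once. Ignored for inverse distance.
#' @param row_standardize Rescale rows to sum to one (default `TRUE`).
#' @return An object of class `spr_weights`: the ordered district ids, the
#'   n-by-n weight matrix, the scheme, the standardization state and any
#'   island ids.
#' @examples
#' d <- tibble::tibble(district_id = c("A", "B", "C"),
#'                     easting_km = c(0, 1, 2), northing_km = 0)
#' e <- tibble::tibble(district_id_a = c("A", "B"), district_id_b = c("B", "C"))
#' build_weights(d, "binary_contiguity", adjacency = e)$W
#' @export
build_weights <- function(districts,
                          scheme = c("binary_contiguity", "inverse_distance"),
                          adjacency = NULL,
                          row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  assert_columns(districts, "district_id", "districts")
  ids <- as.character(districts$district_id)
  assert_unique_ids(ids)
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))

  if (scheme == "binary_contiguity") {
    if (is.null(adjacency)) {
      abort("binary_contiguity weights require an adjacency edge list")
    }
    adjacency <- validate_adjacency(adjacency, ids)
    ia <- match(adjacency$district_id_a, ids)
    ib <- match(adjacency$district_id_b, ids)
    W[cbind(ia, ib)] <- 1
    W[cbind(ib, ia)] <- 1
  } else {
    assert_columns(districts, c("easting_km", "northing_km"), "districts")
    if (anyNA(districts$easting_km) || anyNA(districts$northing_km)) {
      bad <- ids[is.na(districts$easting_km) | is.na(districts$northing_km)]
      abort(sprintf("missing centroid coordinates for: %s",
                    paste(bad, collapse = ", ")))
    }
    d <- as.matrix(stats::dist(cbind(districts$easting_km, districts$northing_km)))
    coincident <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
    if (nrow(coincident) > 0L) {
      abort(sprintf("coincident centroids: %s and %s (inverse distance undefined)",
                    ids[coincident[1, 1]], ids[coincident[1, 2]]))
    }
    W <- 1 / d
    diag(W) <- 0
    dimnames(W) <- list(ids, ids)
  }

  rs <- rowSums(W)
  islands <- ids[rs == 0]
  if (row_standardize) {
    keep <- rs > 0
    W[keep, ] <- W[keep, , drop = FALSE] / rs[keep]
  }
  structure(list(ids = ids, W = W, scheme = scheme,
                 row_standardized = row_standardize, islands = islands),
            class = "spr_weights")
}

validate_adjacency <- function(adjacency, ids) {
  assert_columns(adjacency, c("district_id_a", "district_id_b"), "adjacency")
  adjacency <- dplyr::mutate(adjacency,
                             district_id_a = as.character(.data$district_id_a),
                             district_id_b = as.character(.data$district_id_b))
  if (any(adjacency$district_id_a == adjacency$district_id_b)) {
    bad <- adjacency$district_id_a[adjacency$district_id_a == adjacency$district_id_b][1]
    abort(sprintf("adjacency must be irreflexive; district %s is listed as its own neighbour", bad))
  }
  unknown <- setdiff(c(adjacency$district_id_a, adjacency$district_id_b), ids)
  if (length(unknown) > 0L) {
    abort(sprintf("adjacency names unknown district(s): %s",
                  paste(head(unknown, 5L), collapse = ", ")))
  }
  key <- paste(pmin(adjacency$district_id_a, adjacency$district_id_b),
               pmax(adjacency$district_id_a, adjacency$district_id_b))
  if (anyDuplicated(key)) {
    abort(sprintf("adjacency pair listed more than once: %s",
                  key[duplicated(key)][1]))
  }
  adjacency
}

#' @export
print.spr_weights <- function(x, ...) {
  cat(sprintf("<spr_weights> %d districts, scheme = %s, row_standardized = %s\n",
              length(x$ids), x$scheme, x$row_standardized))
  if (length(x$islands) > 0L) {
    cat(sprintf("  islands (no neighbours): %s\n", paste(x$islands, collapse = ", ")))
  }
  invisible(x)
}

#' Spatial lag of a district-level variable
#'
#' Computes `lag_i = sum_j w_ij * value_j`. With row-standardized weights
#' this is the average of the variable over district i's neighbours, so
#' the lag of a constant is that constant for every connected district and
#' every lag lies between the minimum and maximum of the input values.
#' Districts with no neighbours get `NA` (they carry no neighbourhood
#' information and are dropped from downstream pattern regressions).
#'
#' @param w An [spr_weights] object.
#' @param values A numeric vector aligned with `w$ids`, or named by
#'   district id.
#' @return A tibble with columns `district_id`, `lag` and `island`.
#' @export
spatial_lag <- function(w, values) {
  stopifnot(inherits(w, "spr_weights"))
  if (!is.null(names(values))) {
    missing <- setdiff(w$ids, names(values))
    if (length(missing) > 0L) {
      abort(sprintf("values missing for district(s): %s",
                    paste(head(missing, 5L), collapse = ", ")))
    }
    values <- values[w$ids]
  }
  if (length(values) != length(w$ids)) {
    abort(sprintf("values has length %d but weights cover %d districts",
                  length(values), length(w$ids)))
  }
  lag <- as.numeric(w$W %*% values)
  island <- w$ids %in% w$islands
  lag[island] <- NA_real_
  tibble::tibble(district_id = w$ids, lag = lag, island = island)
}
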