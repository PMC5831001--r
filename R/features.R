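#' Spatial pattern regressors
#'
#' Five deterministic functions of district geography identify the spatial
#' dimensions whose pattern strength the engine measures:
#'
#' * `northness()` — the projected northing, so larger values lie further
#'   north; a positive slope on it is a north-south divide.
#' * `westness()` — the negated easting, so larger values lie further west
#'   and a west-east divide carries a positive slope.
#' * `centrality()` — Euclidean distance in km from a designated centre
#'   point (for Great Britain, London); larger values are more peripheral.
#' * `urbanity()` — population density in persons per square kilometre.
#' * contiguity and proximity are not column functions: they are spatial
#'   lags of the residual vector under [build_weights()] schemes and are
#'   constructed inside [measure_patterns()].
#'
#' @param districts A data frame with `district_id` plus the columns each
#'   measure needs: `northing_km`/`easting_km` (projected, kilometres),
#'   `population` and `area_km2`.
#' @param centre Numeric length-2 vector `c(easting_km, northing_km)` of
#'   the centre point, in the same projection as the district centroids.
#' @return A tibble with `district_id` and the named measure.
#' @name spatial_regressors
NULL

check_coords <- function(districts, cols) {
  assert_columns(districts, c("district_id", cols), "districts")
  for (col in cols) {
    if (anyNA(districts[[col]])) {
      bad <- districts$district_id[is.na(districts[[col]])]
      abort(sprintf("missing %s for district(s): %s", col,
                    paste(head(bad, 5L), collapse = ", ")))
    }
  }
  invisible(districts)
}

#' @rdname spatial_regressors
#' @export
northness <- function(districts) {
  check_coords(districts, "northing_km")
  tibble::tibble(district_id = as.character(districts$district_id),
                 northness = districts$northing_km)
}

#' @rdname spatial_regressors
#' @export
westness <- function(districts) {
  check_coords(districts, "easting_km")
  tibble::tibble(district_id = as.character(districts$district_id),
                 westness = -districts$easting_km)
}

#' @rdname spatial_regressors
#' @export
centrality <- function(districts, centre) {
  check_coords(districts, c("easting_km", "northing_km"))
  if (is.null(centre) || length(centre) != 2L || anyNA(centre)) {
    abort("centrality requires centre = c(easting_km, northing_km)")
  }
  tibble::tibble(
    district_id = as.character(districts$district_id),
    centrality = sqrt((districts$easting_km - centre[1])^2 +
                        (districts$northing_km - centre[2])^2))
}

#' @rdname spatial_regressors
#' @export
urbanity <- function(districts) {
  assert_columns(districts, c("district_id", "population", "area_km2"),
                 "districts")
  if (any(is.na(districts$area_km2) | districts$area_km2 <= 0)) {
    bad <- districts$district_id[is.na(districts$area_km2) | districts$area_km2 <= 0]
    abort(sprintf("non-positive area for district(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  tibble::tibble(district_id = as.character(districts$district_id),
                 urbanity = districts$population / districts$area_km2)
}

#' All point-geography regressors at once
#'
#' Convenience wrapper joining [northness()], [westness()],
#' [centrality()] and [urbanity()] into one tibble.
#'
#' @inheritParams spatial_regressors
#' @return A tibble with `district_id`, `northness`, `westness`,
#'   `centrality`, `urbanity`.
#' @export
spatial_features <- function(districts, centre) {
  northness(districts) |>
    dplyr::left_join(westness(districts), by = "district_id") |>
    dplyr::left_join(centrality(districts, centre), by = "district_id") |>
    dplyr::left_join(urbanity(districts), by = "district_id")
}

#' Derive queen contiguity from GeoJSON polygons
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features
#' keyed by a `district_id` property and returns the queen-criterion
#' adjacency edge list: two districts are adjacent iff their boundaries
#' share at least one vertex (coordinates compared after rounding to
#' `tolerance`). This covers administrative boundary files, where
#' touching polygons share their boundary vertices exactly.
#'
#' @param path Path to a GeoJSON file, or an already-parsed list.
#' @param id_property Name of the feature property holding the district
#'   id (default `"district_id"`).
#' @param tolerance Coordinates are rounded to this many digits before
#'   comparison (default 6).
#' @return A tibble edge list with columns `district_id_a`,
#'   `district_id_b`, each unordered adjacent pair once.
#' @export
contiguity_from_polygons <- function(path, id_property = "district_id",
                                     tolerance = 6) {
  gj <- if (is.character(path)) jsonlite::read_json(path) else path
  if (is.null(gj$features)) abort("not a GeoJSON FeatureCollection")
  vertex_key <- function(coords, id) {
    # flatten polygon rings to a character vector of rounded vertex keys
    if (!is.list(coords) || length(coords) == 0L) {
      abort(sprintf("invalid geometry for district %s: empty coordinates", id))
    }
    pts <- list()
    walk <- function(x) {
      if (is.list(x) && length(x) >= 2L && is.numeric(x[[1]]) && is.numeric(x[[2]])) {
        pts[[length(pts) + 1L]] <<- c(x[[1]], x[[2]])
      } else if (is.list(x)) {
        for (el in x) walk(el)
      } else {
        abort(sprintf("invalid geometry for district %s", id))
      }
    }
    walk(coords)
    vapply(pts, function(p) paste(round(p[1], tolerance), round(p[2], tolerance)), "")
  }
  feats <- gj$features
  ids <- character(length(feats))
  verts <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties[[id_property]]
    if (is.null(id)) abort(sprintf("feature %d has no '%s' property", i, id_property))
    geom <- f$geometry
    if (is.null(geom) || !geom$type %in% c("Polygon", "MultiPolygon")) {
      abort(sprintf("invalid geometry for district %s: expected Polygon or MultiPolygon", id))
    }
    ids[i] <- as.character(id)
    verts[[i]] <- unique(vertex_key(geom$coordinates, id))
  }
  assert_unique_ids(ids)
  pairs <- list()
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(verts[[i]], verts[[j]])) > 0L) {
        pairs[[length(pairs) + 1L]] <- tibble::tibble(
          district_id_a = ids[j], district_id_b = ids[i])
      }
    }
  }
  if (length(pairs) == 0L) {
    return(tibble::tibble(district_id_a = character(), district_id_b = character()))
  }
  dplyr::bind_rows(pairs)
}
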