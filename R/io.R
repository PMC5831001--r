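#' File readers and writers
#'
#' Plain-CSV interchange formats binding the modules into a workflow:
#'
#' * life tables: `district_id, sex, age_start, age_end, qx`
#' * centroids: `district_id, easting_km, northing_km, area_km2, population`
#' * adjacency edge list: `district_id_a, district_id_b` (each unordered
#'   pair once)
#' * attributes: `district_id` plus outcome/covariate columns
#' * weights export: sparse triplets `i, j, w` by district id
#'
#' All readers require a header, check numeric columns cell-by-cell and
#' report the file and column of the first offending value.
#'
#' @param path File path.
#' @name spr_io
NULL

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                   check.names = FALSE))
  assert_columns(df, required, basename(path))
  for (cn in intersect(numeric_cols, names(df))) {
    v <- df[[cn]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad) > 0L) {
        abort(sprintf("%s: non-numeric value '%s' in column %s (row %d)",
                      basename(path), v[bad[1]], cn, bad[1]))
      }
      df[[cn]] <- num
    }
  }
  df
}

#' @rdname spr_io
#' @export
read_lifetable_csv <- function(path) {
  lt <- read_checked_csv(path, c("district_id", "sex", "age_start", "age_end", "qx"),
                         c("age_start", "age_end", "qx"))
  lt$district_id <- as.character(lt$district_id)
  validate_lifetable(lt)
  lt
}

#' @rdname spr_io
#' @param lt,districts,adjacency,attributes Tibbles in the respective format.
#' @export
write_lifetable_csv <- function(lt, path) {
  write.csv(lt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname spr_io
#' @export
read_centroids_csv <- function(path) {
  d <- read_checked_csv(path, c("district_id", "easting_km", "northing_km"),
                        c("easting_km", "northing_km", "area_km2", "population"))
  d$district_id <- as.character(d$district_id)
  assert_unique_ids(d$district_id)
  d
}

#' @rdname spr_io
#' @export
write_centroids_csv <- function(districts, path) {
  write.csv(districts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname spr_io
#' @export
read_adjacency_csv <- function(path) {
  a <- read_checked_csv(path, c("district_id_a", "district_id_b"), character())
  a$district_id_a <- as.character(a$district_id_a)
  a$district_id_b <- as.character(a$district_id_b)
  a
}

#' @rdname spr_io
#' @export
write_adjacency_csv <- function(adjacency, path) {
  write.csv(adjacency, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname spr_io
#' @export
read_attributes_csv <- function(path) {
  d <- read_checked_csv(path, "district_id", character())
  d$district_id <- as.character(d$district_id)
  assert_unique_ids(d$district_id)
  for (cn in setdiff(names(d), "district_id")) {
    if (is.character(d[[cn]])) {
      suppressWarnings(num <- as.numeric(d[[cn]]))
      bad <- which(!is.na(d[[cn]]) & d[[cn]] != "" & is.na(num))
      if (length(bad) > 0L) {
        abort(sprintf("%s: non-numeric value '%s' in column %s (row %d)",
                      basename(path), d[[cn]][bad[1]], cn, bad[1]))
      }
      d[[cn]] <- num
    }
  }
  d
}

#' @rdname spr_io
#' @export
write_attributes_csv <- function(attributes, path) {
  write.csv(attributes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname spr_io
#' @param w An [spr_weights] object.
#' @export
write_weights_csv <- function(w, path) {
  stopifnot(inherits(w, "spr_weights"))
  nz <- which(w$W != 0, arr.ind = TRUE)
  trip <- tibble::tibble(i = w$ids[nz[, 1]], j = w$ids[nz[, 2]],
                         w = w$W[nz]) |>
    dplyr::arrange(.data$i, .data$j)
  write.csv(trip, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write or read a simulated input bundle
#'
#' Persists a [simulate_districts()] result as the four plain-CSV inputs
#' (centroids, adjacency, attributes, life tables) plus a ground-truth
#' JSON (`beta`, `rho`, `seed`, config echo) for recovery tests.
#'
#' @param sim A [simulate_districts()] result.
#' @param dir Output directory (created if needed).
#' @return `write_bundle()` the directory, invisibly; `read_bundle()` a
#'   list of tibbles plus the parsed truth.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_centroids_csv(sim$districts, file.path(dir, "centroids.csv"))
  write_adjacency_csv(sim$adjacency, file.path(dir, "adjacency.csv"))
  write_attributes_csv(sim$attributes, file.path(dir, "attributes.csv"))
  write_lifetable_csv(sim$lifetables, file.path(dir, "lifetables.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  list(districts = read_centroids_csv(file.path(dir, "centroids.csv")),
       adjacency = read_adjacency_csv(file.path(dir, "adjacency.csv")),
       attributes = read_attributes_csv(file.path(dir, "attributes.csv")),
       lifetables = read_lifetable_csv(file.path(dir, "lifetables.csv")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}

#' Read a run configuration
#'
#' A flat YAML document naming the input files and analysis options:
#' `lifetables`, `centroids`, `adjacency` (or `polygons` for GeoJSON),
#' `attributes`, `centre_easting_km`/`centre_northing_km`,
#' `threshold_age`, `cohort_size`, `outcome_scale`
#' (`cohort`/`percent`), `covariates`, `baseline_covariates`,
#' `exclusions`, `subset_ids`, `se_type`, `population_weights`,
#' `exclude_outliers`, `outlier_cutoff`, `impute_column`,
#' `impute_donors`, `seed`, `out_dir`. Relative paths resolve against
#' the config file's directory.
#'
#' @param path Path to the YAML config.
#' @return A named list with resolved paths.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("lifetables", "centroids", "adjacency", "polygons",
                "attributes", "out_dir")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  for (key in c("lifetables", "centroids", "attributes")) {
    if (is.null(cfg[[key]])) abort(sprintf("config is missing '%s'", key))
    if (!file.exists(cfg[[key]])) {
      abort(sprintf("config references missing file: %s", cfg[[key]]))
    }
  }
  if (!is.null(cfg$impute_column) && is.null(cfg$seed)) {
    abort("config enables stochastic imputation but sets no seed")
  }
  cfg
}

#' Read and join all inputs of a configured run
#'
#' Reads life tables, centroids, adjacency (edge list or polygon-derived)
#' and attributes; validates the district-id join across files (unmatched
#' ids are an error naming them); applies configured exclusions and
#' optional imputation; computes the standardized premature-mortality
#' outcome at the configured threshold age.
#'
#' @param cfg A [read_run_config()] list (or equivalent).
#' @return A list: `data` (per district and sex, with
#'   `premature_mortality` as outcome), `districts`, `adjacency`,
#'   `exclusions` (log).
#' @export
read_inputs <- function(cfg) {
  lt <- read_lifetable_csv(cfg$lifetables)
  districts <- read_centroids_csv(cfg$centroids)
  adjacency <- if (!is.null(cfg$adjacency)) {
    read_adjacency_csv(cfg$adjacency)
  } else if (!is.null(cfg$polygons)) {
    contiguity_from_polygons(cfg$polygons)
  }
  attributes_tbl <- read_attributes_csv(cfg$attributes)

  ids_lt <- unique(lt$district_id)
  for (pair in list(c("centroids", "attributes"),
                    c("lifetables", "centroids"))) {
    a <- switch(pair[1], centroids = districts$district_id,
                lifetables = ids_lt)
    b <- switch(pair[2], attributes = attributes_tbl$district_id,
                centroids = districts$district_id)
    unmatched <- c(setdiff(a, b), setdiff(b, a))
    if (length(unmatched) > 0L) {
      abort(sprintf("district ids do not match between %s and %s: %s",
                    pair[1], pair[2],
                    paste(head(unique(unmatched), 5L), collapse = ", ")))
    }
  }

  if (!is.null(cfg$exclusions) && length(cfg$exclusions) > 0L) {
    attributes_tbl <- exclude_districts(attributes_tbl,
                                        ids = unlist(cfg$exclusions))
    excl <- exclusion_log(attributes_tbl)
    districts <- districts[districts$district_id %in% attributes_tbl$district_id, ]
    lt <- lt[lt$district_id %in% attributes_tbl$district_id, ]
    if (!is.null(adjacency)) {
      adjacency <- dplyr::filter(adjacency,
                                 .data$district_id_a %in% districts$district_id,
                                 .data$district_id_b %in% districts$district_id)
    }
  } else {
    excl <- tibble::tibble(district_id = character(), reason = character())
  }

  if (!is.null(cfg$impute_column) &&
      anyNA(attributes_tbl[[cfg$impute_column]])) {
    attributes_tbl <- impute_income(attributes_tbl,
                                    column = cfg$impute_column,
                                    donors = unlist(cfg$impute_donors),
                                    seed = cfg$seed)
  }

  threshold <- cfg$threshold_age %||% 70
  cohort <- cfg$cohort_size %||% 100000
  pm <- premature_mortality(lt, threshold_age = threshold, cohort_size = cohort)
  if (identical(cfg$outcome_scale, "percent")) {
    pm$premature_mortality <- 100 * pm$premature_mortality / cohort
  }
  data <- dplyr::left_join(pm, attributes_tbl, by = "district_id")
  list(data = data, districts = districts, adjacency = adjacency,
       exclusions = excl)
}

#' Execute a configured run end to end
#'
#' Reads all inputs per [read_inputs()], runs the five-step procedure
#' separately by sex via [run_spr()] and writes the report (rounded CSV
#' plus full-precision JSON carrying the config hash and seed) to the
#' configured output directory.
#'
#' @inheritParams read_inputs
#' @return The [run_spr()] report, invisibly.
#' @export
run_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  inputs <- read_inputs(cfg)
  centre <- c(cfg$centre_easting_km %||% NA_real_,
              cfg$centre_northing_km %||% NA_real_)
  report <- run_spr(
    inputs$data, inputs$districts,
    outcome = "premature_mortality",
    covariates = unlist(cfg$covariates),
    baseline_covariates = unlist(cfg$baseline_covariates) %||% character(),
    adjacency = inputs$adjacency,
    centre = if (!anyNA(centre)) centre,
    by = "sex",
    subset_ids = unlist(cfg$subset_ids),
    population_weights = isTRUE(cfg$population_weights),
    exclude_outliers = isTRUE(cfg$exclude_outliers),
    outlier_cutoff = cfg$outlier_cutoff %||% 2.5,
    se_type = cfg$se_type %||% "HC1")
  if (!is.null(cfg$out_dir)) {
    write_report(report, cfg$out_dir, config = cfg)
  }
  invisible(report)
}

#' Write a pattern report to disk
#'
#' Two artifacts: `report.csv`, the human-readable table (slopes at 4
#' decimals, declines at 1 decimal of a percent), and `report.json`,
#' full-precision rows plus metadata — the run options, the seed, and a
#' hash of the configuration — so a stored config reproduces the file
#' byte for byte.
#'
#' @param report An [run_spr()] report.
#' @param dir Output directory (created if needed).
#' @param config Optional configuration list recorded in the metadata.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir, config = NULL) {
  stopifnot(inherits(report, "spr_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report_table(report), file.path(dir, "report.csv"),
            row.names = FALSE, quote = FALSE)
  opts <- attr(report, "options")
  meta <- list(options = opts, seed = config$seed %||% NULL,
               config_hash = rlang::hash(list(opts, config)))
  jsonlite::write_json(
    list(metadata = meta,
         results = tidy(report),
         fit_summary = glance(report)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
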