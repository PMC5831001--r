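test_that("northness and westness orient the geo-coordinate regressors", {
  d <- tibble::tibble(district_id = c("S", "N"),
                      easting_km = c(5, 5), northing_km = c(100, 200),
                      area_km2 = 1, population = 1)
  expect_equal(northness(d)$northness, c(100, 200))
  # larger westness = further west: negated easting keeps a positive
  # west-east divide slope positive
  d2 <- tibble::tibble(district_id = c("E", "W"),
                       easting_km = c(300, 100), northing_km = 0)
  expect_equal(westness(d2)$westness, c(-300, -100))
  expect_gt(westness(d2)$westness[2], westness(d2)$westness[1])
})

test_that("slopes on the geo regressors are translation- and sign-consistent", {
  set.seed(3)
  d <- tibble::tibble(district_id = sprintf("d%02d", 1:20),
                      easting_km = runif(20, 0, 500),
                      northing_km = runif(20, 0, 1000))
  y <- 0.4 * d$northing_km - 0.2 * d$easting_km + rnorm(20)
  df <- dplyr::mutate(d, y = y, north = northness(d)$northness,
                      west = westness(d)$westness)
  slope <- function(data, x) coef(fit_ols(data, "y", x))[[x]]
  # oracle: refit on shifted northings — the slope is unchanged
  shifted <- dplyr::mutate(df, north = north + 50)
  expect_equal(slope(df, "north"), slope(shifted, "north"), tolerance = 1e-10)
  # sign-flip oracle: slope on westness = -slope on easting
  df$easting <- d$easting_km
  expect_equal(slope(df, "west"), -slope(df, "easting"), tolerance = 1e-10)
})

test_that("centrality is Euclidean distance from the configured centre", {
  d <- tibble::tibble(district_id = c("ctr", "pyth"),
                      easting_km = c(10, 13), northing_km = c(20, 24))
  cen <- centrality(d, centre = c(10, 20))
  expect_equal(cen$centrality, c(0, 5))
  expect_error(centrality(d, centre = NULL), "centre")
  # permuting district order permutes outputs identically
  p <- c(2, 1)
  expect_equal(centrality(d[p, ], centre = c(10, 20))$centrality,
               cen$centrality[p])
})

test_that("urbanity is population density with scaling and guard rails", {
  d <- tibble::tibble(district_id = c("a", "b"),
                      easting_km = 0, northing_km = 0,
                      area_km2 = c(10, 10), population = c(1000, 0))
  expect_equal(urbanity(d)$urbanity, c(100, 0))
  half <- dplyr::mutate(d, area_km2 = area_km2 / 2)
  expect_equal(urbanity(half)$urbanity, 2 * urbanity(d)$urbanity)
  bad <- dplyr::mutate(d, area_km2 = c(10, 0))
  expect_error(urbanity(bad), "non-positive area.*b")
})

test_that("missing coordinates are reported by district", {
  d <- tibble::tibble(district_id = c("ok", "gone"),
                      easting_km = c(1, NA), northing_km = c(1, 2))
  expect_error(westness(d), "missing easting_km.*gone")
  expect_no_error(northness(d))
})

# helper: a GeoJSON FeatureCollection of unit squares at given offsets
square_geojson <- function(offsets, path) {
  feature <- function(id, ox, oy) {
    ring <- list(c(ox, oy), c(ox + 1, oy), c(ox + 1, oy + 1),
                 c(ox, oy + 1), c(ox, oy))
    list(type = "Feature",
         properties = list(district_id = id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  }
  fc <- list(type = "FeatureCollection",
             features = purrr::imap(offsets, ~feature(.y, .x[1], .x[2])))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  path
}

test_that("queen contiguity from polygons links boundary-sharing squares", {
  path <- withr::local_tempfile(fileext = ".geojson")
  # 2x2 grid of touching unit squares: all 6 pairs share at least a corner
  square_geojson(list(a = c(0, 0), b = c(1, 0), c = c(0, 1), d = c(1, 1)), path)
  adj <- contiguity_from_polygons(path)
  expect_equal(nrow(adj), 6)

  # two disjoint squares: no adjacency
  square_geojson(list(a = c(0, 0), b = c(5, 5)), path)
  expect_equal(nrow(contiguity_from_polygons(path)), 0)

  # 3x3 grid: the centre square touches all 8 others; verify the full
  # neighbour-count distribution against an exhaustive intersection oracle
  offs <- list()
  for (r in 0:2) for (c in 0:2) offs[[sprintf("s%d%d", r, c)]] <- c(c, r)
  square_geojson(offs, path)
  adj3 <- contiguity_from_polygons(path)
  counts <- table(c(adj3$district_id_a, adj3$district_id_b))
  expect_equal(unname(counts[["s11"]]), 8)
  expect_equal(sort(as.vector(counts)), sort(c(3, 5, 3, 5, 8, 5, 3, 5, 3)))
})

test_that("invalid polygon geometry is rejected with the district named", {
  path <- withr::local_tempfile(fileext = ".geojson")
  fc <- list(type = "FeatureCollection",
             features = list(list(type = "Feature",
                                  properties = list(district_id = "broken"),
                                  geometry = list(type = "Point",
                                                  coordinates = c(1, 2)))))
  jsonlite::write_json(fc, path, auto_unbox = TRUE)
  expect_error(contiguity_from_polygons(path), "broken")
})
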