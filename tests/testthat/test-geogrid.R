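test_that("LAEA projection matches closed forms and round-trips", {
  spec <- grid_spec()
  # the projection center maps to the origin
  o <- project_laea(spec$lon0, spec$lat0, spec)
  expect_equal(c(o$x_km, o$y_km), c(0, 0), tolerance = 1e-9)
  # 1 degree due north of center: closed form y = 2 R sin(dphi / 2)
  p <- project_laea(spec$lon0, spec$lat0 + 1, spec)
  expect_equal(p$x_km, 0, tolerance = 1e-9)
  expect_equal(p$y_km, 2 * 6371.0072 * sin(pi / 360), tolerance = 1e-6)
  expect_equal(p$y_km, 111.19, tolerance = 0.01)
  # round-trip within 1e-6 km over scattered points
  set.seed(4)
  lon <- runif(50, -125, -66); lat <- runif(50, 24, 50)
  xy <- project_laea(lon, lat, spec)
  ll <- inverse_laea(xy$x_km, xy$y_km, spec)
  back <- project_laea(ll$lon, ll$lat, spec)
  expect_lt(max(abs(back$x_km - xy$x_km), abs(back$y_km - xy$y_km)), 1e-6)
  # antipode of the center is rejected
  expect_error(project_laea(180 + spec$lon0, -spec$lat0, spec), "antipode")
})

test_that("projection preserves area within 0.5% of the spherical form", {
  spec <- grid_spec()
  R <- 6371.0072
  for (lat0 in c(28, 47)) {
    lons <- c(seq(-100, -99, length.out = 25),
              rep(-99, 25), seq(-99, -100, length.out = 25), rep(-100, 25))
    lats <- c(rep(lat0, 25), seq(lat0, lat0 + 1, length.out = 25),
              rep(lat0 + 1, 25), seq(lat0 + 1, lat0, length.out = 25))
    xy <- project_laea(lons, lats, spec)
    x <- xy$x_km; y <- xy$y_km
    shoelace <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    truth <- R^2 * (pi / 180) *
      (sin((lat0 + 1) * pi / 180) - sin(lat0 * pi / 180))
    expect_lt(abs(shoelace - truth) / truth, 0.005)
  }
})

test_that("cell binning is half-open with high-index edge assignment", {
  spec <- grid_spec()
  expect_equal(unlist(cell_of(spec$x0, spec$y0, spec)),
               c(row = 0L, col = 0L))
  # a point exactly on an interior edge belongs to the higher-index cell
  expect_equal(cell_of(spec$x0 + 250, spec$y0 + 500, spec)$col, 1L)
  expect_equal(cell_of(spec$x0 + 250, spec$y0 + 500, spec)$row, 2L)
  # 1 km outside the extent is off-grid
  expect_true(is.na(cell_of(spec$x0 - 1, 0, spec)$row))
  expect_true(is.na(cell_of(0, spec$y0 + 4000 + 1, spec)$row))
  # the top edge itself is exclusive
  expect_true(is.na(cell_of(spec$x0 + 6000, 0, spec)$col))
})

test_that("OTU distributions pool species records before thresholding", {
  spec <- grid_spec()
  cen <- cell_centroid(8, 12, spec)
  # two species, one record each, same cell: merge precedes the >= 2 rule
  store <- tiny_store(data.frame(
    species = c("Aa bb", "Cc dd"), lat = rep(cen$lat, 2),
    lon = rep(cen$lon, 2)))
  d <- otu_distribution(c("Aa bb", "Cc dd"), store, spec)
  expect_equal(d$positive_cells, data.frame(row = 8L, col = 12L))
  # a single record is below the positivity threshold
  d1 <- otu_distribution("Aa bb", store, spec)
  expect_equal(nrow(d1$positive_cells), 0)
  # two records of one species in one cell are enough
  store2 <- tiny_store(data.frame(
    species = rep("Aa bb", 2), lat = rep(cen$lat, 2),
    lon = rep(cen$lon, 2)))
  d2 <- otu_distribution("Aa bb", store2, spec)
  expect_equal(nrow(d2$positive_cells), 1)
  # species with zero records: empty distribution
  expect_equal(nrow(otu_distribution("Ee ff", store, spec)$positive_cells),
               0)
  # order of species does not matter (set semantics)
  d3 <- otu_distribution(c("Cc dd", "Aa bb"), store, spec)
  expect_identical(d3$positive_cells, d$positive_cells)
})

test_that("the overlay surface is a per-cell fraction of mapped OTUs", {
  spec <- small_spec()
  mk <- function(cells) list(otu_id = "x",
                             positive_cells = data.frame(row = cells[, 1],
                                                         col = cells[, 2]))
  d1 <- mk(rbind(c(0, 0), c(0, 1)))
  d2 <- mk(rbind(c(0, 0), c(0, 1)))
  d3 <- mk(rbind(c(0, 0), c(1, 4)))
  d4 <- mk(rbind(c(0, 0), c(0, 1)))
  surf <- overlay(list(d1, d2, d3, d4), spec)
  expect_equal(surf$n_otus, 4)
  expect_equal(surf$values[1, 1], 1)       # positive in 4 of 4
  expect_equal(surf$values[1, 2], 0.75)    # positive in 3 of 4
  expect_equal(surf$values[2, 5], 0.25)
  # conservation: values times n_otus are integer counts
  expect_true(all(abs(surf$values * surf$n_otus -
                        round(surf$values * surf$n_otus)) < 1e-12))
  # empty distributions are not mapped OTUs
  surf2 <- overlay(list(d1, mk(matrix(0, 0, 2))), spec)
  expect_equal(surf2$n_otus, 1)
  expect_true(all(surf2$values %in% c(0, 1)))
  expect_error(overlay(list(mk(matrix(0, 0, 2))), spec), "no mapped OTUs")
})

test_that("a cosmopolitan OTU shifts values uniformly, preserving ranks", {
  spec <- small_spec()
  set.seed(9)
  dists <- lapply(1:5, function(i) {
    cells <- unique(cbind(sample(0:1, 4, TRUE), sample(0:4, 4, TRUE)))
    list(otu_id = paste0("o", i),
         positive_cells = data.frame(row = cells[, 1], col = cells[, 2]))
  })
  base <- overlay(dists, spec)
  all_cells <- expand.grid(row = 0:1, col = 0:4)
  cosmo <- list(otu_id = "cosmo", positive_cells = all_cells)
  with_cosmo <- overlay(c(dists, list(cosmo)), spec)
  # brute-force rank comparison: cell ordering is unchanged
  expect_identical(order(base$values, row(base$values), col(base$values)),
                   order(with_cosmo$values, row(with_cosmo$values),
                         col(with_cosmo$values)))
  # and the argmax cell set is identical
  expect_identical(which(base$values == max(base$values)),
                   which(with_cosmo$values == max(with_cosmo$values)))
})

test_that("surfaces export to flat CSV and GeoJSON", {
  spec <- small_spec()
  vals <- matrix(0, 2, 5); vals[1, 2] <- 0.5; vals[2, 4] <- 0.25
  surf <- surface_from_values(vals, spec, n_otus = 4L)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "s.csv"); gj <- file.path(dir, "s.geojson")
  df <- write_surface(surf, csv_path = csv, geojson_path = gj)
  expect_equal(nrow(df), 10)
  expect_true(file.exists(csv))
  got <- read.csv(csv)
  expect_equal(sum(got$fraction), 0.75)
  expect_equal(sort(unique(got$count)), c(0, 1, 2))
  js <- paste(readLines(gj), collapse = "")
  expect_match(js, '"FeatureCollection"')
  expect_equal(lengths(regmatches(js, gregexpr('"Feature"', js))), 2)
})
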