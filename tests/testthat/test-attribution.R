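test_that("haversine matches closed forms and an independent implementation", {
  expect_equal(haversine_km(c(-71, 42), c(-71, 42)), 0)
  # quarter great circle: pi * R / 2
  expect_equal(haversine_km(c(0, 0), c(0, 90)), pi * 6371 / 2,
               tolerance = 1e-9)
  expect_equal(haversine_km(c(0, 0), c(0, 90)), 10007.54, tolerance = 0.01)
  # symmetry
  expect_equal(haversine_km(c(-71, 42), c(-106, 35)),
               haversine_km(c(-106, 35), c(-71, 42)))
  skip_if_not_installed("geosphere")
  set.seed(14)
  a <- cbind(runif(20, -180, 180), runif(20, -89, 89))
  b <- cbind(runif(20, -180, 180), runif(20, -89, 89))
  expect_equal(haversine_km(a, b),
               geosphere::distHaversine(a, b, r = 6371000) / 1000,
               tolerance = 1e-9)
})

test_that("AT5PE is the arithmetic mean of the five peak distances", {
  truth <- c(-98, 39.5)
  km_per_deg <- 6371 * pi / 180
  peaks <- data.frame(lon = truth[1],
                      lat = truth[2] + c(100, 200, 300, 400, 500) /
                        km_per_deg)
  expect_equal(at5pe(peaks, truth), 300, tolerance = 1e-6)
  # all peaks at truth
  same <- data.frame(lon = rep(truth[1], 5), lat = rep(truth[2], 5))
  expect_equal(at5pe(same, truth), 0)
  # peak order does not matter; a far outlier adds outlier/5
  shuffled <- peaks[c(3, 1, 5, 2, 4), ]
  expect_equal(at5pe(shuffled, truth), at5pe(peaks, truth))
  outlier <- peaks; outlier$lat[5] <- truth[2] + 1500 / km_per_deg
  expect_equal(at5pe(outlier, truth) - at5pe(peaks, truth), 1000 / 5,
               tolerance = 1e-6)
  expect_error(at5pe(peaks[1:4, ], truth), "5 peaks")
})

test_that("truth percentage is the strict-less percentile over all cells", {
  spec <- small_spec()  # 10 cells
  truth <- unlist(cell_centroid(1, 2, spec))  # lon, lat of cell (1, 2)
  # truth cell is the unique maximum of 10 cells -> 90.0
  vals <- matrix(0.1, 2, 5); vals[2, 3] <- 0.9
  expect_equal(truth_percentage(surface_from_values(vals, spec),
                                c(truth["lon"], truth["lat"])), 90)
  # uniform surface: no cell strictly less -> 0
  expect_equal(truth_percentage(surface_from_values(matrix(0.3, 2, 5), spec),
                                c(truth["lon"], truth["lat"])), 0)
  # {0.1, 0.2, 0.2, 0.3, 0.5} with truth at the 0.3 cell -> 60.0
  spec5 <- grid_spec(cell_km = 100, width_km = 500, height_km = 100)
  vals5 <- matrix(c(0.1, 0.2, 0.2, 0.3, 0.5), 1, 5)
  t5 <- unlist(cell_centroid(0, 3, spec5))
  expect_equal(truth_percentage(surface_from_values(vals5, spec5),
                                c(t5["lon"], t5["lat"])), 60)
  # off-grid truth errors
  expect_error(truth_percentage(surface_from_values(vals, spec), c(0, 0)),
               "off-grid")
})

test_that("truth percentage equals the brute-force count on random surfaces", {
  set.seed(77)
  for (i in 1:40) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    spec <- grid_spec(cell_km = 250, width_km = nc * 250,
                      height_km = nr * 250)
    vals <- matrix(sample(seq(0, 1, 0.05), nr * nc, TRUE), nr, nc)
    tr <- sample(0:(nr - 1), 1); tc <- sample(0:(nc - 1), 1)
    cen <- cell_centroid(tr, tc, spec)
    expect_equal(truth_percentage(surface_from_values(vals, spec),
                                  c(cen$lon, cen$lat)),
                 brute_tp(vals, tr, tc))
  }
})

test_that("sharpening mass into the truth cell never decreases TP", {
  set.seed(88)
  spec <- small_spec()
  vals <- matrix(runif(10), 2, 5)
  cen <- cell_centroid(1, 3, spec)
  tp_seq <- vapply(seq(0, 0.9, 0.1), function(extra) {
    v <- vals; v[2, 4] <- v[2, 4] + extra
    truth_percentage(surface_from_values(v, spec), c(cen$lon, cen$lat))
  }, 0)
  expect_true(all(diff(tp_seq) >= 0))
})

test_that("positivity needs accuracy and resolution together", {
  th <- thresholds()
  expect_true(classify_attribution(92, 450, th))
  expect_false(classify_attribution(92, 700, th))
  expect_false(classify_attribution(89.9, 100, th))
  # boundary semantics: TP uses >=, AT5PE uses strict <
  expect_true(classify_attribution(90, 599.99, th))
  expect_false(classify_attribution(90, 600, th))
})

test_that("cohort summaries count sites, strata and rates", {
  df <- data.frame(sample_id = paste0("s", 1:4),
                   site = c("A", "A", "B", "B"),
                   n_mapped_otus = c(25, 5, 30, 40),
                   tp = c(95, 99, 50, 92), at5pe = c(100, 700, 200, 300))
  s <- summarize_cohort(df)
  all_row <- s[s$site == "all sites", ]
  expect_equal(all_row$n, 4)
  expect_equal(all_row$tp_pass, 3)
  expect_equal(all_row$at5pe_pass, 3)
  expect_equal(all_row$positive, 2)
  expect_equal(all_row$pct_positive, 50.0)
  expect_equal(all_row$n_ge, 3)
  expect_equal(all_row$positive_ge, 2)
  expect_equal(all_row$pct_positive_ge, 66.7)
  # single positive sample -> 100%
  one <- summarize_cohort(df[4, ])
  expect_equal(one$pct_positive[one$site == "all sites"], 100.0)
  # empty cohort -> zeros with null percentages
  empty <- summarize_cohort(df[0, ])
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$pct_positive))
})
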