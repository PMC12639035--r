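test_that("period index is chronological and anchored at the first year", {
  expect_identical(period_index(1997, 1, 1997), 1L)
  expect_identical(period_index(1998, 1, 1997), 13L)
  expect_identical(period_index(2009, 12, 1997), 156L)
  yrs <- rep(1997:1999, each = 12)
  mos <- rep(1:12, 3)
  idx <- period_index(yrs, mos, 1997)
  expect_true(all(diff(idx) == 1))
  expect_error(period_index(2000, 13, 1997), "month")
  expect_error(period_index(2000, 0, 1997), "month")
})

test_that("panel construction orders, balances and round-trips", {
  p <- make_toy_panel(2, 3)
  expect_s3_class(p, "regional_panel")
  expect_identical(attr(p, "n_regions"), 2L)
  expect_identical(attr(p, "n_periods"), 3L)
  expect_equal(nrow(p), 6)
  # stable ordering: regions lexical, periods chronological within region
  expect_identical(p$region, sort(p$region))
  expect_true(all(tapply(p$period, p$region, function(x) all(diff(x) > 0))))

  f <- tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- load_panel(f)
  for (col in c("region", "year", "month", "conflict", "TA", "DL", "PA")) {
    expect_identical(p2[[col]], p[[col]])
  }
})

test_that("column mapping, missing columns and bad counts are caught", {
  p <- make_toy_panel(2, 2)
  f <- tempfile(fileext = ".csv")
  df <- as.data.frame(p)[, c("region", "year", "month", "conflict",
                             "TA", "DL", "PA")]
  names(df)[4] <- "events"
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(load_panel(f), "missing required columns")
  p3 <- load_panel(f, column_map = c(conflict = "events"))
  expect_identical(p3$conflict, p$conflict)
  expect_error(load_panel(f, column_map = c(conflict = "nope")),
               "not present")

  dfbad <- as.data.frame(p)
  dfbad$conflict[3] <- 1.5
  expect_error(regional_panel(dfbad), "row 3")
  dfok <- as.data.frame(p)
  dfok$conflict <- dfok$conflict + 1e-12  # integral within tolerance: cast
  expect_identical(regional_panel(dfok)$conflict, p$conflict)
})

test_that("unbalanced panels are reported cell by cell and refused", {
  p <- make_toy_panel(2, 3)
  df <- as.data.frame(p)[-2, ]  # drop region r01, period 2
  rep_ <- validate_panel(df)
  expect_false(rep_$is_balanced)
  expect_identical(rep_$missing_cells$region, "r01")
  expect_identical(rep_$missing_cells$period, 2L)
  expect_error(regional_panel(df), "not balanced")
  out <- regional_panel(df, strict = FALSE)
  expect_false(attr(out, "validation")$is_balanced)
  js <- jsonlite::fromJSON(report_to_json(rep_))
  expect_false(js$is_balanced)
})

test_that("balanced panel iff no missing cells", {
  for (seed in 1:5) {
    p <- make_toy_panel(3, 4, seed = seed)
    rep_full <- validate_panel(as.data.frame(p))
    expect_true(rep_full$is_balanced)
    expect_identical(nrow(rep_full$missing_cells), 0L)
    drop <- sample(nrow(p), 2)
    rep_miss <- validate_panel(as.data.frame(p)[-drop, ])
    expect_false(rep_miss$is_balanced)
    expect_identical(nrow(rep_miss$missing_cells), 2L)
  }
})

test_that("haversine distances match closed forms and metric axioms", {
  R_earth <- 6371.0088
  g <- data.frame(region = c("a", "b", "c"),
                  lat = c(0, 0, 0), lon = c(0, 1, 180))
  d <- pairwise_distances(g)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 2 * pi * R_earth / 360, tolerance = 1e-6)
  expect_equal(d["a", "c"], pi * R_earth, tolerance = 1e-6)
  expect_true(isSymmetric(d))

  set.seed(42)
  big <- data.frame(region = sprintf("r%02d", 1:12),
                    lat = runif(12, -60, 60), lon = runif(12, -180, 180))
  D <- pairwise_distances(big)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  for (k in 1:100) {
    tri <- sample(12, 3)
    expect_lte(D[tri[1], tri[3]],
               D[tri[1], tri[2]] + D[tri[2], tri[3]] + 1e-9)
  }
  expect_error(pairwise_distances(data.frame(region = "x", lat = 95, lon = 0)),
               "latitude")
})

test_that("haversine agrees with an independent geodesic implementation", {
  skip_if_not_installed("geosphere")
  set.seed(9)
  g <- data.frame(region = sprintf("r%d", 1:6),
                  lat = runif(6, -80, 80), lon = runif(6, -180, 180))
  D <- pairwise_distances(g)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      ref <- geosphere::distHaversine(c(g$lon[i], g$lat[i]),
                                      c(g$lon[j], g$lat[j]),
                                      r = 6371008.8) / 1000
      expect_equal(D[i, j], ref, tolerance = 1e-9)
    }
  }
})

test_that("geometry requires the declared columns", {
  expect_error(region_geometry(data.frame(region = "a", lat = 1)), "columns")
  g <- region_geometry(data.frame(region = c("b", "a"), lat = c(1, 2),
                                  lon = c(3, 4)))
  expect_identical(g$centroids$region, c("a", "b"))  # sorted
  expect_identical(rownames(g$distances), c("a", "b"))
})
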