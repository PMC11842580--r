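test_that("dekadal SMI aggregation equals the hand/loop oracle and stays in [0,1]", {
  g <- small_grid(3, 3)
  d <- dekad(2021, month = 5, dekad_of_month = 1)   # a 10-day dekad
  dates <- seq(dekad_start(d), dekad_end(d), by = "day")
  ramp <- matrix(rep(seq(0, 0.9, by = 0.1), each = 9), 9, 10)
  st <- daily_stack(ramp, dates, g, "smi")
  expect_true(all(abs(aggregate_smi_dekad(st, d)$values - 0.45) < 1e-12))
  const <- daily_stack(matrix(0.5, 9, 10), dates, g, "smi")
  expect_true(all(aggregate_smi_dekad(const, d)$values == 0.5))
  set.seed(5)
  v <- matrix(runif(90), 9, 10)
  st2 <- daily_stack(v, dates, g, "smi")
  agg <- aggregate_smi_dekad(st2, d)
  for (px in 1:9) {                                  # loop oracle
    s <- 0
    for (j in 1:10) s <- s + v[px, j]
    expect_equal(as.vector(agg$values)[px], s / 10)
  }
  expect_true(all(agg$values >= 0 & agg$values <= 1))
  expect_error(aggregate_smi_dekad(st2, dekad(2020, 1)), "does not cover")
  bad <- daily_stack(matrix(1.5, 9, 10), dates, g, "smi")
  expect_error(aggregate_smi_dekad(bad, d), "outside")
})

test_that("aggregation honours the minimum-valid-days rule", {
  g <- small_grid(1, 1)
  d <- dekad(2021, month = 5, dekad_of_month = 1)
  dates <- seq(dekad_start(d), dekad_end(d), by = "day")
  v <- matrix(0.4, 1, 10)
  v[1, 1:4] <- NA                                    # 6 valid days < 7
  expect_true(is.na(aggregate_smi_dekad(daily_stack(v, dates, g), d)$values[1, 1]))
  v[1, 4] <- 0.4                                     # exactly 7 valid days
  expect_equal(aggregate_smi_dekad(daily_stack(v, dates, g), d)$values[1, 1], 0.4)
})

test_that("climatology mean/sd match hand values; degenerate pixels invalid", {
  g <- small_grid(1, 2)
  mk <- function(a, b) raster_field(matrix(c(a, b), 1, 2), g)
  clim <- build_climatology(list(mk(0.2, 0.3), mk(0.4, 0.3)), min_years = 2L)
  expect_equal(clim$mean, c(0.3, 0.3))
  expect_equal(clim$sd[1], sd(c(0.2, 0.4)))          # 0.1414..., n-1 form
  expect_equal(clim$sd[1], 0.1414, tolerance = 1e-3)
  expect_false(clim$valid[2])                        # identical years: sd 0
  expect_true(clim$valid[1])
  expect_error(build_climatology(list()))
})

test_that("standardizing baseline members yields per-pixel mean 0 and sd 1", {
  g <- small_grid(4, 4)
  set.seed(77)
  fields <- lapply(1:12, function(i)
    raster_field(matrix(rnorm(16, mean = 0.5, sd = 0.07), 4, 4), g))
  clim <- build_climatology(fields, min_years = 5L)
  z <- vapply(fields, function(f)
    as.vector(standardize(f, clim)$values), numeric(16))
  expect_equal(rowMeans(z), rep(0, 16), tolerance = 1e-12)
  expect_equal(apply(z, 1, sd), rep(1, 16), tolerance = 1e-12)
  # identities: I = mu -> 0, I = mu + sigma -> 1
  f_mu <- raster_field(matrix(clim$mean, 4, 4), g)
  expect_equal(as.vector(standardize(f_mu, clim)$values), rep(0, 16))
  f_mu_s <- raster_field(matrix(clim$mean + clim$sd, 4, 4), g)
  expect_equal(as.vector(standardize(f_mu_s, clim)$values), rep(1, 16))
  expect_error(standardize(const_field(1, small_grid(3, 3)), clim),
               "grid mismatch")
})

test_that("FAPAR quality filtering invalidates exactly the rejected flags", {
  g <- small_grid(4, 4)
  set.seed(9)
  flags <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
  comp <- fapar_composite(matrix(0.4, 4, 4), g, as.Date("2021-06-02"), flags)
  out <- qc_filter_fapar(comp, accepted = c(0L, 1L))
  expect_equal(sum(is.na(out$values)), sum(flags >= 2))
  expect_true(all(out$values[flags <= 1] == 0.4))
  expect_equal(qc_filter_fapar(comp, accepted = 0:3)$values, comp$values)
  all_bad <- qc_filter_fapar(comp, accepted = integer(0))
  expect_true(all(is.na(all_bad$values)))
})

test_that("dekadal FAPAR compositing is an inverse-time-distance weighted mean", {
  g <- small_grid(2, 2)
  d <- dekad(2021, month = 6, dekad_of_month = 2)    # days 11..20, mid 15.5
  mid <- dekad_midpoint(d)
  mk <- function(val, start) fapar_composite(matrix(val, 2, 2), g, start)
  # two composites symmetric about the dekad midpoint -> plain average
  a <- mk(0.2, as.Date("2021-06-08")); b <- mk(0.4, as.Date("2021-06-16"))
  expect_equal(abs((as.numeric(a$start) + 3.5) - mid),
               abs((as.numeric(b$start) + 3.5) - mid))
  out <- composite_fapar_dekad(list(a, b), d)
  expect_true(all(abs(out$values - 0.3) < 1e-12))
  # one composite exactly centred -> its value
  cen <- fapar_composite(matrix(0.7, 2, 2), g, as.Date("2021-06-12"))
  expect_true(all(composite_fapar_dekad(list(cen), d)$values == 0.7))
  # direct-formula oracle on asymmetric distances
  set.seed(3)
  v1 <- matrix(runif(4), 2, 2); v2 <- matrix(runif(4), 2, 2)
  c1 <- fapar_composite(v1, g, as.Date("2021-06-10"))
  c2 <- fapar_composite(v2, g, as.Date("2021-06-20"))
  d1 <- abs(as.numeric(c1$start) + 3.5 - mid)
  d2 <- abs(as.numeric(c2$start) + 3.5 - mid)
  w1 <- 1 / (d1 + 0.5); w2 <- 1 / (d2 + 0.5)
  want <- (w1 * v1 + w2 * v2) / (w1 + w2)
  expect_equal(composite_fapar_dekad(list(c1, c2), d)$values, want)
  # per-pixel renormalization when one input is invalid
  v2na <- v2; v2na[1, 1] <- NA
  c2na <- fapar_composite(v2na, g, as.Date("2021-06-20"))
  got <- composite_fapar_dekad(list(c1, c2na), d)$values
  expect_equal(got[1, 1], v1[1, 1])                  # weight renormalized to 1
  expect_error(composite_fapar_dekad(list(c1), dekad(2021, 1)), "no usable")
})

test_that("bilinear resampling reproduces planes and respects local bounds", {
  fine <- grid_spec(8, 8, cell_size = 1 / 48, origin_lon = 5, origin_lat = 62)
  coarse <- grid_spec(4, 4, cell_size = 1 / 24, origin_lon = 5, origin_lat = 62)
  expect_true(all(resample_bilinear(const_field(0.3, fine), coarse)$values == 0.3))
  # planar gradient: bilinear is exact on planes (away from edge clamping)
  ctr <- grid_cell_center(fine, matrix(1:8, 8, 8),
                          matrix(1:8, 8, 8, byrow = TRUE))
  plane <- raster_field(2 * ctr$lon + 3 * ctr$lat, fine)
  out <- resample_bilinear(plane, coarse)
  tc <- grid_cell_center(coarse, matrix(1:4, 4, 4),
                         matrix(1:4, 4, 4, byrow = TRUE))
  want <- 2 * tc$lon + 3 * tc$lat
  expect_equal(out$values[2:3, 2:3], want[2:3, 2:3], tolerance = 1e-9)
  # random field: outputs bounded by the contributing pixels' range
  set.seed(12)
  rnd <- raster_field(matrix(runif(64), 8, 8), fine)
  rs <- resample_bilinear(rnd, coarse)
  expect_true(all(rs$values >= min(rnd$values) - 1e-12 &
                    rs$values <= max(rnd$values) + 1e-12))
  far <- grid_spec(4, 4, origin_lon = 50, origin_lat = 10)
  expect_error(resample_bilinear(rnd, far), "disjoint")
})
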