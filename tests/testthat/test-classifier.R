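test_that("there are seven classes, three of them recovery classes", {
  expect_length(cdi_classes(), 7L)
  expect_length(cdi_recovery_classes(), 3L)
  expect_true(all(cdi_recovery_classes() %in% names(cdi_classes())))
  expect_length(cdi_palette(), 7L)
})

test_that("the bundled decision table validates and has 8 x 7 covered cells", {
  tab <- load_decision_table()
  expect_true(isTRUE(validate_table(tab)))
  cells <- unique(tab[, c("column", "prev")])
  expect_equal(nrow(cells), 8L * 7L)
  expect_setequal(unique(tab$column), LETTERS[1:8])
  expect_setequal(unique(tab$prev), names(cdi_classes()))
})

test_that("validate_table catches seeded violations", {
  tab <- load_decision_table()
  # direct drought -> no-drought transition
  bad <- tab
  bad$out[bad$column == "A" & bad$prev == "ALERT"] <- "NO_DROUGHT"
  rep1 <- validate_table(bad)
  expect_false(isTRUE(rep1))
  expect_true(any(grepl("ALERT.*NO_DROUGHT|NO_DROUGHT", rep1)))
  # missing cell
  expect_false(isTRUE(validate_table(tab[!(tab$column == "A" &
                                             tab$prev == "WATCH"), ])))
  expect_false(isTRUE(validate_table(tab[-1, ])))
  # E/G/H must be ALERT
  bad2 <- tab
  bad2$out[bad2$column == "H"] <- "WATCH"
  expect_false(isTRUE(validate_table(bad2)))
})

test_that("flag computation honours the threshold boundary conventions", {
  thr <- cdi_thresholds()
  # SPI comparisons strict: exactly -2 / -1 do not flag
  f <- compute_flags(-2, -1 + 1e-12, 0.5, 0.5, thr)
  expect_false(f$spi)
  f <- compute_flags(-2 - 1e-9, 0, 0.5, 0.5, thr)
  expect_true(f$spi)
  f <- compute_flags(0, -1 - 1e-9, 0.5, 0.5, thr)
  expect_true(f$spi)
  # SMA / FAPAR inclusive: exactly -1 flags
  f <- compute_flags(0, 0, -1, -1, thr)
  expect_true(f$sma); expect_true(f$fapar)
  # partial-recovery interval (-0.5, 0]: 0 in, -0.5 out
  f <- compute_flags(0, 0, 0, -0.5, thr)
  expect_true(f$sma_partial); expect_false(f$fapar_partial)
  # wet-SPI escape needs both bounds
  expect_true(compute_flags(0.6, 0.1, 0, 0, thr)$wet_spi)
  expect_false(compute_flags(0.6, 0, 0, 0, thr)$wet_spi)
  expect_false(compute_flags(0.5, 0.1, 0, 0, thr)$wet_spi)
  # missing-input policy
  f <- compute_flags(NA, 0, -2, -2, thr)
  expect_true(f$missing); expect_true(is.na(f$spi))
  f <- compute_flags(0, 0, NA, NA, thr)
  expect_false(f$missing); expect_false(f$sma); expect_false(f$fapar)
})

test_that("flag triples map bijectively onto columns A..H", {
  combos <- expand.grid(spi = c(FALSE, TRUE), sma = c(FALSE, TRUE),
                        fapar = c(FALSE, TRUE))
  cols <- flags_column(combos$spi, combos$sma, combos$fapar)
  expect_setequal(cols, LETTERS[1:8])
  expect_equal(flags_column(FALSE, FALSE, FALSE), "A")
  expect_equal(flags_column(TRUE, FALSE, FALSE), "B")
  expect_equal(flags_column(FALSE, TRUE, FALSE), "C")
  expect_equal(flags_column(FALSE, FALSE, TRUE), "D")
  expect_equal(flags_column(FALSE, TRUE, TRUE), "E")
  expect_equal(flags_column(TRUE, TRUE, FALSE), "F")
  expect_equal(flags_column(TRUE, FALSE, TRUE), "G")
  expect_equal(flags_column(TRUE, TRUE, TRUE), "H")
})

test_that("classify_pixel implements the framework's stated cells", {
  tab <- load_decision_table()
  classes <- names(cdi_classes())
  # E, G, H -> Alert whatever the previous class
  for (prev in classes) {
    expect_equal(classify_pixel(flag_rec(sma = TRUE, fapar = TRUE), prev, tab),
                 "ALERT")
    expect_equal(classify_pixel(flag_rec(spi = TRUE, fapar = TRUE), prev, tab),
                 "ALERT")
    expect_equal(classify_pixel(flag_rec(spi = TRUE, sma = TRUE,
                                         fapar = TRUE), prev, tab), "ALERT")
    expect_equal(classify_pixel(flag_rec(spi = TRUE), prev, tab), "WATCH")
  }
  # column C: wet-SPI escape only from No drought / Recovery
  for (prev in c("NO_DROUGHT", "RECOVERY")) {
    expect_equal(classify_pixel(flag_rec(sma = TRUE, wet_spi = TRUE), prev,
                                tab), "NO_DROUGHT")
    expect_equal(classify_pixel(flag_rec(sma = TRUE), prev, tab), "WARNING")
  }
  expect_equal(classify_pixel(flag_rec(sma = TRUE, wet_spi = TRUE), "WATCH",
                              tab), "WARNING")
  # column A recovery logic
  expect_equal(classify_pixel(flag_rec(sma_partial = TRUE), "WARNING", tab),
               "TEMP_SM_RECOVERY")
  expect_equal(classify_pixel(flag_rec(fapar_partial = TRUE), "ALERT", tab),
               "TEMP_VEG_RECOVERY")
  expect_equal(classify_pixel(flag_rec(), "WATCH", tab), "RECOVERY")
  expect_equal(classify_pixel(flag_rec(), "RECOVERY", tab), "NO_DROUGHT")
  expect_equal(classify_pixel(flag_rec(), "NO_DROUGHT", tab), "NO_DROUGHT")
  # missing SPI -> missing pixel
  expect_true(is.na(classify_pixel(flag_rec(spi = NA), "WATCH", tab)))
})

test_that("classify_pixel and the compiled lookup agree over the full enumeration", {
  tab <- load_decision_table()
  lut <- compile_table(tab)
  classes <- names(cdi_classes())
  combos <- expand.grid(spi = c(FALSE, TRUE), sma = c(FALSE, TRUE),
                        fapar = c(FALSE, TRUE), wet = c(FALSE, TRUE),
                        smaP = c(FALSE, TRUE), fapP = c(FALSE, TRUE),
                        prev = classes, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    got <- classify_pixel(flag_rec(cb$spi, cb$sma, cb$fapar, cb$wet,
                                   cb$smaP, cb$fapP), cb$prev, tab)
    ci <- match(flags_column(cb$spi, cb$sma, cb$fapar), LETTERS)
    via_lut <- classes[lut[ci, match(cb$prev, classes), cb$wet + 1,
                           cb$smaP + 1, cb$fapP + 1] + 1L]
    expect_identical(got, via_lut)
  }
})

test_that("mask reductions collapse the reachable columns to A/B and A/B/C/F", {
  combos <- expand.grid(spi = c(FALSE, TRUE), sma = c(FALSE, TRUE),
                        fapar = c(FALSE, TRUE))
  for (i in 1:8) {
    fl <- flag_rec(combos$spi[i], combos$sma[i], combos$fapar[i],
                   sma_partial = TRUE, fapar_partial = TRUE)
    snow <- apply_mask_reduction(fl, snow = TRUE, crop_state = 2L,
                                 version = 4L)
    expect_true(flags_column(snow$spi, snow$sma, snow$fapar) %in% c("A", "B"))
    expect_false(snow$sma_partial); expect_false(snow$fapar_partial)
    off <- apply_mask_reduction(fl, snow = FALSE, crop_state = 1L,
                                version = 3L)
    expect_true(flags_column(off$spi, off$sma, off$fapar) %in%
                  c("A", "B", "C", "F"))
    # v2 applies no reduction; non-crop pixels are never FAPAR-reduced
    v2 <- apply_mask_reduction(fl, snow = TRUE, crop_state = 1L, version = 2L)
    expect_identical(v2, fl)
    nc <- apply_mask_reduction(fl, snow = FALSE, crop_state = 0L,
                               version = 4L)
    expect_identical(nc$fapar, fl$fapar)
  }
})

test_that("10,000 random pixel trajectories never take a forbidden transition", {
  tab <- load_decision_table()
  g <- grid_spec(100, 100, origin_lon = 0, origin_lat = 50)
  set.seed(99)
  zfield <- function() raster_field(matrix(rnorm(10000), 100, 100), g,
                                    time = dekad(2021, 1))
  maps <- list(cdi_init_map(g))
  snow <- raster_field(matrix(runif(10000) < 0.2, 100, 100), g)
  crop <- raster_field(matrix(sample(0:2, 10000, TRUE), 100, 100), g)
  lut <- compile_table(tab)
  for (step in 1:12) {
    maps[[step + 1]] <- cdi_step(maps[[step]], zfield(), zfield(), zfield(),
                                 zfield(), snow = snow, crop = crop,
                                 version = 4L, table = tab, lut = lut)
  }
  aud <- audit_transitions(maps, tab)
  expect_equal(aud$n_illegal, 0L)
  expect_equal(aud$n_drought_to_no_drought, 0L)
  expect_equal(sum(aud$matrix), 10000L * 12L)
})

test_that("warning/alert never occur on snow pixels in v4 random bundles", {
  g <- grid_spec(50, 50, origin_lon = 0, origin_lat = 50)
  set.seed(123)
  zf <- function() raster_field(matrix(rnorm(2500, sd = 1.5), 50, 50), g,
                                time = dekad(2021, 1))
  snow <- raster_field(matrix(runif(2500) < 0.5, 50, 50), g)
  prev <- raster_field(matrix(sample(0:6, 2500, TRUE), 50, 50), g)
  out <- cdi_step(prev, zf(), zf(), zf(), zf(), snow = snow, version = 4L)
  on_snow <- out$values[snow$values]
  expect_false(any(on_snow %in% cdi_classes()[c("WARNING", "ALERT")]))
})

test_that("version differences are strictly mask-local", {
  g <- grid_spec(30, 30, origin_lon = 0, origin_lat = 50)
  set.seed(7)
  zf <- function() raster_field(matrix(rnorm(900, sd = 1.2), 30, 30), g,
                                time = dekad(2021, 20))
  snow <- raster_field(matrix(runif(900) < 0.3, 30, 30), g)
  crop <- raster_field(matrix(sample(0:2, 900, TRUE), 30, 30), g)
  prev <- raster_field(matrix(sample(0:6, 900, TRUE), 30, 30), g)
  s1 <- zf(); s3 <- zf(); sm <- zf(); fp <- zf()
  runs <- lapply(c(2L, 3L, 4L), function(v)
    cdi_step(prev, s1, s3, sm, fp, snow = snow, crop = crop, version = v))
  unmasked <- !snow$values & crop$values != 1L
  expect_identical(runs[[1]]$values[unmasked], runs[[3]]$values[unmasked])
  expect_identical(runs[[2]]$values[unmasked], runs[[3]]$values[unmasked])
  # v3 ignores snow but applies the crop reduction
  crop_only <- !snow$values
  expect_identical(runs[[2]]$values[crop_only & crop$values == 1L],
                   cdi_step(prev, s1, s3, sm, fp, snow = NULL, crop = crop,
                            version = 3L)$values[crop_only & crop$values == 1L])
})

test_that("transition matrices count flows between consecutive maps", {
  g <- small_grid(2, 2)
  mk <- function(...) raster_field(matrix(c(...), 2, 2), g)
  const <- list(mk(0, 1, 2, 3), mk(0, 1, 2, 3))
  tm <- transition_matrix(const)
  expect_equal(sum(diag(tm)), 4L)
  expect_equal(sum(tm), 4L)
  moved <- list(mk(1, 0, 0, 0), mk(2, 0, 0, 0))
  tm2 <- transition_matrix(moved)
  expect_equal(tm2["WATCH", "WARNING"], 1L)
  expect_equal(sum(tm2), 4L)
  expect_error(transition_matrix(const[1]))
})
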