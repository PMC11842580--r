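#' Synthetic input scenes with injectable drought events
#'
#' A fully synthetic, seed-reproducible generator for every input the CDI
#' pipeline consumes: zero-inflated gamma daily precipitation with a
#' seasonal cycle, a daily soil moisture index responding to dekadal
#' precipitation anomalies through a first-order autoregression (squashed to
#' `[0, 1]`), seasonal 8-day FAPAR composites with quality flags damped by
#' soil-moisture deficit, daily NDSI snow fields with a latitude-dependent
#' snow season and cloud gaps, and a crop layout (fraction, rangeland,
#' SOS/EOS phenology). Drought events scale precipitation over a region and
#' window and propagate to soil moisture and vegetation with configurable
#' lags, emulating the Watch -> Warning -> Alert cascade.
#'
#' @name synthetic
NULL

dekad_serial <- function(d) d$year * 36L + d$ordinal
serial_dekad <- function(s) dekad((s - 1L) %/% 36L, (s - 1L) %% 36L + 1L)

#' Scene configuration
#'
#' Defaults mirror the operational study conditions: SPI baseline
#' 1981-2010, soil-moisture baseline 1995 onward, FAPAR baseline 2012
#' onward, evaluation year 2021, 1/24-degree cells. The grid is a 20 x 20
#' high-latitude block so the snow season has a latitudinal gradient.
#'
#' @param grid A [grid_spec()].
#' @param spi_baseline_years,sma_baseline_years,fapar_baseline_years
#'   Integer year vectors for the three climatologies.
#' @param eval_years Years to evaluate (inputs for these years are
#'   generated for all variables).
#' @param seed Integer seed; fully determines the scene.
#' @param precip List: `wet_prob` (mean wet-day probability), `wet_amp`
#'   (seasonal amplitude, wetter winters), `shape` (gamma shape of wet-day
#'   amounts), `scale` (mean gamma scale, mm), `scale_amp` (seasonal
#'   amplitude of the scale).
#' @param smi List: `rho` (dekadal AR(1) memory), `coupling` (weight of the
#'   standardized dekadal precipitation anomaly), `noise_sd` (dekadal
#'   innovation), `alpha` (logit-scale gain), `mean` and `amp` (seasonal
#'   mean soil wetness), `daily_sd` (daily observation noise).
#' @param fapar List: `min`, `max` (seasonal FAPAR range), `peak_dekad`
#'   (dekad-of-year of the seasonal maximum), `damp` (deficit damping per
#'   unit of soil-moisture state), `noise_sd`, `cloud_prob` (probability of
#'   a cloud quality flag).
#' @param snow List: `p_winter` (snow probability per day in core winter at
#'   the northern edge), `p_shoulder` (shoulder dekads), `lat_extent`
#'   (fraction of rows, from the north edge, over which the probability
#'   decays to zero), `cloud_prob`, `cloud_code`.
#' @param crop List: `fraction_high`, `fraction_low` (percent), `sos`,
#'   `eos`, `winter_sos`, `winter_eos` (dekads-of-year).
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(grid = grid_spec(20, 20, origin_lon = 5,
                                          origin_lat = 62),
                         spi_baseline_years = 1981:2010,
                         sma_baseline_years = 1995:2020,
                         fapar_baseline_years = 2012:2020,
                         eval_years = 2021L,
                         seed = 1L,
                         precip = list(wet_prob = 0.5, wet_amp = 0.15,
                                       shape = 0.9, scale = 6,
                                       scale_amp = 0.2),
                         smi = list(rho = 0.5, coupling = 0.05,
                                    noise_sd = 0.2, alpha = 1.2,
                                    mean = 0.55, amp = 0.08,
                                    daily_sd = 0.01),
                         fapar = list(min = 0.15, max = 0.6,
                                      peak_dekad = 19, damp = 0.015,
                                      noise_sd = 0.04, cloud_prob = 0.1),
                         snow = list(p_winter = 0.85, p_shoulder = 0.4,
                                     lat_extent = 2 / 3, cloud_prob = 0.15,
                                     cloud_code = 250L),
                         crop = list(fraction_high = 40, fraction_low = 0.5,
                                     sos = 10L, eos = 30L,
                                     winter_sos = 33L, winter_eos = 9L)) {
  structure(list(grid = grid, spi_baseline_years = spi_baseline_years,
                 sma_baseline_years = sma_baseline_years,
                 fapar_baseline_years = fapar_baseline_years,
                 eval_years = as.integer(eval_years), seed = as.integer(seed),
                 precip = precip, smi = smi, fapar = fapar, snow = snow,
                 crop = crop),
            class = "scene_config")
}

#' Injectable drought event
#'
#' During `[start, end]` the event multiplies daily precipitation in its
#' region by `multiplier`. The soil-moisture state receives an additional
#' deficit forcing over the window lagged by `sm_lag` dekads, and FAPAR is
#' suppressed over the window lagged by `veg_lag` dekads, encoding the
#' propagation chain SPI -> SMA -> FAPAR. Forcings default to scale with
#' the precipitation deficit `(1 - multiplier)`; override them to build
#' e.g. a vegetation-only anomaly (`multiplier = 1`, `veg_damp > 0`).
#'
#' @param rows,cols Integer index vectors defining the affected region.
#' @param start,end [dekad()]s bounding the precipitation deficit window.
#' @param multiplier Precipitation multiplier in `[0, 1]`.
#' @param sm_lag,veg_lag Propagation lags in dekads (>= 0).
#' @param sm_forcing Deficit added to the soil-moisture state (logit-scale
#'   units) during the lagged window.
#' @param veg_damp Fractional FAPAR suppression during the lagged window.
#' @return A list of class `"drought_event"`.
#' @export
drought_event <- function(rows, cols, start, end, multiplier = 0.2,
                          sm_lag = 4L, veg_lag = 7L,
                          sm_forcing = NULL, veg_damp = NULL) {
  stopifnot(multiplier >= 0, multiplier <= 1, sm_lag >= 0, veg_lag >= 0,
            dekad_serial(start) <= dekad_serial(end))
  if (is.null(sm_forcing)) sm_forcing <- 2.5 * (1 - multiplier)
  if (is.null(veg_damp)) veg_damp <- 0.55 * (1 - multiplier)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 start = start, end = end, multiplier = multiplier,
                 sm_lag = as.integer(sm_lag), veg_lag = as.integer(veg_lag),
                 sm_forcing = sm_forcing, veg_damp = veg_damp),
            class = "drought_event")
}

# pixel indices (column-major) of an event region
event_pixels <- function(ev, grid) {
  as.vector(outer(ev$rows, (ev$cols - 1L) * grid$n_rows, `+`))
}

# seasonal helpers (dekad-of-year 1..36)
season_cos <- function(o, peak) cos(2 * pi * (o - peak) / 36)

#' Generate a full synthetic input scene
#'
#' @param config A [scene_config()].
#' @param events List of [drought_event()]s (events must fall inside the
#'   evaluation years).
#' @return A list with elements `precip` and `smi` ([daily_stack()]s),
#'   `fapar` (list of [fapar_composite()]s), `ndsi` ([daily_stack()] of raw
#'   NDSI codes over the evaluation years), `crop_fraction`
#'   ([raster_field()]), `rangeland`, `sos`, `eos` (matrices), plus the
#'   `config` and `events` used. Bit-identical for identical seed/config.
#' @export
generate_scene <- function(config = scene_config(), events = list()) {
  if (inherits(events, "drought_event")) events <- list(events)
  set.seed(config$seed)
  g <- config$grid
  np <- g$n_rows * g$n_cols

  p_first <- min(config$spi_baseline_years) - 1L
  p_last <- max(config$eval_years)
  dates <- seq(as.Date(sprintf("%04d-01-01", p_first)),
               as.Date(sprintf("%04d-12-31", p_last)), by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))

  # --- daily precipitation: zero-inflated gamma, seasonal, wetter winters
  pc <- config$precip
  wetp <- pc$wet_prob + pc$wet_amp * cos(2 * pi * (doy - 15) / 365.25)
  scl <- pc$scale * (1 + pc$scale_amp * cos(2 * pi * (doy - 15) / 365.25))
  wet <- matrix(stats::runif(np * nd), np, nd) <
    matrix(wetp, np, nd, byrow = TRUE)
  amt <- matrix(stats::rgamma(np * nd, shape = pc$shape), np, nd) *
    matrix(scl, np, nd, byrow = TRUE)
  precip_v <- wet * amt
  for (ev in events) {
    px <- event_pixels(ev, g)
    in_win <- dates >= dekad_start(ev$start) & dates <= dekad_end(ev$end)
    precip_v[px, in_win] <- precip_v[px, in_win] * ev$multiplier
  }

  # --- dekad bookkeeping over the generated span
  dk_first <- dekad(p_first, 1L); dk_last <- dekad(p_last, 36L)
  dks <- dekad_seq(dk_first, dk_last)
  n_dk <- length(dks)
  dk_ord <- vapply(dks, function(d) d$ordinal, integer(1))
  dk_year <- vapply(dks, function(d) d$year, integer(1))
  # day -> dekad index within dks (every generated day is covered)
  day_dk <- integer(nd)
  pos <- 1L
  for (j in seq_len(n_dk)) {
    n_j <- dekad_day_count(dks[[j]])
    day_dk[pos:(pos + n_j - 1L)] <- j
    pos <- pos + n_j
  }

  # dekadal precipitation totals and their climatological anomaly (per
  # dekad-of-year mean/sd over the SMA baseline years: event-free by
  # construction since events live in the evaluation years)
  ptot <- vapply(seq_len(n_dk), function(j)
    rowSums(precip_v[, day_dk == j, drop = FALSE]), numeric(np))
  base_cols <- dk_year %in% config$sma_baseline_years
  a <- matrix(0, np, n_dk)
  for (o in 1:36) {
    ref <- ptot[, base_cols & dk_ord == o, drop = FALSE]
    mu <- rowMeans(ref)
    sd_o <- apply(ref, 1, stats::sd)
    sd_o[sd_o < 1e-9] <- 1e-9
    sel <- which(dk_ord == o)
    a[, sel] <- (ptot[, sel, drop = FALSE] - mu) / sd_o
  }

  # --- soil moisture state: dekadal AR(1) on the precipitation anomaly
  sm <- config$smi
  w <- matrix(0, np, n_dk)
  innov <- matrix(stats::rnorm(np * n_dk, sd = sm$noise_sd), np, n_dk)
  for (j in seq_len(n_dk)) {
    prev <- if (j == 1L) 0 else w[, j - 1L]
    w[, j] <- sm$rho * prev + sm$coupling * a[, j] + innov[, j]
  }
  for (ev in events) {
    px <- event_pixels(ev, g)
    s0 <- dekad_serial(ev$start) + ev$sm_lag
    s1 <- dekad_serial(ev$end) + ev$sm_lag
    hit <- which(dk_year * 36L + dk_ord >= s0 & dk_year * 36L + dk_ord <= s1)
    w[px, hit] <- w[px, hit] - ev$sm_forcing
  }

  # --- daily SMI (only stored from just before the SMA baseline onward)
  smi_first <- min(config$sma_baseline_years)
  smi_keep <- dates >= as.Date(sprintf("%04d-01-01", smi_first))
  base_wet <- sm$mean + sm$amp * cos(2 * pi * (dk_ord - 3) / 36)
  smi_dek <- stats::plogis(stats::qlogis(
    matrix(base_wet, np, n_dk, byrow = TRUE)) + sm$alpha * w)
  smi_v <- smi_dek[, day_dk[smi_keep], drop = FALSE] +
    matrix(stats::rnorm(np * sum(smi_keep), sd = sm$daily_sd),
           np, sum(smi_keep))
  smi_v <- pmin(pmax(smi_v, 0), 1)

  # --- 8-day FAPAR composites with quality flags
  fp <- config$fapar
  fap_years <- c(config$fapar_baseline_years, config$eval_years)
  composites <- list()
  for (y in sort(unique(fap_years))) {
    year_len <- as.integer(as.Date(sprintf("%04d-12-31", y)) -
                             as.Date(sprintf("%04d-01-01", y))) + 1L
    for (start_doy in seq(1L, 361L, by = 8L)) {
      n_days <- min(8L, year_len - start_doy + 1L)
      start <- as.Date(sprintf("%04d-01-01", y)) + (start_doy - 1L)
      mid <- as.numeric(start) + (n_days - 1) / 2
      j <- day_dk[match(floor(mid), as.numeric(dates))]
      # seasonal baseline continuous in day-of-year (a dekad-stepped curve
      # would alias leap-year shifts into spurious grid-wide anomalies)
      doy_mid <- start_doy + (n_days - 1) / 2
      peak_doy <- (fp$peak_dekad - 0.5) * 365.25 / 36
      f0 <- fp$min + (fp$max - fp$min) * 0.5 *
        (1 + cos(2 * pi * (doy_mid - peak_doy) / 365.25))
      val <- f0 * (1 - fp$damp * pmax(0, -w[, j]))
      for (ev in events) {
        s <- dk_year[j] * 36L + dk_ord[j]
        if (s >= dekad_serial(ev$start) + ev$veg_lag &&
            s <= dekad_serial(ev$end) + ev$veg_lag)
          val[event_pixels(ev, g)] <- val[event_pixels(ev, g)] *
            (1 - ev$veg_damp)
      }
      val <- pmin(pmax(val + stats::rnorm(np, sd = fp$noise_sd), 0), 1)
      flags <- matrix(ifelse(stats::runif(np) < fp$cloud_prob, 2L, 0L),
                      g$n_rows, g$n_cols)
      composites[[length(composites) + 1L]] <-
        fapar_composite(px_to_matrix(val, g), g, start, flags, n_days)
    }
  }

  # --- daily NDSI over the evaluation years (lat- and season-dependent)
  sn <- config$snow
  ndsi_dates <- dates[dk_year[day_dk] %in% config$eval_years]
  nnd <- length(ndsi_dates)
  row_idx <- rep(seq_len(g$n_rows), g$n_cols)
  lat_fac <- pmax(0, 1 - (row_idx - 1) / (sn$lat_extent * g$n_rows))
  ords <- dk_ord[day_dk[dk_year[day_dk] %in% config$eval_years]]
  seas <- ifelse(ords <= 6 | ords >= 31, sn$p_winter,
                 ifelse(ords <= 9 | ords >= 28, sn$p_shoulder, 0))
  p_snow <- outer(lat_fac, seas)
  snowing <- matrix(stats::runif(np * nnd), np, nnd) < p_snow
  ndsi_v <- matrix(0, np, nnd)
  ndsi_v[snowing] <- round(stats::runif(sum(snowing), 40, 90))
  cloudy <- matrix(stats::runif(np * nnd), np, nnd) < sn$cloud_prob
  ndsi_v[cloudy] <- sn$cloud_code

  # --- crop layout: high-fraction west half, marginal NE block, a
  # rangeland strip in the far south rows, winter crops in the SW corner
  cr <- config$crop
  frac <- matrix(0, g$n_rows, g$n_cols)
  frac[, seq_len(floor(g$n_cols / 2))] <- cr$fraction_high
  ne_rows <- seq_len(max(1L, floor(g$n_rows / 4)))
  ne_cols <- (g$n_cols - max(1L, floor(g$n_cols / 4)) + 1L):g$n_cols
  frac[ne_rows, ne_cols] <- cr$fraction_low
  rangeland <- matrix(FALSE, g$n_rows, g$n_cols)
  rangeland[g$n_rows, ] <- TRUE
  sos <- matrix(cr$sos, g$n_rows, g$n_cols)
  eos <- matrix(cr$eos, g$n_rows, g$n_cols)
  sw_rows <- (g$n_rows - max(1L, floor(g$n_rows / 5)) + 1L):g$n_rows
  sw_cols <- seq_len(max(1L, floor(g$n_cols / 5)))
  sos[sw_rows, sw_cols] <- cr$winter_sos
  eos[sw_rows, sw_cols] <- cr$winter_eos

  list(
    precip = daily_stack(precip_v, dates, g, "precip"),
    smi = daily_stack(smi_v, dates[smi_keep], g, "smi"),
    fapar = composites,
    ndsi = daily_stack(ndsi_v, ndsi_dates, g, "ndsi"),
    crop_fraction = raster_field(frac, g, "crop_fraction"),
    rangeland = rangeland, sos = sos, eos = eos,
    config = config, events = events
  )
}

#' Named golden fixtures for regression testing
#'
#' Small, fast scenes with declared qualitative expectations:
#' `"nordic-snow"` (snowy winter; under CDIv4 snow pixels never emit
#' Warning/Alert), `"france-offseason"` (vegetation-only anomaly on
#' out-of-season cropland; Alert under CDIv2 but not under v3/v4) and
#' `"all-zero"` (an all-dry degenerate scene exercising the
#' invalid-climatology paths).
#'
#' @param name Fixture identifier.
#' @return A list with `config`, `events` and an `expectations` list.
#' @export
golden_fixture <- function(name = c("nordic-snow", "france-offseason",
                                    "all-zero")) {
  name <- match.arg(name)
  small <- grid_spec(8, 8, origin_lon = 5, origin_lat = 62)
  base_cfg <- function(...)
    scene_config(grid = small, spi_baseline_years = 1996:2015,
                 sma_baseline_years = 2001:2015,
                 fapar_baseline_years = 2008:2015, eval_years = 2016L,
                 seed = 42L, ...)
  switch(name,
    "nordic-snow" = list(
      config = base_cfg(),
      events = list(drought_event(1:4, 1:8, dekad(2016, 1), dekad(2016, 4),
                                  multiplier = 0.1, sm_lag = 0, veg_lag = 0)),
      expectations = list(no_warning_alert_on_snow_v4 = TRUE)),
    "france-offseason" = list(
      # temperate scene: no snow season, so the v2/v4 contrast is purely the
      # crop mask's doing
      config = base_cfg(snow = list(p_winter = 0, p_shoulder = 0,
                                    lat_extent = 2 / 3, cloud_prob = 0.15,
                                    cloud_code = 250L)),
      # a late-season drought drives cropland (sos 10, eos 30) into Alert;
      # the vegetation anomaly then lingers past EOS (dekads 31..36), where
      # only the unmasked v2 keeps the Alert alive through FAPAR alone
      events = list(
        drought_event(1:8, 1:4, dekad(2016, 22), dekad(2016, 27),
                      multiplier = 0.2, sm_lag = 2, veg_lag = 4),
        drought_event(1:8, 1:4, dekad(2016, 28), dekad(2016, 36),
                      multiplier = 1, sm_lag = 0, veg_lag = 0,
                      sm_forcing = 0, veg_damp = 0.6)),
      expectations = list(v2_has_more_alerts_than_v4 = TRUE)),
    "all-zero" = list(
      config = {
        cfg <- base_cfg()
        cfg$precip$wet_prob <- 0; cfg$precip$wet_amp <- 0
        cfg
      },
      events = list(),
      expectations = list(spi_climatology_invalid = TRUE))
  )
}
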