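# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

small_grid <- function(nr = 6, nc = 6)
  grid_spec(nr, nc, origin_lon = 5, origin_lat = 62)

# a 12x12 scene with one 9-dekad severe precipitation deficit, plus its
# classifier runs for the three CDI versions
event_scene <- function() cached("event_scene", {
  cfg <- scene_config(grid = grid_spec(12, 12, origin_lon = 5,
                                       origin_lat = 62), seed = 7L)
  ev <- drought_event(3:8, 3:8, dekad(2021, 10), dekad(2021, 18))
  generate_scene(cfg, list(ev))
})

event_run <- function(version = 4L)
  cached(paste0("event_run_v", version),
         run_pipeline(event_scene(), version = version))

# quick flag record for classify_pixel
flag_rec <- function(spi = FALSE, sma = FALSE, fapar = FALSE,
                     wet_spi = FALSE, sma_partial = FALSE,
                     fapar_partial = FALSE)
  list(spi = spi, sma = sma, fapar = fapar, wet_spi = wet_spi,
       sma_partial = sma_partial, fapar_partial = fapar_partial)

# constant-valued raster field on a grid
const_field <- function(x, grid, variable = "", time = NULL)
  raster_field(matrix(x, grid$n_rows, grid$n_cols), grid,
               variable = variable, time = time)

# k snow days then no-snow (or all missing), on a one-pixel grid
snow_days_fixture <- function(k, n_days = 10L, g = small_grid(1, 1),
                              missing_all = FALSE) {
  lapply(seq_len(n_days), function(i) {
    v <- if (missing_all) NA_integer_ else if (i <= k) 1L else 0L
    raster_field(matrix(v, 1, 1), g,
                 valid = matrix(TRUE, 1, 1), variable = "snow_daily")
  })
}

# daily stack of iid draws (with optional zero inflation), for oracles
random_stack <- function(grid, dates, seed, zero_p = 0.5, shape = 0.9,
                         scale = 6) {
  set.seed(seed)
  np <- grid$n_rows * grid$n_cols
  nd <- length(dates)
  v <- matrix(stats::rgamma(np * nd, shape = shape, scale = scale), np, nd)
  v[matrix(stats::runif(np * nd), np, nd) < zero_p] <- 0
  daily_stack(v, dates, grid, "precip")
}
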