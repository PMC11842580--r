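#' Standardized Precipitation Index (SPI)
#'
#' The SPI expresses the precipitation accumulated over a timescale ending
#' at dekad T as a standard normal deviate, by fitting a gamma distribution
#' to the accumulation's climatology over a reference baseline and mapping
#' the current value through the fitted CDF into the normal quantile
#' function. Two short timescales are used here: ~30 days (SPI-1, extreme
#' threshold -2) and ~90 days (SPI-3, moderate threshold -1), with a 30-year
#' reference period (default 1981-2010).
#'
#' Because short accumulations can be exactly zero, the fit is a mixed
#' distribution `H(x) = q + (1 - q) G(x; k, theta)` where `q` is the
#' probability of a zero total (estimated as the zero fraction) and `G` the
#' gamma CDF fitted to the positive totals. A zero total is mapped through
#' `z = qnorm(q / 2)` (center-of-mass convention, avoids the bias of
#' mapping all zeros to `H(0) = q`).
#'
#' @name spi
NULL

spi_window_days <- function(scale) {
  stopifnot(scale %in% c(1L, 3L))
  if (scale == 1L) 30L else 90L
}

#' Accumulate daily precipitation over an SPI window
#'
#' Sums daily precipitation per pixel over the window terminating at the
#' last day of the terminal dekad. In `"days"` mode (default) the window is
#' exactly `window_days` days; in `"months"` mode it is the
#' `round(window_days / 30)` complete calendar months ending with the
#' terminal dekad's month (so the value is shared by all three dekads of
#' that month). A pixel is invalid if any contributing day is invalid.
#'
#' @param precip A [daily_stack()] of non-negative daily totals (mm).
#' @param terminal [dekad()] at which the window ends.
#' @param window_days Window length in days (30 or 90 for SPI-1/SPI-3).
#' @param mode `"days"` (rolling daily window) or `"months"`.
#' @return A [raster_field()] of accumulated precipitation.
#' @export
accumulate_precipitation <- function(precip, terminal, window_days = 30L,
                                     mode = c("days", "months")) {
  mode <- match.arg(mode)
  stopifnot(window_days > 0)
  if (mode == "days") {
    last <- dekad_end(terminal)
    first <- last - (window_days - 1L)
  } else {
    n_months <- max(1L, as.integer(round(window_days / 30)))
    m <- terminal$month; y <- terminal$year
    last <- as.Date(sprintf("%04d-%02d-%02d", y, m, days_in_month(y, m)))
    fm <- m - n_months + 1L; fy <- y
    while (fm < 1L) { fm <- fm + 12L; fy <- fy - 1L }
    first <- as.Date(sprintf("%04d-%02d-01", fy, fm))
  }
  idx <- stack_date_cols(precip, first, last, "the accumulation window")
  vals <- precip$values[, idx, drop = FALSE]
  if (any(vals < 0, na.rm = TRUE)) stop("negative precipitation values")
  total <- rowSums(vals)                      # NA if any day invalid
  raster_field(px_to_matrix(total, precip$grid), precip$grid,
               variable = sprintf("precip_accum_%dd",
                                  as.integer(last - first) + 1L),
               time = terminal)
}

# Vectorized gamma MLE over rows of a (pixels x years) matrix of positive
# totals. Thom's approximation initializes the shape, then Newton iterations
# on d/dk [log k - digamma(k) - s] with s = log(mean) - mean(log). Rows where
# s <= 0 (e.g. near-constant samples) fall back to moment estimates.
fit_gamma_rows <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ml <- rowMeans(log(x), na.rm = TRUE)
  s <- log(m) - ml
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:25) {
    f <- log(k) - digamma(k) - s
    df <- 1 / k - trigamma(k)
    step <- f / df
    k_new <- k - step
    k <- ifelse(is.finite(k_new) & k_new > 0, k_new, k)
  }
  v <- (rowMeans(x^2, na.rm = TRUE) - m^2) * n / pmax(n - 1, 1)
  mom_k <- m^2 / v
  use_mom <- !is.finite(k) | k <= 0 | !is.finite(s) | s <= 0
  k[use_mom] <- mom_k[use_mom]
  theta <- m / k
  bad <- !is.finite(k) | k <= 0 | !is.finite(theta) | theta <= 0
  k[bad] <- NA_real_; theta[bad] <- NA_real_
  list(shape = k, scale = theta)
}

#' Fit the per-pixel gamma climatology of accumulated precipitation
#'
#' Given the accumulation for one fixed dekad-of-year across the baseline
#' years, estimates per pixel the zero-total probability `q` and the gamma
#' parameters of the positive totals (maximum likelihood with a moment
#' fallback). Pixels with fewer than `min_years` usable years or fewer than
#' `min_positive` positive totals are flagged invalid.
#'
#' @param totals `n_pixels x n_years` matrix of accumulations (`NA` =
#'   invalid year), or a list of [raster_field()]s (one per baseline year).
#' @param grid [grid_spec()] (required when `totals` is a matrix).
#' @param min_years Minimum usable baseline years per pixel (default 20).
#' @param min_positive Minimum positive totals per pixel (default 10).
#' @return An object of class `"gamma_climatology"`: per-pixel vectors
#'   `shape`, `scale`, `q`, `n_years`, and logical `valid`.
#' @export
fit_gamma_climatology <- function(totals, grid = NULL, min_years = 20L,
                                  min_positive = 10L) {
  if (is.list(totals) && !is.matrix(totals)) {
    stopifnot(length(totals) > 0)
    grid <- totals[[1]]$grid
    totals <- vapply(totals, function(f) as.vector(f$values),
                     numeric(grid$n_rows * grid$n_cols))
  }
  stopifnot(is.matrix(totals), !is.null(grid))
  if (ncol(totals) == 0) stop("empty baseline")
  n_eff <- rowSums(!is.na(totals))
  n_zero <- rowSums(totals == 0, na.rm = TRUE)
  q <- ifelse(n_eff > 0, n_zero / n_eff, NA_real_)
  pos <- totals
  pos[!is.na(pos) & pos == 0] <- NA
  n_pos <- rowSums(!is.na(pos))
  fit <- fit_gamma_rows(pos)
  valid <- n_eff >= min_years & n_pos >= min_positive &
    is.finite(fit$shape) & is.finite(fit$scale) & !is.na(q) & q < 1
  structure(list(shape = fit$shape, scale = fit$scale, q = q,
                 n_years = n_eff, valid = valid, grid = grid),
            class = "gamma_climatology")
}

#' Transform accumulated precipitation to an SPI z-score
#'
#' `z = qnorm(q + (1 - q) * pgamma(total, shape, scale))` for positive
#' totals, `z = qnorm(q / 2)` for zero totals, clamped to `[-z_max, z_max]`.
#' Strictly increasing in the total at a fixed fit.
#'
#' @param total Accumulated precipitation (vector).
#' @param shape,scale,q Gamma fit parameters (recycled against `total`).
#' @param z_max Absolute clamp on the output (default 3.5).
#' @return Numeric vector of z-scores.
#' @export
spi_value <- function(total, shape, scale, q = 0, z_max = 3.5) {
  n <- length(total)
  q <- rep_len(q, n); shape <- rep_len(shape, n); scale <- rep_len(scale, n)
  p <- q + (1 - q) * stats::pgamma(total, shape = shape, scale = scale)
  zero <- !is.na(total) & total == 0
  p[zero] <- q[zero] / 2
  z <- stats::qnorm(p)
  pmin(pmax(z, -z_max), z_max)
}

#' Build the SPI gamma climatology for a set of dekads-of-year
#'
#' Accumulates the baseline years' precipitation for each requested
#' dekad-of-year and fits [fit_gamma_climatology()] to each.
#'
#' @param precip A [daily_stack()] covering the baseline years (plus the
#'   window lead-in before the first year).
#' @param scale SPI timescale: 1 (~30 days) or 3 (~90 days).
#' @param baseline_years Integer vector of baseline years (default
#'   `1981:2010`).
#' @param ordinals Dekads-of-year to fit (default all 36).
#' @param mode Accumulation mode, see [accumulate_precipitation()].
#' @inheritParams fit_gamma_climatology
#' @return An object of class `"spi_climatology"`: a list of per-ordinal
#'   gamma fits plus the scale/mode/baseline metadata.
#' @export
spi_climatology <- function(precip, scale = 1L, baseline_years = 1981:2010,
                            ordinals = 1:36, mode = c("days", "months"),
                            min_years = 20L, min_positive = 10L) {
  mode <- match.arg(mode)
  w <- spi_window_days(scale)
  fits <- vector("list", 36L)
  for (o in ordinals) {
    totals <- vapply(baseline_years, function(y) {
      as.vector(accumulate_precipitation(precip, dekad(y, o), w, mode)$values)
    }, numeric(precip$grid$n_rows * precip$grid$n_cols))
    fits[[o]] <- fit_gamma_climatology(totals, precip$grid,
                                       min_years = min_years,
                                       min_positive = min_positive)
  }
  structure(list(scale = as.integer(scale), mode = mode,
                 baseline_years = baseline_years, fits = fits,
                 grid = precip$grid),
            class = "spi_climatology")
}

#' SPI map for one dekad
#'
#' Accumulates the current precipitation over the scale's window ending at
#' `d` and standardizes it through the fitted climatology for that
#' dekad-of-year.
#'
#' @param precip A [daily_stack()] covering the window ending at `d`.
#' @param d Terminal [dekad()].
#' @param clim An [spi_climatology()] containing a fit for `d$ordinal`.
#' @param z_max Absolute clamp on the output z-scores.
#' @return A [raster_field()] named `"spi1"` or `"spi3"`; pixels with an
#'   invalid fit or accumulation are invalid.
#' @export
spi_field <- function(precip, d, clim, z_max = 3.5) {
  fit <- clim$fits[[d$ordinal]]
  if (is.null(fit)) stop("no SPI climatology fitted for dekad-of-year ",
                         d$ordinal)
  stopifnot(grids_equal(precip$grid, clim$grid))
  acc <- accumulate_precipitation(precip, d, spi_window_days(clim$scale),
                                  clim$mode)
  total <- as.vector(acc$values)
  z <- spi_value(total, fit$shape, fit$scale, fit$q, z_max)
  z[!fit$valid] <- NA_real_
  raster_field(px_to_matrix(z, precip$grid), precip$grid,
               variable = sprintf("spi%d", clim$scale), time = d)
}
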