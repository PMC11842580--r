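#' Z-score anomalies of dekadal indicators
#'
#' Soil moisture and vegetation enter the CDI as standardized anomalies:
#' `z = (I - mu) / sigma`, where `mu` and `sigma` are the per-pixel,
#' per-dekad mean and standard deviation over a baseline set of years. A
#' value near 0 means near-normal conditions; values at or below -1 flag an
#' abnormal deficit. The non-standardized indicator `I` is the dekadal mean
#' of the daily Soil Moisture Index (SMA) or the dekadal composite of the
#' 8-day FAPAR product (FAPAR anomaly).
#'
#' @name anomalies
NULL

#' Aggregate daily SMI to a dekadal mean
#'
#' `I = sum(SMI_n) / N` over the `N` days of the dekad (the daily SMI is the
#' 18:00 value of the soil moisture index, in `[0, 1]`). A pixel is invalid
#' when fewer than `min_days` of the dekad's days are valid; otherwise the
#' mean is taken over the valid days.
#'
#' @param smi A [daily_stack()] of SMI values in `[0, 1]`.
#' @param d A [dekad()] fully covered by `smi`.
#' @param min_days Minimum valid days per pixel (default 7).
#' @return A [raster_field()] named `"smi_dekad"`.
#' @export
aggregate_smi_dekad <- function(smi, d, min_days = 7L) {
  cols <- stack_dekad_cols(smi, d)
  vals <- smi$values[, cols, drop = FALSE]
  if (any(vals < 0 | vals > 1, na.rm = TRUE))
    stop("SMI values outside [0, 1]")
  n_ok <- rowSums(!is.na(vals))
  m <- rowMeans(vals, na.rm = TRUE)
  m[n_ok < min_days] <- NA_real_
  raster_field(px_to_matrix(m, smi$grid), smi$grid,
               variable = "smi_dekad", time = d)
}

#' Per-pixel baseline climatology (mean and standard deviation)
#'
#' For one fixed dekad-of-year, computes the per-pixel sample mean and
#' standard deviation (n-1 denominator) over the baseline years. A pixel is
#' valid only where at least `min_years` years are usable and the standard
#' deviation exceeds `sigma_min` (a degenerate, constant pixel cannot be
#' standardized).
#'
#' @param fields List of [raster_field()]s, one per baseline year, same grid
#'   and dekad-of-year.
#' @param min_years Minimum usable years per pixel (default 5; soil-moisture
#'   and vegetation archives are short, and short baselines still identify
#'   deficits usefully).
#' @param sigma_min Lower guard on sigma (default 1e-6).
#' @return An object of class `"dekad_climatology"` with per-pixel `mean`,
#'   `sd`, `n_years` and `valid` vectors.
#' @export
build_climatology <- function(fields, min_years = 5L, sigma_min = 1e-6) {
  stopifnot(length(fields) > 0)
  grid <- fields[[1]]$grid
  x <- vapply(fields, function(f) {
    stopifnot(grids_equal(f$grid, grid))
    as.vector(f$values)
  }, numeric(grid$n_rows * grid$n_cols))
  n <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - mu)^2, na.rm = TRUE)
  sdv <- sqrt(ss / pmax(n - 1, 1))
  sdv[n < 2] <- NA_real_
  valid <- n >= min_years & is.finite(sdv) & sdv > sigma_min
  mu[n == 0] <- NA_real_
  structure(list(mean = mu, sd = sdv, n_years = n, valid = valid,
                 grid = grid),
            class = "dekad_climatology")
}

#' Standardize a field against its climatology
#'
#' `z = (I - mu) / sigma` per pixel; invalid where either the field or the
#' climatology is invalid.
#'
#' @param field A [raster_field()].
#' @param clim A [build_climatology()] result on the same grid.
#' @param variable Name for the output field.
#' @return A [raster_field()] of z-scores.
#' @export
standardize <- function(field, clim, variable = paste0(field$variable, "_z")) {
  if (!grids_equal(field$grid, clim$grid)) stop("grid mismatch")
  v <- as.vector(field$values)
  z <- (v - clim$mean) / clim$sd
  z[!clim$valid] <- NA_real_
  raster_field(px_to_matrix(z, field$grid), field$grid,
               variable = variable, time = field$time)
}

#' FAPAR 8-day composite
#'
#' A [raster_field()] of FAPAR in `[0, 1]` for one 8-day period, plus a
#' per-pixel integer quality-flag matrix. Flag semantics are product
#' configuration; the bundled convention is 0 = good, 1 = usable/degraded,
#' 2 = cloud, 3 = fill.
#'
#' @param values FAPAR matrix in `[0, 1]`.
#' @param grid A [grid_spec()].
#' @param start `Date` of the first day of the 8-day period.
#' @param flags Integer matrix of quality flags (default all 0).
#' @param n_days Period length in days (8, except possibly year end).
#' @return An object of class `"fapar_composite"`.
#' @export
fapar_composite <- function(values, grid, start, flags = NULL, n_days = 8L) {
  values <- as.matrix(values)
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("FAPAR values outside [0, 1]")
  if (is.null(flags)) flags <- matrix(0L, nrow(values), ncol(values))
  stopifnot(identical(dim(flags), dim(values)))
  structure(list(values = values, flags = flags, grid = grid,
                 start = as.Date(start), n_days = as.integer(n_days)),
            class = "fapar_composite")
}

fapar_midpoint <- function(comp) {
  as.numeric(comp$start) + (comp$n_days - 1) / 2
}

#' Mask low-quality FAPAR pixels via quality flags
#'
#' Pixels whose flag is not in `accepted` are set invalid (`NA`); accepted
#' pixels are untouched.
#'
#' @param comp A [fapar_composite()].
#' @param accepted Integer vector of accepted flag values (default
#'   `c(0L, 1L)`: good and usable retrievals).
#' @return A [fapar_composite()] with rejected pixels set to `NA`.
#' @export
qc_filter_fapar <- function(comp, accepted = c(0L, 1L)) {
  out <- comp
  out$values[!(comp$flags %in% accepted)] <- NA_real_
  out
}

#' Dekadal FAPAR composite from 8-day composites
#'
#' Builds the 10-day FAPAR value at dekad `d` as the inverse-time-distance
#' weighted mean of the `k` temporally closest 8-day composites: weights are
#' proportional to `1 / (dist + eps)` with `dist` the absolute difference in
#' days between the composite midpoint and the dekad midpoint, renormalized
#' per pixel over the valid inputs. `eps = 0.5` day avoids a division blow-up
#' when a composite midpoint coincides with the dekad midpoint while
#' preserving the distance ordering. The default `k = 2` uses the two
#' closest composites, the minimum that brackets a 10-day window.
#'
#' @param composites List of (already QC-filtered) [fapar_composite()]s.
#' @param d Target [dekad()].
#' @param k Number of closest composites to blend (default 2).
#' @param eps Distance offset in days (default 0.5).
#' @param max_distance Composites whose midpoint is farther than this many
#'   days from the dekad midpoint are never used (default 20).
#' @return A [raster_field()] named `"fapar_dekad"`.
#' @export
composite_fapar_dekad <- function(composites, d, k = 2L, eps = 0.5,
                                  max_distance = 20) {
  stopifnot(length(composites) > 0)
  mid <- dekad_midpoint(d)
  dist <- vapply(composites, function(cc) abs(fapar_midpoint(cc) - mid),
                 numeric(1))
  usable <- which(dist <= max_distance)
  if (length(usable) == 0) stop("no usable FAPAR composite near ", format(d))
  sel <- usable[order(dist[usable])][seq_len(min(k, length(usable)))]
  grid <- composites[[sel[1]]]$grid
  w <- 1 / (dist[sel] + eps)
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  wsum <- matrix(0, grid$n_rows, grid$n_cols)
  for (j in seq_along(sel)) {
    cc <- composites[[sel[j]]]
    stopifnot(grids_equal(cc$grid, grid))
    ok <- !is.na(cc$values)
    acc[ok] <- acc[ok] + w[j] * cc$values[ok]
    wsum[ok] <- wsum[ok] + w[j]
  }
  out <- acc / wsum
  out[wsum == 0] <- NA_real_
  raster_field(out, grid, variable = "fapar_dekad", time = d)
}
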