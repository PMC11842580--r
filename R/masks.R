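#' Snow and crop/growing-season masks
#'
#' Two mask families gate the CDI indicators. Dynamic dekadal snow masks,
#' built from daily NDSI snow-cover fields, suppress soil-moisture (and
#' vegetation) anomalies where snow lies on the ground, where model-based
#' soil moisture is unreliable. Static crop/growing-season masks, built from
#' a crop-fraction raster and SOS/EOS phenology, restrict the vegetation
#' anomaly to croplands inside their growing season, so bare-soil FAPAR
#' signals after harvest are not mistaken for drought stress.
#'
#' @name masks
NULL

#' Classify a daily NDSI field into snow / no-snow / missing
#'
#' NDSI values are on a 0-100 scale; values above 10 are called snow, 0 is
#' no snow, and values in 1-10 are discarded as uncertain (too prone to
#' false snow detection) and treated as no snow by default (`uncertain =
#' "missing"` treats them as unobserved instead). Special codes (cloud,
#' fill) become missing.
#'
#' @param ndsi A [raster_field()] of raw NDSI values and special codes.
#' @param cloud_codes Integer codes treated as missing (default `c(250L,
#'   255L)`: cloud and fill).
#' @param uncertain `"no_snow"` (default) or `"missing"`: handling of the
#'   discarded 1-10 range.
#' @return A [raster_field()] with integer values 1 (snow), 0 (no snow),
#'   `NA` (missing), named `"snow_daily"`.
#' @export
classify_ndsi <- function(ndsi, cloud_codes = c(250L, 255L),
                          uncertain = c("no_snow", "missing")) {
  uncertain <- match.arg(uncertain)
  v <- ndsi$values
  special <- !is.na(v) & v %in% cloud_codes
  bad <- !is.na(v) & !special & (v < 0 | v > 100)
  if (any(bad)) stop("NDSI values outside 0-100 that are not declared codes")
  out <- matrix(NA_integer_, nrow(v), ncol(v))
  out[!is.na(v) & !special & v > 10] <- 1L
  out[!is.na(v) & !special & v == 0] <- 0L
  unc <- !is.na(v) & !special & v >= 1 & v <= 10
  if (uncertain == "no_snow") out[unc] <- 0L
  raster_field(out, ndsi$grid, variable = "snow_daily", time = ndsi$time)
}

#' Composite daily snow fields into a dekadal snow mask
#'
#' A pixel is mapped as snow when snow was observed on at least
#' `min_snow_days` of the dekad's days (3 of 10 in the operational rule;
#' with `mode = "proportional"` the threshold scales as `ceiling(0.3 * N)`
#' for 8/9/11-day dekads). A pixel with zero valid observations in the whole
#' dekad (e.g. persistent cloud) is imputed with its value in the previous
#' dekad's mask; with no previous mask it defaults to no snow.
#'
#' @param days List of daily snow fields from [classify_ndsi()], covering
#'   the dekad (length `dekad_day_count(d)`).
#' @param d The target [dekad()].
#' @param previous The previous dekad's snow mask ([raster_field()] of
#'   logicals), or `NULL`.
#' @param min_snow_days Absolute snow-day threshold (default 3).
#' @param mode `"absolute"` (default) or `"proportional"`.
#' @return A [raster_field()] of logicals named `"snow_mask"`.
#' @export
composite_snow_dekad <- function(days, d, previous = NULL,
                                 min_snow_days = 3L,
                                 mode = c("absolute", "proportional")) {
  mode <- match.arg(mode)
  if (length(days) == 0) stop("empty day list")
  n_days <- dekad_day_count(d)
  if (length(days) != n_days)
    stop("expected ", n_days, " daily fields for ", format(d),
         ", got ", length(days))
  grid <- days[[1]]$grid
  thr <- if (mode == "absolute") min_snow_days else
    as.integer(ceiling(0.3 * n_days))
  snow_n <- matrix(0L, grid$n_rows, grid$n_cols)
  obs_n <- matrix(0L, grid$n_rows, grid$n_cols)
  for (f in days) {
    stopifnot(grids_equal(f$grid, grid))
    ok <- !is.na(f$values)
    obs_n[ok] <- obs_n[ok] + 1L
    snow_n[ok & f$values == 1L] <- snow_n[ok & f$values == 1L] + 1L
  }
  out <- snow_n >= thr
  unobs <- obs_n == 0L
  if (any(unobs)) {
    if (!is.null(previous)) {
      stopifnot(grids_equal(previous$grid, grid))
      prev_v <- previous$values
      prev_v[is.na(prev_v)] <- FALSE
      out[unobs] <- prev_v[unobs]
    } else {
      out[unobs] <- FALSE
    }
  }
  raster_field(out, grid, variable = "snow_mask", time = d)
}

#' Circular growing-season membership
#'
#' Inclusive membership of dekad-of-year `t` in the circular interval
#' `[sos, eos]`: a winter crop with `sos = 33, eos = 9` is in season for
#' dekads 33..36 and 1..9. Vectorized.
#'
#' @param sos,eos,t Dekads-of-year in 1..36.
#' @return Logical.
#' @export
season_contains <- function(sos, eos, t) {
  stopifnot(all(sos >= 1 & sos <= 36, na.rm = TRUE),
            all(eos >= 1 & eos <= 36, na.rm = TRUE),
            all(t >= 1 & t <= 36, na.rm = TRUE))
  ifelse(sos <= eos, t >= sos & t <= eos, t >= sos | t <= eos)
}

# crop mask state codes
CROP_STATES <- c(NON_CROP = 0L, CROP_OUT_OF_SEASON = 1L, CROP_IN_SEASON = 2L)

#' Build the 36 static crop/growing-season masks
#'
#' A pixel is cropland when its crop area fraction is at least
#' `threshold_pct` percent and it is not rangeland. For each dekad-of-year
#' the cropland pixels are split into in-season (dekad inside the circular
#' `[SOS, EOS]` interval, both ends inclusive) and out-of-season. The masks
#' are static: identical for every year. Crop pixels with missing phenology
#' are demoted to non-crop with a warning.
#'
#' @param crop_fraction [raster_field()] of crop area percent (0-100).
#' @param rangeland Logical matrix (or [raster_field()]) flagging rangeland.
#' @param sos,eos Integer matrices (or [raster_field()]s) of dekad-of-year
#'   phenology, 1..36.
#' @param threshold_pct Crop-fraction threshold in percent (default 1).
#' @return List of 36 [raster_field()]s with integer values 0 = non-crop,
#'   1 = cropland out of season, 2 = cropland in season.
#' @export
build_crop_mask <- function(crop_fraction, rangeland, sos, eos,
                            threshold_pct = 1) {
  grid <- crop_fraction$grid
  getm <- function(x) if (inherits(x, "raster_field")) x$values else as.matrix(x)
  frac <- crop_fraction$values
  rl <- getm(rangeland)
  sosm <- getm(sos); eosm <- getm(eos)
  is_crop <- !is.na(frac) & frac >= threshold_pct & !(rl %in% TRUE)
  no_phen <- is_crop & (is.na(sosm) | is.na(eosm))
  if (any(no_phen)) {
    warning(sum(no_phen), " crop pixel(s) without phenology demoted to non-crop")
    is_crop[no_phen] <- FALSE
  }
  lapply(1:36, function(t) {
    m <- matrix(CROP_STATES[["NON_CROP"]], grid$n_rows, grid$n_cols)
    if (any(is_crop)) {
      in_season <- season_contains(sosm[is_crop], eosm[is_crop], t)
      m[is_crop] <- ifelse(in_season, CROP_STATES[["CROP_IN_SEASON"]],
                           CROP_STATES[["CROP_OUT_OF_SEASON"]])
    }
    raster_field(m, grid, variable = "crop_mask", time = t)
  })
}
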