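#' End-to-end CDI pipeline on a synthetic or loaded scene
#'
#' Runs the full chain for every dekad of the scene's evaluation years:
#' SPI-1/SPI-3 gamma climatologies and fields, dekadal soil-moisture
#' aggregation, climatology and anomaly, FAPAR quality filtering, dekadal
#' compositing, climatology and anomaly, dynamic snow masks (with the T-1
#' imputation chain), static crop masks, and the stateful classifier from
#' an all-No-drought cold start. Deterministic given the scene and
#' configuration.
#'
#' @param scene A scene as returned by [generate_scene()].
#' @param version CDI version (2, 3 or 4).
#' @param out_dir Optional output directory; when given, all indicator,
#'   mask and class rasters are written as ASCII grids plus a provenance
#'   JSON (configuration hash included).
#' @param table Decision table (defaults to the bundled one).
#' @param thr A [cdi_thresholds()].
#' @param spi_mode SPI accumulation mode, `"days"` or `"months"`.
#' @param spi_min_years,clim_min_years Minimum baseline years for the SPI
#'   gamma fit and the z-score climatologies.
#' @return An object of class `"cdi_run"`: lists (one element per
#'   evaluation dekad) of `cdi`, `spi1`, `spi3`, `sma`, `fapar` and `snow`
#'   fields, the 36 `crop` masks, the dekad list, the transition `audit`,
#'   and the `version`.
#' @export
run_pipeline <- function(scene, version = 4L, out_dir = NULL,
                         table = load_decision_table(),
                         thr = cdi_thresholds(),
                         spi_mode = c("days", "months"),
                         spi_min_years = 20L, clim_min_years = 5L) {
  spi_mode <- match.arg(spi_mode)
  cfg <- scene$config
  g <- cfg$grid
  eval_dekads <- unlist(lapply(sort(cfg$eval_years), dekads_in_year),
                        recursive = FALSE)

  clim1 <- spi_climatology(scene$precip, 1L, cfg$spi_baseline_years,
                           mode = spi_mode, min_years = spi_min_years)
  clim3 <- spi_climatology(scene$precip, 3L, cfg$spi_baseline_years,
                           mode = spi_mode, min_years = spi_min_years)

  sma_clim <- vector("list", 36L)
  fapar_clim <- vector("list", 36L)
  fap_qc <- lapply(scene$fapar, qc_filter_fapar)
  fap_years <- vapply(fap_qc, function(x)
    as.integer(format(x$start, "%Y")), integer(1))
  for (o in 1:36) {
    sma_clim[[o]] <- build_climatology(
      lapply(cfg$sma_baseline_years, function(y)
        aggregate_smi_dekad(scene$smi, dekad(y, o))),
      min_years = clim_min_years)
    fapar_clim[[o]] <- build_climatology(
      lapply(cfg$fapar_baseline_years, function(y)
        composite_fapar_dekad(fap_qc[fap_years == y], dekad(y, o))),
      min_years = clim_min_years)
  }

  crop <- build_crop_mask(scene$crop_fraction, scene$rangeland,
                          scene$sos, scene$eos)

  lut <- compile_table(table)
  n <- length(eval_dekads)
  out <- list(cdi = vector("list", n), spi1 = vector("list", n),
              spi3 = vector("list", n), sma = vector("list", n),
              fapar = vector("list", n), snow = vector("list", n))
  prev_map <- cdi_init_map(g)
  prev_snow <- NULL
  for (i in seq_len(n)) {
    d <- eval_dekads[[i]]
    spi1 <- spi_field(scene$precip, d, clim1)
    spi3 <- spi_field(scene$precip, d, clim3)
    sma <- standardize(aggregate_smi_dekad(scene$smi, d),
                       sma_clim[[d$ordinal]], variable = "sma")
    fap <- standardize(
      composite_fapar_dekad(fap_qc[fap_years == d$year], d),
      fapar_clim[[d$ordinal]], variable = "fapar_anomaly")
    day_cols <- stack_dekad_cols(scene$ndsi, d)
    days <- lapply(day_cols, function(j)
      classify_ndsi(raster_field(px_to_matrix(scene$ndsi$values[, j], g), g,
                                 "ndsi", scene$ndsi$dates[j]),
                    cloud_codes = cfg$snow$cloud_code))
    snow <- composite_snow_dekad(days, d, previous = prev_snow)
    map <- cdi_step(prev_map, spi1, spi3, sma, fap, snow = snow,
                    crop = crop[[d$ordinal]], version = version,
                    table = table, thr = thr, lut = lut)
    out$cdi[[i]] <- map; out$spi1[[i]] <- spi1; out$spi3[[i]] <- spi3
    out$sma[[i]] <- sma; out$fapar[[i]] <- fap; out$snow[[i]] <- snow
    prev_map <- map; prev_snow <- snow
  }

  audit <- audit_transitions(out$cdi, table)
  run <- structure(c(out, list(crop = crop, dekads = eval_dekads,
                               audit = audit, version = version,
                               config = cfg)),
                   class = "cdi_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.cdi_run <- function(x, ...) {
  counts <- class_counts(x$cdi)
  cat(sprintf("<cdi_run v%d: %d dekads, %dx%d grid>\n", x$version,
              length(x$cdi), x$config$grid$n_rows, x$config$grid$n_cols))
  print(counts)
  cat(sprintf("illegal transitions: %d\n", x$audit$n_illegal))
  invisible(x)
}

#' Pixel-dekad counts per CDI class over a run
#'
#' @param maps List of class-code [raster_field()]s (e.g. `run$cdi`).
#' @return Named integer vector over the seven classes plus `MISSING`.
#' @export
class_counts <- function(maps) {
  v <- unlist(lapply(maps, function(m) as.vector(m$values)))
  out <- c(table(factor(v, levels = 0:6, labels = names(cdi_classes()))))
  c(out, MISSING = sum(is.na(v)))
}

# stable polynomial content hash over the serialized object, for provenance
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(run$dekads)) {
    d <- run$dekads[[i]]
    write_cdi(run$cdi[[i]], file.path(out_dir, dekad_filename("cdi", d)))
    for (v in c("spi1", "spi3", "sma", "fapar", "snow"))
      write_ascii_grid(run[[v]][[i]],
                       file.path(out_dir, dekad_filename(v, d)))
  }
  for (o in 1:36)
    write_ascii_grid(run$crop[[o]],
                     file.path(out_dir, sprintf("crop_mask_%02d.asc", o)))
  utils::write.csv(run$audit$matrix,
                   file.path(out_dir, "transition_matrix.csv"))
  jsonlite::write_json(
    list(version = run$version,
         config_hash = config_hash(run$config),
         n_dekads = length(run$dekads),
         n_illegal_transitions = run$audit$n_illegal,
         class_counts = as.list(class_counts(run$cdi))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
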