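#' Plain-text raster I/O
#'
#' Rasters are exchanged in the ESRI ASCII grid format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by the rows of values, north row first. The
#' header represents a [grid_spec()] exactly (cell-center registration,
#' regular lon/lat cells), and the format is plain text, so stacks are
#' diffable and portable. Each file can carry a JSON sidecar
#' (`<file>.json`) with the variable name, time tag and, for class maps,
#' the class legend and palette. Dekads are encoded in file names as
#' `{var}_{YYYY}{MM}{D}.asc` with `D` in 1..3.
#'
#' @name io
NULL

#' Write / read a raster field as an ESRI ASCII grid
#'
#' @param field A [raster_field()].
#' @param path Output path (`.asc`).
#' @param digits Significant digits for float output (default 7).
#' @param sidecar Write the JSON sidecar? (default `TRUE`).
#' @return `write_ascii_grid()`: the path, invisibly. `read_ascii_grid()`:
#'   a [raster_field()].
#' @export
write_ascii_grid <- function(field, path, digits = 7, sidecar = TRUE) {
  g <- field$grid
  v <- field$values
  nodata <- -9999
  header <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_lon),
    sprintf("yllcorner %.10g", g$origin_lat - g$n_rows * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %d", nodata))
  vv <- v * 1  # logical -> numeric
  txt <- formatC(vv, digits = digits, format = "g")
  txt[is.na(vv)] <- as.character(nodata)
  dim(txt) <- dim(vv)
  rows <- apply(txt, 1, paste, collapse = " ")
  writeLines(c(header, rows), path)
  if (sidecar) {
    meta <- list(variable = field$variable, crs = g$crs)
    if (inherits(field$time, "dekad"))
      meta$dekad <- list(year = field$time$year, ordinal = field$time$ordinal)
    else if (inherits(field$time, "Date"))
      meta$date <- format(field$time)
    if (identical(field$variable, "cdi")) {
      meta$flag_values <- unname(cdi_classes())
      meta$flag_meanings <- names(cdi_classes())
      meta$palette <- unname(cdi_palette())
    }
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(vals) == nr * nc)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  meta_path <- paste0(path, ".json")
  variable <- ""; time <- NULL; crs <- "EPSG:4326"
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$variable)) variable <- meta$variable
    if (!is.null(meta$crs)) crs <- meta$crs
    if (!is.null(meta$dekad)) time <- dekad(meta$dekad$year, meta$dekad$ordinal)
    else if (!is.null(meta$date)) time <- as.Date(meta$date)
    if (!is.null(meta$crs) && !grepl("4326", meta$crs))
      stop("unsupported CRS in ", meta_path, ": ", meta$crs,
           " (geographic EPSG:4326 required)")
  }
  grid <- grid_spec(nr, nc, cell_size = hdr$cellsize,
                    origin_lon = hdr$xllcorner,
                    origin_lat = hdr$yllcorner + nr * hdr$cellsize,
                    crs = crs)
  raster_field(m, grid, variable = variable, time = time)
}

dekad_filename <- function(var, d, ext = ".asc") {
  sprintf("%s_%04d%02d%d%s", var, d$year, d$month, d$dekad_of_month, ext)
}

parse_dekad_filename <- function(fn) {
  m <- regmatches(fn, regexec("_([0-9]{4})([0-9]{2})([1-3])\\.asc$", fn))[[1]]
  if (length(m) == 0) return(NULL)
  dekad(as.integer(m[2]), month = as.integer(m[3]),
        dekad_of_month = as.integer(m[4]))
}

#' Read a dekadal stack of ASCII grids from a directory
#'
#' Collects `{variable}_{YYYY}{MM}{D}.asc` files, parses their dekads from
#' the file names, checks every field shares `expected_grid` (when given)
#' and returns the fields ordered in time.
#'
#' @param dir Directory to scan.
#' @param variable Variable name prefix to match.
#' @param expected_grid Optional [grid_spec()] every field must match.
#' @return List of [raster_field()]s sorted by dekad.
#' @export
read_stack <- function(dir, variable, expected_grid = NULL) {
  files <- list.files(dir, pattern = paste0("^", variable,
                                            "_[0-9]{6}[1-3]\\.asc$"),
                      full.names = TRUE)
  if (length(files) == 0) stop("no '", variable, "' grids found in ", dir)
  fields <- lapply(files, read_ascii_grid)
  dks <- lapply(basename(files), parse_dekad_filename)
  for (i in seq_along(fields)) {
    fields[[i]]$time <- dks[[i]]
    fields[[i]]$variable <- variable
    if (!is.null(expected_grid) &&
        !grids_equal(fields[[i]]$grid, expected_grid))
      stop("grid mismatch in ", files[i])
  }
  fields[order(vapply(dks, dekad_serial, integer(1)))]
}

#' Write a CDI class map
#'
#' Writes the integer class raster as an ASCII grid whose JSON sidecar
#' carries the seven-class legend (`flag_values` / `flag_meanings`) and the
#' display palette (warm colors for the Watch/Warning/Alert stages).
#'
#' @param map A class-code [raster_field()] (variable `"cdi"`).
#' @param path Output `.asc` path.
#' @return The path, invisibly.
#' @export
write_cdi <- function(map, path) {
  stopifnot(inherits(map, "raster_field"))
  map$variable <- "cdi"
  write_ascii_grid(map, path, digits = 1)
}
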