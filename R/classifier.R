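#' The CDI seven-class scale and state-machine classifier
#'
#' The CDI classifies every pixel, every dekad, into one of seven classes:
#' three primary drought stages (Watch: precipitation deficit; Warning:
#' soil-moisture deficit; Alert: vegetation stress), No drought, and three
#' recovery classes (Recovery, Temporary Soil Moisture Recovery, Temporary
#' Vegetation Recovery) that modulate every return from drought to
#' no-drought; a direct drought-to-no-drought transition is never allowed.
#' The classification combines the indicator exceedance flags at dekad T
#' with the class at T-1 through an 8-column x 7-row decision table.
#'
#' @name classifier
NULL

#' CDI class codes
#'
#' Integer raster encoding of the seven classes. `MISSING` is out-of-band
#' (`NA` in class rasters), never an eighth class.
#'
#' @return Named integer vector of the seven class codes.
#' @export
cdi_classes <- function() {
  c(NO_DROUGHT = 0L, WATCH = 1L, WARNING = 2L, ALERT = 3L,
    RECOVERY = 4L, TEMP_SM_RECOVERY = 5L, TEMP_VEG_RECOVERY = 6L)
}

#' @rdname cdi_classes
#' @export
cdi_recovery_classes <- function() {
  c("RECOVERY", "TEMP_SM_RECOVERY", "TEMP_VEG_RECOVERY")
}

#' Display palette for CDI maps (warm colors for the drought stages)
#' @return Named character vector of hex colors.
#' @export
cdi_palette <- function() {
  c(NO_DROUGHT = "#F2F2F2", WATCH = "#F5D915", WARNING = "#F5891D",
    ALERT = "#E02609", RECOVERY = "#4DAC26",
    TEMP_SM_RECOVERY = "#B8E186", TEMP_VEG_RECOVERY = "#7FBC41")
}

#' Classifier thresholds
#'
#' The reference thresholds of the decision framework. SPI comparisons are
#' strict (`<`), SMA/FAPAR comparisons are inclusive (`<=`). `wet_spi1` /
#' `wet_spi3` define the wet-precipitation escape of column C, and
#' `partial_lo`/`partial_hi` the partial-recovery interval `(-0.5, 0]`
#' (lower bound exclusive, upper inclusive).
#'
#' @param spi1_extreme SPI-1 extreme drought threshold (default -2).
#' @param spi3_moderate SPI-3 moderate drought threshold (default -1).
#' @param sma Soil-moisture anomaly threshold (default -1).
#' @param fapar FAPAR anomaly threshold (default -1).
#' @param wet_spi1,wet_spi3 Wet-escape bounds (defaults 0.5 and 0).
#' @param partial_lo,partial_hi Partial-recovery interval bounds.
#' @return A list of class `"cdi_thresholds"`.
#' @export
cdi_thresholds <- function(spi1_extreme = -2, spi3_moderate = -1,
                           sma = -1, fapar = -1,
                           wet_spi1 = 0.5, wet_spi3 = 0,
                           partial_lo = -0.5, partial_hi = 0) {
  stopifnot(spi1_extreme < spi3_moderate, spi3_moderate < 0,
            partial_lo < partial_hi)
  structure(list(spi1_extreme = spi1_extreme, spi3_moderate = spi3_moderate,
                 sma = sma, fapar = fapar, wet_spi1 = wet_spi1,
                 wet_spi3 = wet_spi3, partial_lo = partial_lo,
                 partial_hi = partial_hi),
            class = "cdi_thresholds")
}

#' Exceedance and sub-condition flags for one pixel (vectorized)
#'
#' Computes the three exceedance flags that select the decision-table
#' column -- `spi = (SPI-1 < -2) OR (SPI-3 < -1)`, `sma = (SMA <= -1)`,
#' `fapar = (FAPAR <= -1)` -- plus the sub-condition predicates: the wet-SPI
#' escape `(SPI-1 > 0.5) AND (SPI-3 > 0)` and the partial-recovery flags
#' `value in (-0.5, 0]`. Missing-input policy: an invalid SPI makes the
#' pixel missing (all flags `NA`); an invalid SMA or FAPAR behaves as
#' masked (its flags are `FALSE`), matching the mask-reduction semantics.
#'
#' @param spi1,spi3,sma,fapar Numeric vectors of z-scores (`NA` = invalid).
#' @param thr A [cdi_thresholds()].
#' @return A list of logical vectors `spi`, `sma`, `fapar`, `wet_spi`,
#'   `sma_partial`, `fapar_partial`, and `missing`.
#' @export
compute_flags <- function(spi1, spi3, sma, fapar, thr = cdi_thresholds()) {
  n <- max(length(spi1), length(spi3), length(sma), length(fapar))
  spi1 <- rep_len(spi1, n); spi3 <- rep_len(spi3, n)
  sma <- rep_len(sma, n); fapar <- rep_len(fapar, n)
  missing <- is.na(spi1) | is.na(spi3)
  f <- list(
    spi = spi1 < thr$spi1_extreme | spi3 < thr$spi3_moderate,
    sma = !is.na(sma) & sma <= thr$sma,
    fapar = !is.na(fapar) & fapar <= thr$fapar,
    wet_spi = spi1 > thr$wet_spi1 & spi3 > thr$wet_spi3,
    sma_partial = !is.na(sma) & sma > thr$partial_lo & sma <= thr$partial_hi,
    fapar_partial = !is.na(fapar) & fapar > thr$partial_lo &
      fapar <= thr$partial_hi
  )
  f$spi[missing] <- NA; f$wet_spi[missing] <- NA
  f$missing <- missing
  f
}

#' Mask reduction of the flags by CDI version
#'
#' CDIv4 suppresses the soil-moisture and vegetation flags (exceedance and
#' partial) under an active snow mask, collapsing the framework to columns
#' A and B. CDIv3 (and v4) suppresses the vegetation flags on cropland out
#' of its growing season, collapsing to columns A, B, C and F. Non-crop
#' pixels are never FAPAR-reduced (vegetation other than crop is still
#' assessed). CDIv2 applies no reduction.
#'
#' @param flags Flag list from [compute_flags()].
#' @param snow Logical vector: active snow mask.
#' @param crop_state Integer vector of crop states (0 non-crop, 1 cropland
#'   out of season, 2 cropland in season).
#' @param version CDI version, 2, 3 or 4.
#' @return The reduced flag list.
#' @export
apply_mask_reduction <- function(flags, snow, crop_state, version = 4L) {
  stopifnot(version %in% c(2L, 3L, 4L))
  if (version >= 4L) {
    s <- !is.na(snow) & snow
    flags$sma[s] <- FALSE; flags$sma_partial[s] <- FALSE
    flags$fapar[s] <- FALSE; flags$fapar_partial[s] <- FALSE
  }
  if (version >= 3L) {
    off <- !is.na(crop_state) &
      crop_state == CROP_STATES[["CROP_OUT_OF_SEASON"]]
    flags$fapar[off] <- FALSE; flags$fapar_partial[off] <- FALSE
  }
  flags
}

#' Decision-table column from the exceedance flags
#'
#' Bijective mapping of the `(spi, sma, fapar)` flag triple to the column
#' letter: A=(0,0,0), B=(1,0,0), C=(0,1,0), D=(0,0,1), E=(0,1,1), F=(1,1,0),
#' G=(1,0,1), H=(1,1,1).
#'
#' @param spi,sma,fapar Logical vectors.
#' @return Character vector of column letters (`NA` where spi is `NA`).
#' @export
flags_column <- function(spi, sma, fapar) {
  key <- spi * 4L + sma * 2L + fapar * 1L
  c("A", "D", "C", "E", "B", "G", "F", "H")[key + 1L]
}

#' Load the bundled (or a user) decision table
#'
#' The decision framework is data, not code: a CSV mapping `(column, prev,
#' cond)` to the output class. See the bundled file for the format.
#'
#' @param path Path to a decision-table CSV; default the bundled table.
#' @return A `data.frame` of class `"cdi_decision_table"`.
#' @export
load_decision_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "decision_table.csv", package = "cdi")
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE, strip.white = TRUE)
  stopifnot(all(c("column", "prev", "cond", "out") %in% names(tab)))
  class(tab) <- c("cdi_decision_table", "data.frame")
  tab
}

table_conds <- c("any", "wet_spi", "not_wet_spi", "sma_partial",
                 "not_sma_partial", "fapar_partial", "not_fapar_partial")

# evaluate a table condition against a flag record (scalar logicals)
cond_holds <- function(cond, wet_spi, sma_partial, fapar_partial) {
  switch(cond,
         any = TRUE,
         wet_spi = isTRUE(wet_spi), not_wet_spi = !isTRUE(wet_spi),
         sma_partial = isTRUE(sma_partial),
         not_sma_partial = !isTRUE(sma_partial),
         fapar_partial = isTRUE(fapar_partial),
         not_fapar_partial = !isTRUE(fapar_partial),
         stop("unknown condition: ", cond))
}

#' Validate a decision table against the framework's structural constraints
#'
#' Checks that the table (a) is total: every `(column, prev)` cell of the
#' 8 x 7 grid is covered by either a single `any` row or a complementary
#' condition pair; (b) maps columns E, G and H to Alert for every previous
#' class; (c) never maps a drought class (Watch, Warning, Alert) directly
#' to No drought; (d) only emits the seven classes; (e) maps column B
#' (meteorological deficit) to Watch; (f) implements the wet-SPI escape in
#' column C for previous No drought / Recovery.
#'
#' @param table A [load_decision_table()] result.
#' @return Invisibly `TRUE` if valid; otherwise a character vector of
#'   violations with attribute `valid = FALSE` is returned (and no error
#'   thrown), so callers can report. Use `stopifnot(validate_table(tab))`
#'   to hard-fail.
#' @export
validate_table <- function(table) {
  classes <- names(cdi_classes())
  cols <- LETTERS[1:8]
  bad <- character(0)
  pair_of <- c(wet_spi = "not_wet_spi", not_wet_spi = "wet_spi",
               sma_partial = "not_sma_partial",
               not_sma_partial = "sma_partial",
               fapar_partial = "not_fapar_partial",
               not_fapar_partial = "fapar_partial")
  for (cl in cols) for (pv in classes) {
    rows <- table[table$column == cl & table$prev == pv, , drop = FALSE]
    if (nrow(rows) == 0) { bad <- c(bad, sprintf("(%s,%s): missing cell", cl, pv)); next }
    if (!all(rows$cond %in% table_conds))
      bad <- c(bad, sprintf("(%s,%s): unknown condition", cl, pv))
    covered <- (nrow(rows) == 1 && rows$cond == "any") ||
      (nrow(rows) == 2 && !anyNA(pair_of[rows$cond]) &&
         pair_of[rows$cond[1]] == rows$cond[2])
    if (!covered)
      bad <- c(bad, sprintf("(%s,%s): conditions do not partition", cl, pv))
    if (!all(rows$out %in% classes))
      bad <- c(bad, sprintf("(%s,%s): output not a CDI class", cl, pv))
    if (cl %in% c("E", "G", "H") && !all(rows$out == "ALERT"))
      bad <- c(bad, sprintf("(%s,%s): E/G/H must map to ALERT", cl, pv))
    if (cl == "B" && !all(rows$out == "WATCH"))
      bad <- c(bad, sprintf("(%s,%s): B must map to WATCH", cl, pv))
    if (pv %in% c("WATCH", "WARNING", "ALERT") && any(rows$out == "NO_DROUGHT"))
      bad <- c(bad, sprintf("(%s,%s): direct drought -> NO_DROUGHT", cl, pv))
  }
  for (pv in c("NO_DROUGHT", "RECOVERY")) {
    rows <- table[table$column == "C" & table$prev == pv, , drop = FALSE]
    if (!(any(rows$cond == "wet_spi" & rows$out == "NO_DROUGHT") &&
          any(rows$cond == "not_wet_spi" & rows$out == "WARNING")))
      bad <- c(bad, sprintf("(C,%s): wet-SPI escape not implemented", pv))
  }
  if (length(bad)) return(structure(bad, valid = FALSE))
  invisible(TRUE)
}

#' Classify a single pixel
#'
#' Pure decision-table lookup: given the (mask-reduced) flags and the class
#' at T-1, returns the class at T. Exposed mainly for enumeration tests and
#' as the reference semantics of [cdi_step()].
#'
#' @param flags A flag record (list with scalar logicals `spi`, `sma`,
#'   `fapar`, `wet_spi`, `sma_partial`, `fapar_partial`).
#' @param prev Previous class name (one of `names(cdi_classes())`).
#' @param table A validated decision table.
#' @return The output class name.
#' @export
classify_pixel <- function(flags, prev, table = load_decision_table()) {
  if (is.na(flags$spi)) return(NA_character_)
  col <- flags_column(flags$spi, flags$sma, flags$fapar)
  rows <- table[table$column == col & table$prev == prev, , drop = FALSE]
  if (nrow(rows) == 0) stop("decision table has no cell (", col, ",", prev, ")")
  for (i in seq_len(nrow(rows)))
    if (cond_holds(rows$cond[i], flags$wet_spi, flags$sma_partial,
                   flags$fapar_partial))
      return(rows$out[i])
  stop("no condition matched in cell (", col, ",", prev, ")")
}

#' Validate and compile a decision table to a dense lookup array
#'
#' The array has dims (column 1..8, prev 1..7, wet-SPI 1..2, SMA-partial
#' 1..2, FAPAR-partial 1..2); those six inputs fully determine the output
#' class. [cdi_step()] compiles on the fly when not given one.
#'
#' @param table A decision table from [load_decision_table()].
#' @return Integer array of class codes.
#' @export
compile_table <- function(table) {
  ok <- validate_table(table)
  if (!isTRUE(ok)) stop("invalid decision table: ", paste(ok, collapse = "; "))
  classes <- names(cdi_classes())
  arr <- array(NA_integer_, dim = c(8, 7, 2, 2, 2))
  for (ci in 1:8) for (pi in 1:7) for (w in 0:1) for (s in 0:1) for (f in 0:1) {
    flags <- list(spi = ci > 0,  # placeholder; column given directly below
                  wet_spi = w == 1, sma_partial = s == 1,
                  fapar_partial = f == 1)
    rows <- table[table$column == LETTERS[ci] & table$prev == classes[pi], ,
                  drop = FALSE]
    out <- NA_character_
    for (i in seq_len(nrow(rows)))
      if (cond_holds(rows$cond[i], flags$wet_spi, flags$sma_partial,
                     flags$fapar_partial)) { out <- rows$out[i]; break }
    arr[ci, pi, w + 1, s + 1, f + 1] <- cdi_classes()[[out]]
  }
  arr
}

#' One classifier step: class map at T from indicators at T and map at T-1
#'
#' Applies [compute_flags()], the version's mask reduction and the decision
#' table to every pixel. Pixels with an invalid SPI are missing (`NA`) in
#' the output.
#'
#' @param prev_map [raster_field()] of integer class codes at T-1 (use
#'   [cdi_init_map()] for the cold start).
#' @param spi1,spi3,sma,fapar Z-score [raster_field()]s at dekad T.
#' @param snow Snow mask [raster_field()] (logical), or `NULL` for none.
#' @param crop Crop-state [raster_field()] (integer 0/1/2), or `NULL`.
#' @param version CDI version (2, 3 or 4; default 4).
#' @param table Decision table (validated on entry).
#' @param thr A [cdi_thresholds()].
#' @param lut Optional precompiled lookup from [compile_table()]; callers
#'   stepping many dekads with the same table pass it once to avoid
#'   re-validating and re-compiling the table every step.
#' @return A [raster_field()] of integer class codes named `"cdi"`.
#' @export
cdi_step <- function(prev_map, spi1, spi3, sma, fapar, snow = NULL,
                     crop = NULL, version = 4L,
                     table = load_decision_table(),
                     thr = cdi_thresholds(), lut = NULL) {
  grid <- prev_map$grid
  for (f in list(spi1, spi3, sma, fapar))
    if (!grids_equal(f$grid, grid)) stop("grid mismatch")
  if (is.null(lut)) lut <- compile_table(table)
  np <- grid$n_rows * grid$n_cols
  snow_v <- if (is.null(snow)) rep(FALSE, np) else as.vector(snow$values)
  crop_v <- if (is.null(crop)) rep(CROP_STATES[["NON_CROP"]], np) else
    as.vector(crop$values)
  flags <- compute_flags(as.vector(spi1$values), as.vector(spi3$values),
                         as.vector(sma$values), as.vector(fapar$values), thr)
  flags <- apply_mask_reduction(flags, snow_v, crop_v, version)
  col_idx <- match(flags_column(flags$spi, flags$sma, flags$fapar), LETTERS)
  prev_v <- as.vector(prev_map$values)
  out <- rep(NA_integer_, np)
  live <- !is.na(col_idx) & !is.na(prev_v)
  if (any(live)) {
    out[live] <- lut[cbind(col_idx[live], prev_v[live] + 1L,
                           ifelse(isTRUE_v(flags$wet_spi[live]), 2L, 1L),
                           flags$sma_partial[live] + 1L,
                           flags$fapar_partial[live] + 1L)]
  }
  raster_field(px_to_matrix(out, grid), grid, variable = "cdi",
               time = spi1$time)
}

# vectorized isTRUE (NA -> FALSE)
isTRUE_v <- function(x) !is.na(x) & x

#' Cold-start class map (all pixels No drought)
#'
#' The first dekad of a run has no T-1 map; every pixel starts at No
#' drought. A spin-up of at least three dekads is recommended before
#' interpreting the output.
#'
#' @param grid A [grid_spec()].
#' @return A [raster_field()] of class codes, all `NO_DROUGHT`.
#' @export
cdi_init_map <- function(grid) {
  raster_field(matrix(cdi_classes()[["NO_DROUGHT"]], grid$n_rows,
                      grid$n_cols), grid, variable = "cdi")
}

#' Class-transition counts between consecutive dekads
#'
#' The data behind the alluvial diagnostics: a 7 x 7 matrix counting, over
#' all consecutive map pairs and pixels, the transitions from the class at
#' T-1 (rows) to the class at T (columns). Pixels missing in either map are
#' skipped.
#'
#' @param maps Ordered list of class-code [raster_field()]s (>= 2).
#' @return An integer 7 x 7 matrix with class-name dimnames.
#' @export
transition_matrix <- function(maps) {
  stopifnot(length(maps) >= 2)
  classes <- names(cdi_classes())
  tm <- matrix(0L, 7, 7, dimnames = list(from = classes, to = classes))
  for (i in 2:length(maps)) {
    a <- as.vector(maps[[i - 1]]$values); b <- as.vector(maps[[i]]$values)
    stopifnot(grids_equal(maps[[i - 1]]$grid, maps[[i]]$grid))
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tt <- table(factor(a[ok], levels = 0:6), factor(b[ok], levels = 0:6))
    tm <- tm + as.integer(tt)
  }
  tm
}

#' Transitions a decision table can ever produce
#'
#' Enumerates every (column, prev, sub-condition) cell of the table and
#' collects the reachable (prev -> out) pairs, as a logical 7 x 7 matrix.
#' Used by the legality audit: any transition observed in a run but absent
#' here is a bug.
#'
#' @param table A validated decision table.
#' @return Logical 7 x 7 matrix (from x to).
#' @export
allowed_transitions <- function(table) {
  classes <- names(cdi_classes())
  m <- matrix(FALSE, 7, 7, dimnames = list(from = classes, to = classes))
  for (i in seq_len(nrow(table)))
    m[table$prev[i], table$out[i]] <- TRUE
  m
}

#' Audit a run for forbidden transitions
#'
#' @param maps Ordered list of class maps (as in [transition_matrix()]).
#' @param table The decision table the run used.
#' @return List with the observed transition matrix, the count of
#'   transitions not producible by the table, and the count of direct
#'   drought-to-no-drought transitions (both must be zero in a correct run).
#' @export
audit_transitions <- function(maps, table = load_decision_table()) {
  tm <- transition_matrix(maps)
  allowed <- allowed_transitions(table)
  drought <- c("WATCH", "WARNING", "ALERT")
  list(matrix = tm,
       n_illegal = sum(tm[!allowed]),
       n_drought_to_no_drought = sum(tm[drought, "NO_DROUGHT"]))
}
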