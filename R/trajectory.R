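#' Modal class trajectory over a region
#'
#' For each map in a run, the most frequent class among the region's
#' pixels. Used to audit the drought-propagation cascade of an injected
#' event: the expected modal trajectory is No drought, then Watch, Warning
#' and Alert appearing in that order, then a recovery class, then No
#' drought again.
#'
#' @param maps List of class-code [raster_field()]s.
#' @param rows,cols Integer index vectors of the region.
#' @return Character vector of modal class names (one per map; `NA` where
#'   the whole region is missing).
#' @export
modal_trajectory <- function(maps, rows, cols) {
  classes <- names(cdi_classes())
  vapply(maps, function(m) {
    v <- as.vector(m$values[rows, cols])
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_character_)
    classes[which.max(tabulate(v + 1L, nbins = 7L))]
  }, character(1))
}

#' Check the drought-propagation order of a modal trajectory
#'
#' Verifies first-appearance ordering (order, not timing): the trajectory
#' starts at No drought, Watch appears before Warning, Warning before
#' Alert, Alert before the first recovery class, and the trajectory ends at
#' No drought. Revisits of earlier stages (e.g. Warning re-appearing while
#' a long SPI deficit unwinds) are permitted.
#'
#' @param traj Character vector from [modal_trajectory()].
#' @return Logical scalar, with a `stages` attribute giving the
#'   first-appearance index of each stage.
#' @export
trajectory_in_order <- function(traj) {
  first <- function(cls) {
    i <- which(traj %in% cls)[1]
    if (is.na(i)) Inf else i
  }
  f_watch <- first("WATCH"); f_warn <- first("WARNING")
  f_alert <- first("ALERT"); f_rec <- first(cdi_recovery_classes())
  ok <- identical(traj[1], "NO_DROUGHT") &&
    is.finite(f_watch) && is.finite(f_warn) && is.finite(f_alert) &&
    is.finite(f_rec) &&
    f_watch < f_warn && f_warn < f_alert && f_alert < f_rec &&
    identical(traj[length(traj)], "NO_DROUGHT") &&
    f_rec < length(traj)
  structure(ok, stages = c(watch = f_watch, warning = f_warn,
                           alert = f_alert, recovery = f_rec))
}
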