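#' Spatial resampling between regular grids
#'
#' Two resampling schemes are used when bringing inputs onto the CDI grid:
#' bilinear interpolation for continuous fields (FAPAR) and modal (most
#' frequent value) aggregation for binary masks (snow).
#'
#' @name resample
NULL

#' Bilinear resampling of a continuous field
#'
#' Interpolates the source field at each target cell center from the four
#' surrounding source cell centers. Weights of invalid source pixels are
#' renormalized over the valid ones; a target pixel with no valid
#' contributor is invalid. Outputs are convex combinations of contributing
#' values, hence bounded by their local min/max, and a planar field is
#' reproduced exactly. Intended for a source at finer than or equal
#' resolution to the target.
#'
#' @param field A [raster_field()] on the source grid.
#' @param target A [grid_spec()] overlapping the source extent.
#' @return A [raster_field()] on `target`.
#' @export
resample_bilinear <- function(field, target) {
  src <- field$grid
  # fractional source index of each target cell center (row/col units where
  # integer j is the center of source row/col j)
  t_lat <- target$origin_lat - (seq_len(target$n_rows) - 0.5) * target$cell_size
  t_lon <- target$origin_lon + (seq_len(target$n_cols) - 0.5) * target$cell_size
  rx <- (src$origin_lat - t_lat) / src$cell_size + 0.5
  cx <- (t_lon - src$origin_lon) / src$cell_size + 0.5
  if (max(rx) < 1 || min(rx) > src$n_rows || max(cx) < 1 || min(cx) > src$n_cols)
    stop("disjoint extents: target grid does not overlap the source")
  r0 <- pmin(pmax(floor(rx), 1), src$n_rows - 1)
  c0 <- pmin(pmax(floor(cx), 1), src$n_cols - 1)
  if (src$n_rows == 1) r0 <- rep(1, length(rx))
  if (src$n_cols == 1) c0 <- rep(1, length(cx))
  fr <- pmin(pmax(rx - r0, 0), 1)
  fc <- pmin(pmax(cx - c0, 0), 1)

  nr <- target$n_rows; nc <- target$n_cols
  R0 <- matrix(r0, nr, nc); FR <- matrix(fr, nr, nc)
  C0 <- matrix(c0, nr, nc, byrow = TRUE); FC <- matrix(fc, nr, nc, byrow = TRUE)
  r1 <- pmin(R0 + 1, src$n_rows); c1 <- pmin(C0 + 1, src$n_cols)

  v <- field$values
  pick <- function(r, c) v[cbind(as.vector(r), as.vector(c))]
  vals <- cbind(pick(R0, C0), pick(R0, c1), pick(r1, C0), pick(r1, c1))
  w <- cbind(as.vector((1 - FR) * (1 - FC)), as.vector((1 - FR) * FC),
             as.vector(FR * (1 - FC)), as.vector(FR * FC))
  w[is.na(vals)] <- 0
  vals[is.na(vals)] <- 0
  wsum <- rowSums(w)
  out <- rowSums(w * vals) / wsum
  out[wsum == 0] <- NA_real_
  raster_field(matrix(out, nr, nc), target, variable = field$variable,
               time = field$time)
}

#' Modal (most frequent value) aggregation of a binary mask
#'
#' Aggregates a fine binary field to a coarser grid into which it nests
#' exactly (same origin, integer cell-size ratio): each target cell takes
#' the most frequent value among its contributing fine cells, counting only
#' valid ones. Ties break toward `TRUE` ("snow wins"): conservative for a
#' mask whose purpose is to suppress unreliable soil-moisture anomalies.
#'
#' @param mask A [raster_field()] with logical (or 0/1) values on the fine
#'   grid.
#' @param target A [grid_spec()]; the fine grid must nest into it.
#' @param tie `"true"` (default) or `"false"`: winner of an exact 50/50 tie.
#' @return A [raster_field()] of logical values on `target`.
#' @export
resample_modal <- function(mask, target, tie = c("true", "false")) {
  tie <- match.arg(tie)
  src <- mask$grid
  fac <- target$cell_size / src$cell_size
  if (abs(fac - round(fac)) > 1e-8) stop("fine grid does not nest into target")
  fac <- as.integer(round(fac))
  ok <- abs(src$origin_lon - target$origin_lon) < 1e-9 &&
    abs(src$origin_lat - target$origin_lat) < 1e-9 &&
    src$n_rows == target$n_rows * fac && src$n_cols == target$n_cols * fac
  if (!ok) stop("grid mismatch: fine grid must align with and tile the target")
  v <- mask$values * 1
  rb <- (seq_len(src$n_rows) - 1L) %/% fac + 1L
  cb <- (seq_len(src$n_cols) - 1L) %/% fac + 1L
  block <- matrix(rb, src$n_rows, src$n_cols) +
    matrix((cb - 1L) * target$n_rows, src$n_rows, src$n_cols, byrow = TRUE)
  n_true <- tapply(as.vector(v), as.vector(block), sum, na.rm = TRUE)
  n_obs <- tapply(!is.na(as.vector(v)), as.vector(block), sum)
  out <- if (tie == "true") n_true >= n_obs / 2 else n_true > n_obs / 2
  out[n_obs == 0] <- NA
  raster_field(matrix(as.logical(out), target$n_rows, target$n_cols),
               target, variable = mask$variable, time = mask$time)
}
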