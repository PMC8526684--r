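#' Locate the nulla on a smoothed ILM surface
#'
#' The nulla is the deepest point of the (smoothed) internal limiting
#' membrane across the raster — anatomically the lowest point of the
#' foveolar cavity, i.e. the cell with the largest row index. Because the
#' surface lives on a voxel grid, "lowest points" are identified at the
#' grid's depth resolution: every cell within half a row (`depth_tol`) of
#' the maximal smoothed depth counts as a lowest point. Around a flat pit
#' floor these are several adjacent cells; their unweighted center of mass
#' is taken and rounded to the nearest raster cell, an exact half rounding
#' toward the lower index (deterministic tie-break). The B-scan of the
#' result is the "central" B-scan on which all subsequent morphometry is
#' measured.
#'
#' @param surface Numeric matrix `n_bscans` x `width_px`, typically from
#'   [smooth_surface()]; `NA` = missing.
#' @param roi Optional list with integer ranges `bscans` and `columns`
#'   restricting the search to a central subregion; default: full raster.
#' @param depth_tol Depth resolution in rows: cells within `depth_tol` of
#'   the maximum count as tied lowest points (default 0.5, half a voxel
#'   row).
#' @return One-row tibble: `bscan`, `column`, `depth_px` (smoothed row at
#'   the nulla), `n_tied` (number of tied lowest points).
#' @export
find_nulla <- function(surface, roi = NULL, depth_tol = 0.5) {
  stopifnot(is.matrix(surface))
  mask <- !is.na(surface)
  if (!is.null(roi)) {
    keep <- matrix(FALSE, nrow(surface), ncol(surface))
    keep[roi$bscans, roi$columns] <- TRUE
    mask <- mask & keep
  }
  if (!any(mask)) abort("surface has no defined cells in the search region")
  depth <- max(surface[mask])
  tied <- which(mask & surface >= depth - depth_tol, arr.ind = TRUE)
  b <- round_half_down(mean(tied[, 1]))
  c <- round_half_down(mean(tied[, 2]))
  tibble::tibble(bscan = as.integer(b), column = as.integer(c),
                 depth_px = surface[b, c], n_tied = nrow(tied))
}
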