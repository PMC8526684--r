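#' Scan geometry of a raster OCT volume
#'
#' Describes the pixel raster and physical scales of a 20 deg x 20 deg
#' Spectralis-style macular volume scan: 25 horizontal raster lines separated
#' by 221 um, each B-scan 5.3 mm wide (512 columns, so 5300/512 ~ 10.352
#' um/column laterally) and 512 rows deep after rescale. The axial scale
#' defaults to 3.9 um per pixel, the quantum at which all thickness readings
#' are reported.
#'
#' @param width_px,height_px B-scan raster size in pixels (columns, rows).
#' @param n_bscans Number of raster lines in the volume.
#' @param lateral_um_per_px Lateral (column) scale in um per pixel.
#' @param axial_um_per_px Axial (row) scale in um per pixel.
#' @param bscan_spacing_um Distance between adjacent raster lines in um.
#' @return An object of class `scan_geometry` (a named list).
#' @export
#' @examples
#' scan_geometry()
scan_geometry <- function(width_px = 512L, height_px = 512L, n_bscans = 25L,
                          lateral_um_per_px = 5300 / 512,
                          axial_um_per_px = 3.9,
                          bscan_spacing_um = 221) {
  g <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    n_bscans = as.integer(n_bscans),
    lateral_um_per_px = as.numeric(lateral_um_per_px),
    axial_um_per_px = as.numeric(axial_um_per_px),
    bscan_spacing_um = as.numeric(bscan_spacing_um)
  )
  vals <- unlist(g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all scan_geometry fields must be strictly positive and finite")
  }
  if (g$n_bscans < 1L) abort("n_bscans must be >= 1")
  structure(g, class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> %d B-scans of %d x %d px; %.3f um/col, %.2f um/row, %g um between B-scans\n",
    x$n_bscans, x$height_px, x$width_px,
    x$lateral_um_per_px, x$axial_um_per_px, x$bscan_spacing_um
  ))
  invisible(x)
}

# Lateral offsets in um are snapped to whole columns.
um_to_cols <- function(um, geometry) {
  sign(um) * round(abs(um) / geometry$lateral_um_per_px)
}

#' Read or write a scan geometry as JSON
#'
#' @param path File path.
#' @param geometry A [scan_geometry()] object.
#' @return `read_geometry()` returns a `scan_geometry`; `write_geometry()`
#'   returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scan_geometry, x[intersect(names(x), names(scan_geometry()))])
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "scan_geometry"))
  jsonlite::write_json(unclass(geometry), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
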