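#' Nasal/temporal display-orientation convention
#'
#' Horizontal B-scans are exported in display orientation; which image side
#' is nasal depends on the eye. The default convention is image-left =
#' temporal for right eyes (OD) and image-left = nasal for left eyes (OS).
#' Because the export orientation is device- and workflow-specific, the
#' convention is an explicit, mandatory configuration rather than a
#' hard-coded fact.
#'
#' @param od_nasal,os_nasal `"left"` or `"right"`: which image side is nasal
#'   for each eye side.
#' @return Object of class `orientation_convention`.
#' @export
orientation_convention <- function(od_nasal = "right", os_nasal = "left") {
  structure(list(od_nasal = match.arg(od_nasal, c("left", "right")),
                 os_nasal = match.arg(os_nasal, c("left", "right"))),
            class = "orientation_convention")
}

# +1 if nasal lies toward larger column indices, -1 otherwise.
nasal_direction <- function(side, convention = orientation_convention()) {
  side <- match.arg(side, c("OD", "OS"))
  nasal <- if (side == "OD") convention$od_nasal else convention$os_nasal
  if (nasal == "right") 1L else -1L
}

# Columns of the half-open interval [from, to): walks from `from` toward
# `to`, excluding `to`. Direction-aware so adjacent intervals tile exactly.
cols_half_open <- function(from, to) {
  if (from == to) abort("empty column interval")
  s <- sign(to - from)
  seq.int(from, to - s, by = s)
}

#' Build the lateral sampling plan around the nulla
#'
#' Thickness readings are taken at 500-um intervals out to 2000 um on both
#' sides of the nulla (nine columns, T1 nasal-most through T9 temporal-most,
#' T5 at the nulla itself) plus the two umbo columns 100 um nasal (TUn) and
#' temporal (TUt). Offsets are snapped to whole columns
#' (`round(offset / lateral_um_per_px)`); with the default geometry 500 um
#' is 48 columns and 100 um is 10.
#'
#' @param nulla_col Nulla column index (1-based).
#' @param geometry A [scan_geometry()].
#' @param side `"OD"` or `"OS"`.
#' @param convention An [orientation_convention()].
#' @return Tibble with `label`, `offset_um` (signed along the nasal(-) to
#'   temporal(+) axis) and `column`; errors (naming the offset) if any
#'   column falls outside the B-scan.
#' @export
build_sampling_plan <- function(nulla_col, geometry = scan_geometry(),
                                side = "OD",
                                convention = orientation_convention()) {
  dir <- nasal_direction(side, convention)
  offsets <- c(seq(-2000, 2000, by = 500), -100, 100)
  labels <- c(paste0("T", 1:9), "TUn", "TUt")
  column <- nulla_col - dir * um_to_cols(offsets, geometry)
  bad <- column < 1L | column > geometry$width_px
  if (any(bad)) {
    abort(sprintf(
      "sampling plan exceeds the B-scan: offset %+d um maps to column %d (width %d)",
      offsets[which(bad)[1]], column[which(bad)[1]], geometry$width_px
    ))
  }
  tibble::tibble(label = labels, offset_um = offsets, column = as.integer(column))
}

#' Measure retinal thickness at one column
#'
#' Default (`axial`) mode counts retina rows inclusively and scales by the
#' axial pixel size: `(rpe - ilm + 1) * axial_um_per_px`, always an integer
#' multiple of the axial quantum (3.9 um by default). The alternative
#' `rpe_normal` mode measures the geometric distance from the outer boundary
#' point along the local inward normal of the RPE (tangent from a
#' least-squares line fit over +/-250 um of the outer surface) to the ILM;
#' at the near-horizontal macular RPE the two coincide.
#'
#' @param ilm,rpe Numeric vectors of per-column boundary rows (from
#'   [extract_surfaces()]).
#' @param column Column index.
#' @param geometry A [scan_geometry()].
#' @param mode `"axial"` (default) or `"rpe_normal"`.
#' @return Thickness in um.
#' @export
measure_thickness <- function(ilm, rpe, column, geometry = scan_geometry(),
                              mode = c("axial", "rpe_normal")) {
  mode <- match.arg(mode)
  if (is.na(ilm[column]) || is.na(rpe[column])) {
    abort(sprintf("column %d has no retina", column))
  }
  if (ilm[column] > rpe[column]) abort("ilm below rpe: invalid surfaces")
  if (mode == "axial") {
    return((rpe[column] - ilm[column] + 1) * geometry$axial_um_per_px)
  }
  rpe_normal_thickness(ilm, rpe, column, geometry)
}

# Distance from the RPE point along the inward local normal to the ILM,
# in um, using anisotropic pixel scales. The ILM is treated as a piecewise
# linear curve in physical coordinates.
rpe_normal_thickness <- function(ilm, rpe, column, geometry) {
  lat <- geometry$lateral_um_per_px; ax <- geometry$axial_um_per_px
  hw <- max(1L, round(250 / lat))
  cols <- max(1L, column - hw):min(length(rpe), column + hw)
  cols <- cols[!is.na(rpe[cols])]
  x <- cols * lat; y <- rpe[cols] * ax
  slope <- if (length(cols) > 1L) cov(x, y) / var(x) else 0
  # unit inward normal (pointing to smaller depth/row values)
  nvec <- c(slope, -1) / sqrt(1 + slope^2)
  p0 <- c(column * lat, rpe[column] * ax)
  ilm_at <- function(xq) {
    cq <- xq / lat
    c1 <- floor(cq); c2 <- ceiling(cq)
    if (c1 < 1 || c2 > length(ilm) || is.na(ilm[c1]) || is.na(ilm[c2])) return(NA_real_)
    w <- cq - c1
    ((1 - w) * ilm[c1] + w * ilm[c2]) * ax
  }
  f <- function(t) {
    p <- p0 + t * nvec
    yi <- ilm_at(p[1])
    if (is.na(yi)) return(NA_real_)
    p[2] - yi
  }
  upper <- (rpe[column] - ilm[column] + 1) * ax * 2 + ax
  tt <- seq(0, upper, length.out = 512)
  fv <- vapply(tt, f, numeric(1))
  cross <- which(!is.na(fv[-1]) & !is.na(fv[-length(fv)]) &
                   fv[-length(fv)] > 0 & fv[-1] <= 0)
  if (!length(cross)) return((rpe[column] - ilm[column] + 1) * ax)
  i <- cross[1]
  t0 <- tt[i]; t1 <- tt[i + 1]
  f0 <- fv[i]; f1 <- fv[i + 1]
  # one axial quantum restores the inclusive-count convention of axial mode,
  # so the two modes agree on flat geometry
  t0 + f0 / (f0 - f1) * (t1 - t0) + ax
}

#' Measure the retinal cross-sectional area over a column interval
#'
#' Counts retina-labeled pixels with columns in the half-open interval
#' `[col_a, col_b)` and scales by the pixel footprint
#' (`lateral_um_per_px * axial_um_per_px`, ~40.37 um^2 by default).
#'
#' @param map Integer label matrix (the central B-scan).
#' @param col_a,col_b Column interval, `col_a < col_b`.
#' @param geometry A [scan_geometry()].
#' @return Area in um^2.
#' @export
measure_area <- function(map, col_a, col_b, geometry = scan_geometry()) {
  check_label_map(map)
  if (col_a >= col_b) abort("empty column interval: col_a must be < col_b")
  n <- sum(map[, col_a:(col_b - 1L)] == RETINA)
  n * geometry$lateral_um_per_px * geometry$axial_um_per_px
}

#' Orient image-direction measurements into nasal/temporal labels
#'
#' Maps measurements indexed by signed image-column offsets from the nulla
#' (positive = larger columns) onto the T1..T9 / TUn / TUt labels for a
#' given eye side and orientation convention: T1 is always the 2000-um nasal
#' reading, whichever image side that is.
#'
#' @param values Named numeric vector; names are signed image offsets in um
#'   (e.g. `"-2000"`, `"0"`, `"100"`).
#' @param side `"OD"` or `"OS"`.
#' @param convention An [orientation_convention()].
#' @return Tibble with `label`, `offset_um` (nasal-negative axis) and `value`.
#' @export
orient_record <- function(values, side, convention = orientation_convention()) {
  dir <- nasal_direction(side, convention)
  offsets <- c(seq(-2000, 2000, by = 500), -100, 100)
  labels <- c(paste0("T", 1:9), "TUn", "TUt")
  image_offset <- -dir * offsets
  value <- values[as.character(image_offset)]
  if (anyNA(value)) abort("values must be named by signed image offsets in um")
  tibble::tibble(label = labels, offset_um = offsets, value = unname(value))
}

#' Measure the full 21-parameter foveal profile of one eye
#'
#' Runs the measurement pipeline on a segmentation volume: artifact removal
#' on every B-scan, ILM/RPE extraction, 11 x 5 moving-average smoothing of
#' the ILM across the raster, nulla localization on the smoothed surface,
#' and, on the central (nulla) B-scan, the nine thicknesses T1..T9 at 500-um
#' intervals (T5 at the nulla), the umbo thicknesses TUn/TUt at +/-100 um,
#' the eight intervening areas A1..A8 between adjacent thickness columns
#' (half-open, so adjacent areas tile without overlap), and the umbo areas
#' AUn (`[TUn, nulla)`) and AUt (`[nulla, TUt)`).
#'
#' @param volume A [seg_volume()].
#' @param metadata One-row tibble from [eye_metadata()]; `side` must be
#'   known.
#' @param convention An [orientation_convention()].
#' @param window_width,window_stack ILM smoothing windows (defaults 11, 5).
#' @param mode Thickness mode, see [measure_thickness()].
#' @param roi Optional nulla search region, see [find_nulla()].
#' @return One-row tibble in measurement-table order (see
#'   [write_measurements()]); attribute `"diagnostics"` holds per-B-scan
#'   artifact counts and the nulla result.
#' @export
profile_eye <- function(volume, metadata, convention = orientation_convention(),
                        window_width = 11L, window_stack = 5L,
                        mode = "axial", roi = NULL) {
  stopifnot(inherits(volume, "seg_volume"), is.data.frame(metadata),
            nrow(metadata) == 1L)
  if (!metadata$side %in% c("OD", "OS")) abort("metadata$side must be OD or OS")
  g <- volume$geometry
  surf <- extract_surface_maps(volume, clean = TRUE)
  smoothed <- smooth_surface(surf$ilm, window_width, window_stack)
  nulla <- find_nulla(smoothed, roi = roi)
  central <- remove_artifacts(volume$bscans[[nulla$bscan]])
  s <- extract_surfaces(central)
  plan <- build_sampling_plan(nulla$column, g, metadata$side, convention)
  thick <- vapply(plan$column, function(cc) {
    measure_thickness(s$ilm, s$rpe, cc, g, mode = mode)
  }, numeric(1))
  names(thick) <- plan$label
  tcols <- plan$column[match(paste0("T", 1:9), plan$label)]
  areas <- vapply(1:8, function(i) {
    cols <- cols_half_open(tcols[i], tcols[i + 1])
    measure_area(central, min(cols), max(cols) + 1L, g)
  }, numeric(1))
  names(areas) <- paste0("A", 1:8)
  cun <- plan$column[plan$label == "TUn"]
  cut <- plan$column[plan$label == "TUt"]
  ucols_n <- cols_half_open(cun, tcols[5])
  ucols_t <- cols_half_open(tcols[5], cut)
  aun <- measure_area(central, min(ucols_n), max(ucols_n) + 1L, g)
  aut <- measure_area(central, min(ucols_t), max(ucols_t) + 1L, g)
  rec <- dplyr::bind_cols(
    metadata[, c("eye_id", "side", "sex", "origin")],
    tibble::tibble(nulla_bscan = nulla$bscan, nulla_col = nulla$column),
    tibble::as_tibble(as.list(thick[paste0("T", 1:9)])),
    tibble::tibble(TUn = unname(thick["TUn"]), TUt = unname(thick["TUt"])),
    tibble::as_tibble(as.list(areas)),
    tibble::tibble(AUn = aun, AUt = aut)
  )[, measurement_header()]
  attr(rec, "diagnostics") <- list(artifacts = surf$diagnostics, nulla = nulla)
  rec
}
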