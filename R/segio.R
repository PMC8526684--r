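#' Default color palette for segmentation label maps
#'
#' Colors used when label maps are written to, or read from, image files:
#' one opaque RGB color per compartment (brown vitreous, blue retina, orange
#' choroid, gray sclera). Any palette can be supplied as a named character
#' vector of hex colors with names `vitreous`, `retina`, `choroid`, `sclera`.
#'
#' @return Named character vector of four hex colors.
#' @export
default_palette <- function() {
  c(vitreous = "#7A4A1F", retina = "#2B6CB0", choroid = "#ED8936",
    sclera = "#A0AEC0")
}

check_palette <- function(palette) {
  need <- names(seg_labels())
  if (!all(need %in% names(palette))) {
    abort(paste0("palette must name colors for: ", paste(need, collapse = ", ")))
  }
  rgb <- col2rgb(palette[need])
  key <- rgb[1, ] * 65536L + rgb[2, ] * 256L + rgb[3, ]
  if (anyDuplicated(key)) abort("palette colors must be distinct")
  setNames(key, need)
}

check_label_map <- function(map) {
  if (!is.matrix(map)) abort("a label map must be a matrix")
  if (any(map != as.integer(map))) abort("label maps must hold integer label codes")
  bad <- !(map %in% seg_labels())
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("invalid label value %s at (row %d, col %d)",
                  format(map[idx[1], idx[2]]), idx[1], idx[2]))
  }
  invisible(map)
}

#' Construct a segmentation volume
#'
#' A segmentation volume is an ordered stack of per-B-scan label maps
#' (integer matrices coded per [seg_labels()]) plus its [scan_geometry()].
#'
#' @param bscans List of label matrices, one per raster line, in raster order.
#' @param geometry A [scan_geometry()].
#' @return Object of class `seg_volume`.
#' @export
seg_volume <- function(bscans, geometry = scan_geometry()) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (length(bscans) != geometry$n_bscans) {
    abort(sprintf("expected %d B-scans, got %d", geometry$n_bscans, length(bscans)))
  }
  for (i in seq_along(bscans)) {
    m <- bscans[[i]]
    check_label_map(m)
    if (nrow(m) != geometry$height_px || ncol(m) != geometry$width_px) {
      abort(sprintf("B-scan %d is %d x %d, expected %d x %d",
                    i, nrow(m), ncol(m), geometry$height_px, geometry$width_px))
    }
  }
  structure(list(bscans = bscans, geometry = geometry), class = "seg_volume")
}

#' @export
print.seg_volume <- function(x, ...) {
  cat(sprintf("<seg_volume> %d B-scans of %d x %d px\n",
              length(x$bscans), nrow(x$bscans[[1]]), ncol(x$bscans[[1]])))
  invisible(x)
}

# ---- nearest-neighbor rescale ------------------------------------------------

# Center-aligned nearest-neighbor source index map: output index i (1-based)
# samples input index floor((i - 0.5) * n_in / n_out) + 1. Identity when
# n_in == n_out, hence rescaling is idempotent at the target size.
nn_index <- function(n_out, n_in) {
  pmin(pmax(floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1L, 1L), n_in)
}

#' Rescale a label map with nearest-neighbor sampling
#'
#' B-scans are exported as 512 x 496 px images and analyzed at 512 x 512;
#' label maps are rescaled by nearest-neighbor index mapping so that no
#' interpolated (fractional) labels can arise.
#'
#' @param map Integer label matrix.
#' @param height_px,width_px Target size (default 512 x 512).
#' @return Label matrix of the target size containing only labels present in
#'   the input.
#' @export
rescale_labels <- function(map, height_px = 512L, width_px = 512L) {
  check_label_map(map)
  map[nn_index(height_px, nrow(map)), nn_index(width_px, ncol(map)), drop = FALSE]
}

# ---- image file I/O ----------------------------------------------------------

rgb_key_from_array <- function(img) {
  if (length(dim(img)) == 2L) {
    v <- round(img * 255)
    return(v * 65536L + v * 256L + v)
  }
  r <- round(img[, , 1] * 255); g <- round(img[, , 2] * 255); b <- round(img[, , 3] * 255)
  r * 65536L + g * 256L + b
}

map_from_keys <- function(keys, pal_keys, file) {
  lab <- match(keys, pal_keys)
  dim(lab) <- dim(keys)
  if (anyNA(lab)) {
    idx <- which(is.na(lab), arr.ind = TRUE)[1, ]
    k <- keys[idx[1], idx[2]]
    abort(sprintf(
      "%s: pixel color #%06X at (row %d, col %d) is not in the palette",
      file, k, idx[1], idx[2]
    ))
  }
  matrix(unname(seg_labels())[lab], nrow(keys), ncol(keys))
}

read_bmp24 <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "BM")) abort(sprintf("%s: not a BMP file", path))
  readBin(con, "integer", 2, size = 4)          # file size + reserved
  off <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size < 40) abort(sprintf("%s: unsupported BMP header", path))
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 2)          # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  comp <- readBin(con, "integer", 1, size = 4)
  if (bpp != 24L || comp != 0L) {
    abort(sprintf("%s: only uncompressed 24-bit BMP is supported", path))
  }
  seek(con, off)
  stride <- ((3 * w + 3) %/% 4) * 4
  bottom_up <- h > 0
  h <- abs(h)
  raw <- readBin(con, "raw", stride * h)
  if (length(raw) < stride * h) abort(sprintf("%s: truncated BMP pixel data", path))
  px <- matrix(as.integer(raw), nrow = stride)[seq_len(3 * w), , drop = FALSE]
  b <- px[seq(1, 3 * w, 3), , drop = FALSE]
  g <- px[seq(2, 3 * w, 3), , drop = FALSE]
  r <- px[seq(3, 3 * w, 3), , drop = FALSE]
  key <- t(r * 65536L + g * 256L + b)           # rows = image rows (bottom-up)
  if (bottom_up) key <- key[h:1, , drop = FALSE]
  key
}

write_bmp24 <- function(key, path) {
  h <- nrow(key); w <- ncol(key)
  stride <- ((3 * w + 3) %/% 4) * 4
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(54 + stride * h), con, size = 4)
  writeBin(0L, con, size = 4)
  writeBin(54L, con, size = 4)
  writeBin(40L, con, size = 4)
  writeBin(as.integer(w), con, size = 4)
  writeBin(as.integer(h), con, size = 4)         # positive: bottom-up
  writeBin(1L, con, size = 2)
  writeBin(24L, con, size = 2)
  writeBin(0L, con, size = 4)
  writeBin(as.integer(stride * h), con, size = 4)
  writeBin(rep(0L, 4), con, size = 4)
  buf <- matrix(0L, nrow = stride, ncol = h)
  km <- t(key[h:1, , drop = FALSE])              # cols = image rows, bottom-up
  buf[seq(1, 3 * w, 3), ] <- km %% 256L
  buf[seq(2, 3 * w, 3), ] <- (km %/% 256L) %% 256L
  buf[seq(3, 3 * w, 3), ] <- km %/% 65536L
  writeBin(as.raw(buf), con)
  invisible(path)
}

read_label_image <- function(path, palette = default_palette()) {
  pal <- check_palette(palette)
  ext <- tolower(tools::file_ext(path))
  keys <- switch(ext,
    png = rgb_key_from_array(png::readPNG(path)),
    bmp = read_bmp24(path),
    abort(sprintf("%s: unsupported image format '%s' (png or bmp)", path, ext))
  )
  map_from_keys(keys, pal, basename(path))
}

write_label_image <- function(map, path, palette = default_palette()) {
  check_label_map(map)
  pal <- check_palette(palette)
  key <- matrix(pal[match(map, unname(seg_labels()))], nrow(map), ncol(map))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- array(0, dim = c(nrow(map), ncol(map), 3))
    arr[, , 1] <- (key %/% 65536L) / 255
    arr[, , 2] <- ((key %/% 256L) %% 256L) / 255
    arr[, , 3] <- (key %% 256L) / 255
    png::writePNG(arr, path)
  } else if (ext == "bmp") {
    write_bmp24(key, path)
  } else {
    abort(sprintf("%s: unsupported image format '%s' (png or bmp)", path, ext))
  }
  invisible(path)
}

#' Load a segmentation volume from per-B-scan label images
#'
#' Reads one PNG or BMP label image per raster line, maps pixel colors to
#' compartment labels through the palette, rescales each map to the geometry's
#' raster size by nearest neighbor (the device exports 512 x 496 px; analysis
#' runs at 512 x 512), and assembles the stack in file order.
#'
#' @param paths Character vector of image files, one per B-scan, in raster
#'   order; `length(paths)` must equal `geometry$n_bscans`.
#' @param geometry A [scan_geometry()].
#' @param palette Named hex color vector, see [default_palette()].
#' @return A [seg_volume()].
#' @export
load_volume <- function(paths, geometry = scan_geometry(),
                        palette = default_palette()) {
  if (length(paths) != geometry$n_bscans) {
    abort(sprintf("expected %d B-scan files, got %d", geometry$n_bscans, length(paths)))
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("missing B-scan file(s): ", paste(basename(missing), collapse = ", ")))
  }
  maps <- lapply(paths, function(p) {
    m <- read_label_image(p, palette)
    if (nrow(m) != geometry$height_px || ncol(m) != geometry$width_px) {
      m <- rescale_labels(m, geometry$height_px, geometry$width_px)
    }
    if (nrow(m) != geometry$height_px || ncol(m) != geometry$width_px) {
      abort(sprintf("%s: image is %d x %d after rescale, expected %d x %d",
                    basename(p), nrow(m), ncol(m), geometry$height_px, geometry$width_px))
    }
    m
  })
  seg_volume(maps, geometry)
}

#' Write a segmentation volume as per-B-scan label images
#'
#' @param volume A [seg_volume()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; files are `<prefix>_<index>.<format>`.
#' @param format `"png"` (default) or `"bmp"`.
#' @inheritParams load_volume
#' @return Character vector of written file paths, invisibly.
#' @export
write_volume <- function(volume, dir, prefix = "bscan", format = c("png", "bmp"),
                         palette = default_palette()) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%02d.%s", prefix, seq_along(volume$bscans), format))
  for (i in seq_along(paths)) write_label_image(volume$bscans[[i]], paths[i], palette)
  invisible(paths)
}

# ---- measurement tables ------------------------------------------------------

measurement_header <- function() {
  c("eye_id", "side", "sex", "origin", "nulla_bscan", "nulla_col",
    paste0("T", 1:9), "TUn", "TUt", paste0("A", 1:8), "AUn", "AUt")
}

thickness_columns <- function() c(paste0("T", 1:9), "TUn", "TUt")
area_columns <- function() c(paste0("A", 1:8), "AUn", "AUt")

fmt_area <- function(x) sub("0+$", "", sub("\\.0+$", "", sprintf("%.8f", x)))

#' Write and read per-eye measurement tables
#'
#' One row per eye with the fixed header `eye_id, side, sex, origin,
#' nulla_bscan, nulla_col, T1..T9, TUn, TUt, A1..A8, AUn, AUt`. Thicknesses
#' are in um, written with one decimal (exact for the default 3.9 um axial
#' quantum); areas are in um^2, written with enough decimals for an exact
#' round trip under the default geometry. Nulla coordinates are 1-based.
#'
#' `read_measurements()` also serves as the import adapter for an externally
#' produced table with the same header (e.g. a CSV export of a published
#' measurement dataset).
#'
#' @param records Tibble of measurement records (rows from [profile_eye()]).
#' @param path CSV file path.
#' @return `write_measurements()` returns `path` invisibly;
#'   `read_measurements()` returns a tibble with the header above.
#' @export
write_measurements <- function(records, path) {
  if (!nrow(records)) abort("no records to write")
  need <- measurement_header()
  if (!all(need %in% names(records))) {
    abort(paste0("records lack column(s): ",
                 paste(setdiff(need, names(records)), collapse = ", ")))
  }
  if (anyDuplicated(records[, c("eye_id", "side")])) {
    abort("duplicate (eye_id, side) rows are not allowed")
  }
  out <- records[, need]
  for (cn in thickness_columns()) out[[cn]] <- sprintf("%.1f", records[[cn]])
  for (cn in area_columns()) out[[cn]] <- fmt_area(records[[cn]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  tbl <- readr::read_csv(
    path, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      eye_id = "c", side = "c", sex = "c", origin = "c",
      nulla_bscan = "i", nulla_col = "i", .default = "d"
    )
  )
  need <- measurement_header()
  if (!all(need %in% names(tbl))) {
    abort(paste0(path, " lacks measurement column(s): ",
                 paste(setdiff(need, names(tbl)), collapse = ", ")))
  }
  tbl[, need]
}

#' Per-eye metadata constructor
#'
#' @param eye_id Identifier, unique per (eye_id, side).
#' @param side `"OD"` (right) or `"OS"` (left); mandatory.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param origin `"Mauritius"`, `"Asian"` or `"unknown"`; unknown-origin eyes
#'   are excluded from the MANOVA/ANOVA battery downstream.
#' @return One-row tibble.
#' @export
eye_metadata <- function(eye_id, side, sex = "unknown", origin = "unknown") {
  side <- match.arg(side, c("OD", "OS"))
  sex <- match.arg(sex, c("male", "female", "unknown"))
  origin <- match.arg(origin, c("Mauritius", "Asian", "unknown"))
  tibble::tibble(eye_id = as.character(eye_id), side = side, sex = sex, origin = origin)
}
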