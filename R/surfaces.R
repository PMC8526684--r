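# Connected-component bookkeeping for label maps. Regions are 4-connected
# (diagonal contact does not merge); "surrounded by" is judged on the
# 8-neighborhood of a region, so a diagonal leak cannot defeat enclosure.

label_regions <- function(map) {
  out <- matrix(0L, nrow(map), ncol(map))
  n <- 0L
  for (v in seg_labels()) {
    cc <- EBImage::bwlabel(map == v)
    cc <- matrix(as.integer(cc), nrow(map), ncol(map))
    k <- max(cc)
    if (k > 0L) {
      sel <- cc > 0L
      out[sel] <- cc[sel] + n
      n <- n + k
    }
  }
  out
}

# Labels present in the 8-neighborhood of a region (NULL if the region
# touches the image border). Works on the region's bounding box.
region_ring_labels <- function(map, regions, id) {
  idx <- which(regions == id, arr.ind = TRUE)
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  if (r1 == 1L || c1 == 1L || r2 == nrow(map) || c2 == ncol(map)) return(NULL)
  rows <- (r1 - 1L):(r2 + 1L); cols <- (c1 - 1L):(c2 + 1L)
  sub <- regions[rows, cols] == id
  grown <- sub
  n <- nrow(sub); m <- ncol(sub)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    sh <- matrix(FALSE, n, m)
    sh[max(1, 1 + dr):min(n, n + dr), max(1, 1 + dc):min(m, m + dc)] <-
      sub[max(1, 1 - dr):min(n, n - dr), max(1, 1 - dc):min(m, m - dc)]
    grown <- grown | sh
  }
  ring <- grown & !sub
  unique(map[rows, cols][ring])
}

#' Remove enclosed segmentation artifacts from a label map
#'
#' In a clean segmentation map the four compartments each form one large
#' connected region; any additional connected region is a segmentation
#' artifact. For every label, the largest 4-connected region is kept
#' untouched; every other region whose entire 8-neighborhood carries exactly
#' one other label is relabeled to that surrounding label. The pass repeats
#' until a fixpoint, so nested artifacts resolve too. Regions touching the
#' image border, or bordered by two or more labels, are left unchanged and
#' counted in the diagnostics.
#'
#' @param map Integer label matrix.
#' @return The cleaned map, with attribute `"diagnostics"`: a list with
#'   `n_relabeled` (regions removed) and `n_unresolved` (non-maximal regions
#'   left unchanged).
#' @export
remove_artifacts <- function(map) {
  check_label_map(map)
  n_relabeled <- 0L
  repeat {
    regions <- label_regions(map)
    sizes <- tabulate(regions)
    region_label <- map[match(seq_along(sizes), regions)]
    keep <- vapply(seg_labels(), function(v) {
      ids <- which(region_label == v)
      if (!length(ids)) return(NA_integer_)
      ids[which.max(sizes[ids])]
    }, integer(1))
    extras <- setdiff(which(sizes > 0L), keep[!is.na(keep)])
    if (!length(extras)) {
      n_unresolved <- 0L
      break
    }
    changed <- FALSE
    unresolved <- 0L
    for (id in extras) {
      ring <- region_ring_labels(map, regions, id)
      if (!is.null(ring) && length(ring) == 1L && ring != region_label[id]) {
        map[regions == id] <- ring
        changed <- TRUE
        n_relabeled <- n_relabeled + 1L
      } else {
        unresolved <- unresolved + 1L
      }
    }
    if (!changed) {
      n_unresolved <- unresolved
      break
    }
  }
  attr(map, "diagnostics") <- list(n_relabeled = n_relabeled,
                                   n_unresolved = n_unresolved)
  map
}

#' Extract the inner and outer retinal boundaries from a label map
#'
#' Per column, the ILM (internal limiting membrane) is the first retina row
#' scanning downward and the outer boundary (outer edge of the retinal
#' pigment epithelium) the last retina row. Columns without retina pixels
#' are `NA` ("missing").
#'
#' @param map Integer label matrix, ideally after [remove_artifacts()].
#' @return List with numeric vectors `ilm` and `rpe` (one entry per column,
#'   `NA` where missing); errors if the map has no retina at all.
#' @export
extract_surfaces <- function(map) {
  check_label_map(map)
  idx <- which(map == RETINA, arr.ind = TRUE)
  if (!nrow(idx)) abort("label map contains no retina pixels")
  w <- ncol(map)
  ilm <- rep(NA_real_, w); rpe <- rep(NA_real_, w)
  lo <- tapply(idx[, 1], idx[, 2], min)
  hi <- tapply(idx[, 1], idx[, 2], max)
  cols <- as.integer(names(lo))
  ilm[cols] <- as.numeric(lo)
  rpe[cols] <- as.numeric(hi)
  list(ilm = ilm, rpe = rpe)
}

#' Stack the per-B-scan ILM (and RPE) into raster surface maps
#'
#' @param volume A [seg_volume()].
#' @param clean Run [remove_artifacts()] on each B-scan first (default TRUE).
#' @return List with matrices `ilm` and `rpe` of size `n_bscans` x
#'   `width_px` (row depth in pixels, `NA` = missing) and a tibble
#'   `diagnostics` of per-B-scan artifact counts.
#' @export
extract_surface_maps <- function(volume, clean = TRUE) {
  stopifnot(inherits(volume, "seg_volume"))
  g <- volume$geometry
  ilm <- matrix(NA_real_, g$n_bscans, g$width_px)
  rpe <- matrix(NA_real_, g$n_bscans, g$width_px)
  diag <- vector("list", g$n_bscans)
  for (b in seq_len(g$n_bscans)) {
    m <- volume$bscans[[b]]
    if (clean) {
      m <- remove_artifacts(m)
      d <- attr(m, "diagnostics")
    } else {
      d <- list(n_relabeled = NA_integer_, n_unresolved = NA_integer_)
    }
    s <- extract_surfaces(m)
    ilm[b, ] <- s$ilm
    rpe[b, ] <- s$rpe
    diag[[b]] <- tibble::tibble(bscan = b, n_relabeled = d$n_relabeled,
                                n_unresolved = d$n_unresolved)
  }
  list(ilm = ilm, rpe = rpe, diagnostics = dplyr::bind_rows(diag))
}

#' Smooth a surface map with a 2-D moving average over the raster
#'
#' Each cell becomes the unweighted mean of the defined cells in a centered
#' window spanning `window_width` columns (B-scan width dimension) and
#' `window_stack` B-scans (stack dimension); the defaults 11 x 5 are the
#' smoothing the nulla search runs on. Windows are truncated at the raster
#' edges and around missing cells, renormalizing by the number of cells
#' actually present, so no padding biases the edges. A cell whose whole
#' neighborhood is missing stays missing.
#'
#' @param surface Numeric matrix `n_bscans` x `width_px` (`NA` = missing).
#' @param window_width Odd window size along columns (default 11).
#' @param window_stack Odd window size across B-scans (default 5); must not
#'   exceed the number of B-scans.
#' @return Numeric matrix of the same size (fractional values).
#' @export
smooth_surface <- function(surface, window_width = 11L, window_stack = 5L) {
  stopifnot(is.matrix(surface))
  if (window_width %% 2L == 0L || window_stack %% 2L == 0L) {
    abort("window sizes must be odd")
  }
  if (window_stack > nrow(surface)) {
    abort("window_stack must not exceed the number of B-scans")
  }
  n <- nrow(surface); m <- ncol(surface)
  present <- !is.na(surface)
  vals <- ifelse(present, surface, 0)
  num <- matrix(0, n, m); den <- matrix(0, n, m)
  hw <- (window_width - 1L) %/% 2L
  hs <- (window_stack - 1L) %/% 2L
  for (dr in -hs:hs) {
    sr_dst <- max(1, 1 + dr):min(n, n + dr)
    sr_src <- max(1, 1 - dr):min(n, n - dr)
    for (dc in -hw:hw) {
      sc_dst <- max(1, 1 + dc):min(m, m + dc)
      sc_src <- max(1, 1 - dc):min(m, m - dc)
      num[sr_dst, sc_dst] <- num[sr_dst, sc_dst] + vals[sr_src, sc_src]
      den[sr_dst, sc_dst] <- den[sr_dst, sc_dst] + present[sr_src, sc_src]
    }
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
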