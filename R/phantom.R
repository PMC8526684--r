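#' Parametric foveal-pit phantom specification
#'
#' Describes a synthetic four-compartment segmentation volume with a
#' Gaussian foveal depression: a flat retina of `peripheral_thickness_um`
#' whose inner surface (ILM) dips by `pit_depth_um` at `pit_center`,
#' with lateral extent `pit_halfwidth_um` (the Gaussian sigma, isotropic in
#' um across columns and B-scans). The outer retinal boundary (RPE) is flat
#' at pixel row `rpe_row`; a choroid band of `choroid_px` rows sits below it
#' and sclera fills the rest. Optional ILM noise adds independent integer
#' row jitter per (B-scan, column).
#'
#' Defaults mimic the cynomolgus macula: peripheral thickness 351 um
#' (90 rows at 3.9 um), pit depth 140 um and sigma 300 um give a central
#' thickness near 210 um rising past 280 um at 500 um eccentricity.
#'
#' @param geometry A [scan_geometry()].
#' @param pit_center Length-2 integer vector `(bscan, column)`, 1-based.
#' @param pit_depth_um Pit depth in um; must be smaller than
#'   `peripheral_thickness_um`.
#' @param pit_halfwidth_um Gaussian sigma of the pit in um.
#' @param peripheral_thickness_um Retinal thickness far from the pit, um.
#' @param rpe_row Pixel row of the outer retinal boundary (flat), or one row
#'   per column for a tilted RPE.
#' @param choroid_px Height of the choroid band in rows.
#' @param ilm_noise_sigma_px Standard deviation of the per-column integer ILM
#'   jitter, in rows; 0 disables noise.
#' @param seed Integer seed; mandatory whenever `ilm_noise_sigma_px > 0`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = scan_geometry(),
                         pit_center = c(13L, 256L),
                         pit_depth_um = 140,
                         pit_halfwidth_um = 300,
                         peripheral_thickness_um = 351,
                         rpe_row = 330L,
                         choroid_px = 60L,
                         ilm_noise_sigma_px = 0,
                         seed = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (pit_depth_um >= peripheral_thickness_um) {
    abort("pit_depth_um must be smaller than peripheral_thickness_um")
  }
  if (pit_depth_um < 0 || pit_halfwidth_um <= 0) {
    abort("pit_depth_um must be >= 0 and pit_halfwidth_um > 0")
  }
  if (pit_center[1] < 1 || pit_center[1] > geometry$n_bscans ||
      pit_center[2] < 1 || pit_center[2] > geometry$width_px) {
    abort("pit_center must lie inside the raster")
  }
  if (ilm_noise_sigma_px > 0 && is.null(seed)) {
    abort("a seed is mandatory when ilm_noise_sigma_px > 0")
  }
  thick_px <- round(peripheral_thickness_um / geometry$axial_um_per_px)
  if (length(rpe_row) == 1L) rpe_row <- rep(as.integer(rpe_row), geometry$width_px)
  if (min(rpe_row) - thick_px + 1L < 1L) {
    abort("peripheral retina does not fit above rpe_row")
  }
  if (max(rpe_row) + choroid_px >= geometry$height_px) {
    abort("choroid band does not fit below rpe_row")
  }
  structure(list(
    geometry = geometry, pit_center = as.integer(pit_center),
    pit_depth_um = pit_depth_um, pit_halfwidth_um = pit_halfwidth_um,
    peripheral_thickness_um = peripheral_thickness_um,
    rpe_row = as.integer(rpe_row), choroid_px = as.integer(choroid_px),
    ilm_noise_sigma_px = ilm_noise_sigma_px, seed = seed
  ), class = "phantom_spec")
}

# Noiseless analytic ILM rows for one B-scan (vector over columns).
phantom_ilm_rows <- function(spec, bscan) {
  g <- spec$geometry
  base_ilm <- spec$rpe_row - round(spec$peripheral_thickness_um / g$axial_um_per_px) + 1L
  depth_px <- spec$pit_depth_um / g$axial_um_per_px
  d2 <- ((bscan - spec$pit_center[1]) * g$bscan_spacing_um)^2 +
    ((seq_len(g$width_px) - spec$pit_center[2]) * g$lateral_um_per_px)^2
  base_ilm + round(depth_px * exp(-d2 / (2 * spec$pit_halfwidth_um^2)))
}

build_bscan_map <- function(ilm, rpe, choroid_px, geometry) {
  h <- geometry$height_px; w <- geometry$width_px
  rows <- matrix(seq_len(h), h, w)
  ilm_m <- matrix(ilm, h, w, byrow = TRUE)
  rpe_m <- matrix(rpe, h, w, byrow = TRUE)
  map <- matrix(VITREOUS, h, w)
  map[rows >= ilm_m & rows <= rpe_m] <- RETINA
  map[rows > rpe_m & rows <= rpe_m + choroid_px] <- CHOROID
  map[rows > rpe_m + choroid_px] <- SCLERA
  map
}

#' Generate a synthetic segmentation volume with analytic ground truth
#'
#' Builds the four-compartment volume described by a [phantom_spec()] and the
#' ground truth a perfect measurement would return: the true nulla (the pit
#' center) and the full 21-parameter thickness/area profile, discretized with
#' exactly the rounding rules the measurement pipeline uses (whole-column
#' lateral offsets, inclusive row counts times the axial scale, half-open
#' column intervals for areas). On a noiseless phantom, [profile_eye()]
#' therefore reproduces the truth record exactly.
#'
#' @param spec A [phantom_spec()].
#' @param metadata One-row tibble from [eye_metadata()]; its `side` fixes the
#'   nasal/temporal labeling of the truth record.
#' @param convention Orientation convention, see [orientation_convention()].
#' @return List with elements `volume` (a [seg_volume()]) and `truth` (list
#'   with `nulla`, a `(bscan, column)` vector; `record`, a one-row tibble in
#'   measurement-table format; and `profile`, a tibble of per-offset columns
#'   and thicknesses).
#' @export
generate_phantom <- function(spec, metadata = eye_metadata("phantom", "OD"),
                             convention = orientation_convention()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  ilm0 <- t(vapply(seq_len(g$n_bscans), function(b) phantom_ilm_rows(spec, b),
                   numeric(g$width_px)))           # n_bscans x width
  ilm <- ilm0
  if (spec$ilm_noise_sigma_px > 0) {
    jit <- with_seed(spec$seed, {
      matrix(round(rnorm(length(ilm0), 0, spec$ilm_noise_sigma_px)),
             nrow(ilm0), ncol(ilm0))
    })
    rpe_m <- matrix(spec$rpe_row, nrow(ilm0), ncol(ilm0), byrow = TRUE)
    ilm <- pmin(pmax(ilm0 + jit, 1), rpe_m)
  }
  maps <- lapply(seq_len(g$n_bscans), function(b) {
    build_bscan_map(ilm[b, ], spec$rpe_row, spec$choroid_px, g)
  })
  volume <- seg_volume(maps, g)
  truth <- phantom_truth(spec, ilm0, metadata, convention)
  list(volume = volume, truth = truth)
}

# Ground truth from the noiseless surfaces, using the measurement pipeline's
# discretization (shared helpers from the morphometry module).
phantom_truth <- function(spec, ilm0, metadata, convention) {
  g <- spec$geometry
  b0 <- spec$pit_center[1]; c0 <- spec$pit_center[2]
  plan <- build_sampling_plan(c0, g, metadata$side, convention)
  ilm_c <- ilm0[b0, ]
  counts <- spec$rpe_row - ilm_c + 1                 # retina rows per column
  thick <- counts[plan$column] * g$axial_um_per_px
  names(thick) <- plan$label
  px_area <- g$lateral_um_per_px * g$axial_um_per_px
  tcols <- plan$column[match(paste0("T", 1:9), plan$label)]
  areas <- vapply(1:8, function(i) {
    sum(counts[cols_half_open(tcols[i], tcols[i + 1])]) * px_area
  }, numeric(1))
  names(areas) <- paste0("A", 1:8)
  cun <- plan$column[plan$label == "TUn"]
  cut <- plan$column[plan$label == "TUt"]
  aun <- sum(counts[cols_half_open(cun, tcols[5])]) * px_area
  aut <- sum(counts[cols_half_open(tcols[5], cut)]) * px_area
  record <- dplyr::bind_cols(
    metadata,
    tibble::tibble(nulla_bscan = b0, nulla_col = c0),
    tibble::as_tibble(as.list(thick[paste0("T", 1:9)])),
    tibble::tibble(TUn = unname(thick["TUn"]), TUt = unname(thick["TUt"])),
    tibble::as_tibble(as.list(areas)),
    tibble::tibble(AUn = aun, AUt = aut)
  )
  list(
    nulla = c(bscan = b0, column = c0),
    record = record[, measurement_header()],
    profile = tibble::tibble(
      label = plan$label, offset_um = plan$offset_um, column = plan$column,
      thickness_um = unname(thick)
    )
  )
}

#' Segmentation-artifact injection specification
#'
#' Describes small mislabeled discs ("segmentation artifacts") to place
#' strictly inside a host compartment: each blob is a 4-connected disc of
#' radius `blob_radius_px` carrying `wrong_label`, whose entire 8-neighborhood
#' remains the host label, so that artifact removal can invert the injection
#' exactly.
#'
#' @param n_blobs Number of blobs to place across the volume.
#' @param blob_radius_px Disc radius in pixels.
#' @param host Host compartment name(s) (recycled), e.g. `"sclera"`.
#' @param wrong_label Label name(s) the blobs carry (recycled), e.g.
#'   `"choroid"`; must differ from the host.
#' @param seed Integer seed (mandatory: placement is random).
#' @return Object of class `artifact_spec`.
#' @export
artifact_spec <- function(n_blobs = 2L, blob_radius_px = 4L,
                          host = "sclera", wrong_label = "choroid",
                          seed = 1L) {
  host <- rep_len(match.arg(host, names(seg_labels()), several.ok = TRUE), n_blobs)
  wrong_label <- rep_len(match.arg(wrong_label, names(seg_labels()), several.ok = TRUE),
                         n_blobs)
  if (n_blobs > 0 && any(host == wrong_label)) {
    abort("wrong_label must differ from the host compartment")
  }
  structure(list(n_blobs = as.integer(n_blobs),
                 blob_radius_px = as.integer(blob_radius_px),
                 host = host, wrong_label = wrong_label, seed = seed),
            class = "artifact_spec")
}

disc_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2, ]
}

ring_offsets <- function(disc) {
  grown <- unique(do.call(rbind, lapply(c(-1, 0, 1), function(er) {
    do.call(rbind, lapply(c(-1, 0, 1), function(ec) {
      data.frame(dr = disc$dr + er, dc = disc$dc + ec)
    }))
  })))
  key <- paste(grown$dr, grown$dc)
  grown[!(key %in% paste(disc$dr, disc$dc)), ]
}

#' Inject mislabeled artifact blobs into a segmentation volume
#'
#' Places each blob of an [artifact_spec()] at a random position (seeded)
#' inside its host compartment, relabeling exactly the disc pixels. Placement
#' is rejected and resampled (up to 500 tries per blob) until the disc and
#' its full 8-neighborhood lie in the host label, which also keeps blobs from
#' touching each other, compartment borders, or the image edge.
#'
#' @param volume A [seg_volume()].
#' @param spec An [artifact_spec()].
#' @return The modified volume; attribute `"blobs"` records placements
#'   (`bscan`, `row`, `col`, `host`, `wrong_label`).
#' @export
inject_artifacts <- function(volume, spec) {
  stopifnot(inherits(volume, "seg_volume"), inherits(spec, "artifact_spec"))
  if (spec$n_blobs == 0L) return(volume)
  disc <- disc_offsets(spec$blob_radius_px)
  ring <- ring_offsets(disc)
  lab <- seg_labels()
  h <- volume$geometry$height_px; w <- volume$geometry$width_px
  margin <- spec$blob_radius_px + 2L
  placements <- vector("list", spec$n_blobs)
  volume$bscans <- with_seed(spec$seed, {
    maps <- volume$bscans
    for (k in seq_len(spec$n_blobs)) {
      hostv <- lab[[spec$host[k]]]; wrongv <- lab[[spec$wrong_label[k]]]
      placed <- FALSE
      for (try in seq_len(500L)) {
        b <- sample.int(length(maps), 1L)
        r <- sample(seq.int(margin, h - margin), 1L)
        c <- sample(seq.int(margin, w - margin), 1L)
        cells_d <- cbind(r + disc$dr, c + disc$dc)
        cells_r <- cbind(r + ring$dr, c + ring$dc)
        if (all(maps[[b]][cells_d] == hostv) && all(maps[[b]][cells_r] == hostv)) {
          maps[[b]][cells_d] <- wrongv
          placements[[k]] <- tibble::tibble(
            bscan = b, row = r, col = c,
            host = spec$host[k], wrong_label = spec$wrong_label[k]
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf("could not place blob %d inside compartment '%s'",
                      k, spec$host[k]))
      }
    }
    maps
  })
  attr(volume, "blobs") <- dplyr::bind_rows(placements)
  volume
}
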