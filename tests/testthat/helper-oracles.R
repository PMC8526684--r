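# Independent oracles and small fixture builders, written without reusing the
# package's own region machinery.

# 4-connected flood fill over equal-label pixels; returns an integer region
# id matrix.
flood_fill_regions <- function(map) {
  h <- nrow(map); w <- ncol(map)
  out <- matrix(0L, h, w)
  queue <- integer(h * w)
  nid <- 0L
  for (start in seq_len(h * w)) {
    if (out[start] != 0L) next
    nid <- nid + 1L
    lab <- map[start]
    queue[1] <- start
    out[start] <- nid
    lo <- 1L; hi <- 1L
    while (lo <= hi) {
      cur <- queue[lo]
      lo <- lo + 1L
      r <- ((cur - 1L) %% h) + 1L
      cc <- ((cur - 1L) %/% h) + 1L
      for (nb in c(if (r > 1L) cur - 1L, if (r < h) cur + 1L,
                   if (cc > 1L) cur - h, if (cc < w) cur + h)) {
        if (out[nb] == 0L && map[nb] == lab) {
          out[nb] <- nid
          hi <- hi + 1L
          queue[hi] <- nb
        }
      }
    }
  }
  out
}

# Labels touching a region through its 8-neighborhood; NULL if the region
# touches the image border.
oracle_ring_labels <- function(map, regions, id) {
  h <- nrow(map); w <- ncol(map)
  cells <- which(regions == id, arr.ind = TRUE)
  if (any(cells[, 1] %in% c(1L, h)) || any(cells[, 2] %in% c(1L, w))) return(NULL)
  labs <- integer(0)
  for (k in seq_len(nrow(cells))) {
    for (dr in -1:1) for (dc in -1:1) {
      r <- cells[k, 1] + dr; cc <- cells[k, 2] + dc
      if (regions[r, cc] != id) labs <- c(labs, map[r, cc])
    }
  }
  unique(labs)
}

# Brute-force artifact remover: flood-fill every label's regions, keep the
# largest per label, relabel every other region fully surrounded by exactly
# one other label; iterate to fixpoint.
oracle_remove_artifacts <- function(map) {
  repeat {
    regions <- flood_fill_regions(map)
    sizes <- tabulate(regions)
    region_label <- map[match(seq_along(sizes), regions)]
    keep <- integer(0)
    for (v in unique(as.vector(map))) {
      ids <- which(region_label == v)
      keep <- c(keep, ids[which.max(sizes[ids])])
    }
    extras <- setdiff(seq_along(sizes), keep)
    changed <- FALSE
    for (id in extras) {
      ring <- oracle_ring_labels(map, regions, id)
      if (!is.null(ring) && length(ring) == 1L && ring != region_label[id]) {
        map[regions == id] <- ring
        changed <- TRUE
      }
    }
    if (!changed) return(map)
  }
}

# Small horizontal-band label map (one region per compartment).
band_map <- function(h = 64L, w = 64L, bounds = c(16L, 32L, 48L)) {
  lab <- seg_labels()
  map <- matrix(lab[["vitreous"]], h, w)
  map[(bounds[1] + 1):bounds[2], ] <- lab[["retina"]]
  map[(bounds[2] + 1):bounds[3], ] <- lab[["choroid"]]
  map[(bounds[3] + 1):h, ] <- lab[["sclera"]]
  map
}

# Geometry for single-B-scan toy volumes.
toy_geometry <- function(h = 64L, w = 64L, n = 1L) {
  scan_geometry(width_px = w, height_px = h, n_bscans = n)
}

# Minimal cohort tibble for the statistics battery (only the columns the
# battery touches, T1..T9 + metadata).
toy_cohort <- function(n, seed, sex_shift = 0, origin_shift = rep(0, 9)) {
  withr::with_seed(seed, {
    sex <- sample(c("male", "female"), n, replace = TRUE)
    origin <- sample(c("Mauritius", "Asian"), n, replace = TRUE)
    y <- matrix(rnorm(n * 9, 300, 10), n, 9)
    y[, 1:3] <- y[, 1:3] + (sex == "female") * sex_shift
    y <- y + outer(origin == "Asian", origin_shift)
    colnames(y) <- paste0("T", 1:9)
    dplyr::bind_cols(
      tibble::tibble(eye_id = sprintf("t%03d", seq_len(n)),
                     side = sample(c("OD", "OS"), n, replace = TRUE),
                     sex = sex, origin = origin),
      tibble::as_tibble(y)
    )
  })
}
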