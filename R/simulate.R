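#' Simulate a tabular measurement cohort
#'
#' Draws per-eye measurement records directly on the measurement-table scale
#' (no image synthesis), emulating the structure of a reference database:
#' each eye has a Gaussian-pit thickness profile whose peripheral thickness
#' and pit depth vary between animals, a center-thickness shift by
#' geographic origin, an edge-thickness shift by sex, and independent
#' per-coefficient measurement noise quantized to the axial scale. Areas are
#' derived from the mean of the adjacent thicknesses times the strip width,
#' matching the strong thickness-area correlations seen in real cohorts.
#'
#' The generator serves the statistics battery (PCA, MANOVA, ANOVA,
#' correlations) with cohorts whose group effects are known by construction.
#'
#' @param n Number of eyes.
#' @param seed Integer seed.
#' @param origin_effect_um Added center thickness (T4..T6, umbo) for Asian
#'   versus Mauritius eyes, um (default 12).
#' @param sex_effect_um Edge thickness (T1..T3, T7..T9) reduction for
#'   females versus males, um (default 5).
#' @param peripheral_um,peripheral_sd_um Mean and between-animal SD of the
#'   peripheral thickness, um.
#' @param depth_um,depth_sd_um Mean and between-animal SD of the pit depth,
#'   um.
#' @param pit_sigma_um Lateral Gaussian sigma of the pit, um (default 375).
#' @param noise_um Per-coefficient measurement noise SD, um (default 4).
#' @param prop_unknown_origin Fraction of eyes with origin recorded as
#'   unknown (excluded downstream; default 0).
#' @param geometry A [scan_geometry()] (sets the axial quantum and strip
#'   widths).
#' @return Cohort tibble in measurement-table format.
#' @export
simulate_cohort <- function(n = 80L, seed = 1L,
                            origin_effect_um = 12, sex_effect_um = 5,
                            peripheral_um = 352, peripheral_sd_um = 12,
                            depth_um = 158, depth_sd_um = 8,
                            pit_sigma_um = 375, noise_um = 4,
                            prop_unknown_origin = 0,
                            geometry = scan_geometry()) {
  ax <- geometry$axial_um_per_px
  lat <- geometry$lateral_um_per_px
  offs <- seq(-2000, 2000, by = 500)
  strip_um <- abs(um_to_cols(500, geometry)) * lat
  umbo_um <- abs(um_to_cols(100, geometry)) * lat
  with_seed(seed, {
    side <- sample(c("OD", "OS"), n, replace = TRUE)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    origin <- sample(c("Mauritius", "Asian"), n, replace = TRUE)
    periph <- rnorm(n, peripheral_um, peripheral_sd_um)
    depth <- rnorm(n, depth_um, depth_sd_um)
    recs <- lapply(seq_len(n), function(i) {
      shape <- exp(-offs^2 / (2 * pit_sigma_um^2))
      tt <- periph[i] - depth[i] * shape
      tt <- tt + (origin[i] == "Asian") * origin_effect_um * shape
      edge <- abs(offs) >= 1500
      tt[edge] <- tt[edge] - (sex[i] == "female") * sex_effect_um
      tt <- tt + rnorm(9, 0, noise_um)
      tt <- round(tt / ax) * ax
      tun <- round((tt[5] + rnorm(1, 1.0, 1.5)) / ax) * ax
      tut <- round((tt[5] + rnorm(1, 1.0, 1.5)) / ax) * ax
      aa <- strip_um * (tt[-9] + tt[-1]) / 2 + rnorm(8, 0, 500)
      rec <- c(tt, TUn = tun, TUt = tut, aa,
               AUn = umbo_um * (tt[5] + tun) / 2 + rnorm(1, 0, 150),
               AUt = umbo_um * (tt[5] + tut) / 2 + rnorm(1, 0, 150))
      names(rec)[1:9] <- paste0("T", 1:9)
      names(rec)[12:19] <- paste0("A", 1:8)
      tibble::as_tibble(as.list(rec))
    })
    dplyr::bind_cols(
      tibble::tibble(
        eye_id = sprintf("sim%03d", seq_len(n)), side = side, sex = sex,
        origin = ifelse(stats::runif(n) < prop_unknown_origin, "unknown", origin),
        nulla_bscan = 13L, nulla_col = 256L
      ),
      dplyr::bind_rows(recs)
    )[, measurement_header()]
  })
}
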