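test_that("sampling-plan offsets snap to whole columns of the default raster", {
  plan <- build_sampling_plan(256L, scan_geometry(), side = "OD")
  cols <- setNames(plan$column, plan$label)
  # 500 um -> 48 columns, 100 um -> 10, 2000 um -> 193 (nasal = image right
  # for OD, so nasal offsets map to larger columns)
  expect_identical(cols[["T5"]], 256L)
  expect_identical(cols[["T4"]] - cols[["T5"]], 48L)
  expect_identical(cols[["T1"]] - cols[["T5"]], 193L)
  expect_identical(cols[["TUn"]] - cols[["T5"]], 10L)
  expect_identical(cols[["TUt"]] - cols[["T5"]], -10L)
  # strictly monotone in offset
  expect_true(all(diff(plan$column[order(plan$offset_um)]) < 0))
})

test_that("orientation flips between eye sides under the convention", {
  od <- build_sampling_plan(256L, side = "OD")
  os <- build_sampling_plan(256L, side = "OS")
  expect_identical(od$column[od$label == "T1"], 256L + 193L)
  expect_identical(os$column[os$label == "T1"], 256L - 193L)
  # flipping the convention mirrors the plan
  flipped <- build_sampling_plan(256L, side = "OD",
                                 convention = orientation_convention("left", "right"))
  expect_identical(flipped$column, os$column)
})

test_that("plans that would leave the B-scan error naming the offset", {
  expect_error(build_sampling_plan(100L, side = "OS"), "-2000 um")
  expect_error(build_sampling_plan(450L, side = "OD"), "-2000 um")
  expect_silent(build_sampling_plan(194L, side = "OD"))
})

test_that("orient_record maps image directions onto nasal/temporal labels", {
  offs <- c(seq(-2000, 2000, by = 500), -100, 100)
  vals <- setNames(as.numeric(offs), as.character(offs))  # value = image offset
  os <- orient_record(vals, "OS")
  expect_identical(os$value[os$label == "T1"], -2000)  # image-left is nasal
  od <- orient_record(vals, "OD")
  expect_identical(od$value[od$label == "T1"], 2000)   # image-right is nasal
  expect_identical(od$value[od$label == "TUt"], -100)
})

test_that("axial thickness is an inclusive pixel count times the axial scale", {
  map <- matrix(seg_labels()[["vitreous"]], 512, 512)
  map[101:150, ] <- seg_labels()[["retina"]]
  s <- extract_surfaces(map)
  g <- scan_geometry()
  expect_equal(measure_thickness(s$ilm, s$rpe, 256L, g), 50 * 3.9)
  one <- matrix(seg_labels()[["vitreous"]], 64, 64)
  one[30, ] <- seg_labels()[["retina"]]
  s1 <- extract_surfaces(one)
  expect_equal(measure_thickness(s1$ilm, s1$rpe, 10L, toy_geometry()), 3.9)
  s$ilm[5] <- NA
  expect_error(measure_thickness(s$ilm, s$rpe, 5L, g), "no retina")
})

test_that("rpe-normal thickness agrees with axial on a flat retina", {
  map <- matrix(seg_labels()[["vitreous"]], 512, 512)
  map[101:150, ] <- seg_labels()[["retina"]]
  s <- extract_surfaces(map)
  g <- scan_geometry()
  ax <- measure_thickness(s$ilm, s$rpe, 256L, g)
  nm <- measure_thickness(s$ilm, s$rpe, 256L, g, mode = "rpe_normal")
  expect_equal(nm, ax, tolerance = 0.05)
})

test_that("areas are half-open pixel counts times the pixel footprint", {
  g <- scan_geometry()
  map <- matrix(seg_labels()[["vitreous"]], 512, 512)
  map[101:150, ] <- seg_labels()[["retina"]]
  a <- measure_area(map, 100L, 148L, g)
  expect_equal(a, 48 * 50 * g$lateral_um_per_px * g$axial_um_per_px)
  expect_equal(a, 96890.625)
  expect_error(measure_area(map, 100L, 100L, g), "empty")
  # additivity over adjacent intervals
  expect_equal(measure_area(map, 100L, 130L, g) + measure_area(map, 130L, 148L, g),
               measure_area(map, 100L, 148L, g))
})

test_that("a flat phantom profiles to constant thickness and equal areas", {
  spec <- phantom_spec(pit_depth_um = 0, peripheral_thickness_um = 195,
                       rpe_row = 300L)
  ph <- generate_phantom(spec)
  rec <- profile_eye(ph$volume, eye_metadata("flat", "OD"))
  tt <- as.numeric(rec[, c(paste0("T", 1:9), "TUn", "TUt")])
  expect_true(all(tt == 195))
  g <- scan_geometry()
  spans <- abs(diff(round(seq(-2000, 2000, 500) / g$lateral_um_per_px)))
  expect_equal(as.numeric(rec[, paste0("A", 1:8)]),
               spans * 50 * g$lateral_um_per_px * g$axial_um_per_px,
               tolerance = 1e-9)
  expect_identical(rec$TUn, rec$TUt)
})

test_that("noiseless pit phantom measurements equal the analytic truth exactly", {
  for (side in c("OD", "OS")) {
    meta <- eye_metadata(paste0("eye-", side), side, "female", "Asian")
    ph <- generate_phantom(phantom_spec(pit_center = c(11L, 270L)), meta)
    rec <- profile_eye(ph$volume, meta)
    expect_identical(as.data.frame(rec)[, 1:6], as.data.frame(ph$truth$record)[, 1:6])
    expect_equal(as.numeric(rec[, 7:27]), as.numeric(ph$truth$record[, 7:27]),
                 tolerance = 1e-12)
    # axial thicknesses are exact multiples of the axial quantum
    tt <- as.numeric(rec[, c(paste0("T", 1:9), "TUn", "TUt")])
    expect_true(all(abs(tt / 3.9 - round(tt / 3.9)) < 1e-9))
    # the pit makes T5 the minimum of the profile
    expect_equal(min(as.numeric(rec[, paste0("T", 1:9)])), rec$T5)
  }
})

test_that("a symmetric phantom measures identically under either eye side", {
  ph <- generate_phantom(phantom_spec(pit_center = c(13L, 256L)))
  od <- profile_eye(ph$volume, eye_metadata("e", "OD"))
  os <- profile_eye(ph$volume, eye_metadata("e", "OS"))
  expect_equal(as.numeric(od[, 7:27]), as.numeric(os[, 7:27]), tolerance = 1e-12)
})

test_that("profile_eye refuses metadata without a known side", {
  ph <- generate_phantom(phantom_spec())
  meta <- eye_metadata("e", "OD")
  meta$side <- "unknown"
  expect_error(profile_eye(ph$volume, meta), "side")
})
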