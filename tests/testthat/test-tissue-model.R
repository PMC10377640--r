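test_that("spectra lookups are exact at tabulated wavelengths and ordered", {
  sp <- chromophore_spectra()
  raw <- utils::read.table(
    system.file("extdata", "chromophore_mua.tsv", package = "rpoxim"),
    header = TRUE, sep = "\t", comment.char = "#")
  expect_identical(mua_lookup(sp, "water", 940),
                   raw$water[raw$wavelength_nm == 940])
  expect_identical(mua_lookup(sp, "oxy_hb", 660),
                   raw$oxy_hb[raw$wavelength_nm == 660])
  # isosbestic ordering of the hemoglobin species
  expect_gt(mua_lookup(sp, "deoxy_hb", 660), mua_lookup(sp, "oxy_hb", 660))
  expect_gt(mua_lookup(sp, "oxy_hb", 940), mua_lookup(sp, "deoxy_hb", 940))
  expect_error(mua_lookup(sp, "water", 500), "outside")
  expect_error(mua_lookup(sp, "unobtainium", 660), "unknown")
})

test_that("mix_absorption implements volume-fraction mixing with SpO2 split", {
  sp <- chromophore_spectra()
  empty <- list(f_blood = 0, f_water = 0, f_fat = 0, f_melanin = 0,
                f_baseline = 0, f_collagen = 0)
  expect_identical(mix_absorption(empty, sp, 660), 0)
  water <- modifyList(empty, list(f_water = 1))
  expect_identical(mix_absorption(water, sp, 940), mua_lookup(sp, "water", 940))
  # direct evaluation of the two-term blood formula as the oracle
  blood <- modifyList(empty, list(f_blood = 1))
  for (s in c(0.70, 1.00)) {
    expect_equal(mix_absorption(blood, sp, 660, spo2 = s),
                 s * mua_lookup(sp, "oxy_hb", 660) +
                   (1 - s) * mua_lookup(sp, "deoxy_hb", 660))
  }
  # deoxy-Hb absorbs more at 660 nm, so lower SpO2 means more absorption
  expect_gt(mix_absorption(blood, sp, 660, spo2 = 0.70),
            mix_absorption(blood, sp, 660, spo2 = 1.00))
  # strictly increasing in the capillary multiplier when blood is present
  half <- modifyList(empty, list(f_blood = 0.3, f_water = 0.3))
  m <- c(0.5, 1, 1.5, 2)
  mu <- vapply(m, function(mm)
    mix_absorption(half, sp, 660, phase_multiplier = mm), numeric(1))
  expect_true(all(diff(mu) > 0))
  expect_error(mix_absorption(blood, sp, 660, phase_multiplier = 1.5),
               "exceed")
})

test_that("point classification matches the brute-force containment oracle", {
  map <- default_map()
  R <- map$geometry$radius_cm
  # named reference points
  expect_identical(classify_point(map, c(0, -0.3, 0)), "bone")
  expect_identical(classify_point(map, c(-0.4, -0.45, 0)), "artery_blood")
  expect_identical(classify_point(map, c(0.4, -0.45, 0)), "artery_blood")
  expect_identical(classify_point(map, c(0, -(R + 1e-9), 0)), "surround")
  expect_identical(classify_point(map, c(0, -(R - 1e-4), 0)), "epidermis")
  # random cloud against the independent oracle
  set.seed(42)
  n <- 2e5
  pts <- cbind(runif(n, -1, 1), runif(n, -1, 1), runif(n, -2.2, 2.2))
  expect_identical(classify_point(map, pts), unname(oracle_classify(map, pts)))
})

test_that("diastolic/systolic maps differ only at the artery annulus and
           area ratios match the analytic value", {
  md <- default_map("diastolic")
  ms <- default_map("systolic")
  set.seed(7)
  n <- 4e5
  pts <- cbind(runif(n, -0.9, 0.9), runif(n, -0.9, 0.9), 0)
  cd <- classify_point(md, pts)
  cs <- classify_point(ms, pts)
  # grid-count estimate of the artery cross-section area ratio
  ratio <- sum(cd == "artery_blood") / sum(cs == "artery_blood")
  expect_equal(ratio, (0.092 / 0.08)^2, tolerance = 0.05)
  # outside the artery annulus the classification is identical
  ann <- sqrt((abs(pts[, 1]) - 0.4)^2 + (pts[, 2] + 0.45)^2) <= 0.092
  expect_identical(cd[!ann], cs[!ann])
  # Monte Carlo area of the bone vs the ellipse formula
  box_area <- 1.8^2
  bone_area <- box_area * mean(cd == "bone")
  expect_equal(bone_area, pi * 0.25 * 0.15, tolerance = 0.05)
})

test_that("geometry validation rejects inconsistent configurations", {
  expect_error(finger_geometry(artery_center_cm = c(0.8, 0.45)),
               "artery")
  expect_error(finger_geometry(bone_size_cm = c(2, 2)), "bone")
  expect_error(finger_geometry(skin_thickness_cm = c(
    epidermis = 0.3, papillary_dermis = 0.3, upper_blood_net_dermis = 0.1,
    reticular_dermis = 0.1, deep_blood_net_dermis = 0.1)),
    "thickness")
  # artery at its widest (diastolic) must still fit
  expect_silent(validate_geometry(finger_geometry(), 0.092))
})

test_that("tissue map resolves phase- and wavelength-dependent properties", {
  mdia <- default_map("diastolic")
  msys <- default_map("systolic")
  # diastole carries more capillary blood -> higher mu_a in dermis layers
  i <- match("reticular_dermis", mdia$layers)
  expect_gt(mdia$mua[i], msys$mua[i])
  # epidermis has no blood: identical across phases
  j <- match("epidermis", mdia$layers)
  expect_identical(mdia$mua[j], msys$mua[j])
  # artery blood: 660 nm absorption rises when SpO2 drops
  m70 <- default_map(spo2 = 0.70)
  k <- match("artery_blood", mdia$layers)
  expect_gt(m70$mua[k], mdia$mua[k])
})
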