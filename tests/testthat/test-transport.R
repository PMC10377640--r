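test_that("free-path sampling matches the exponential law", {
  # closed form: xi = exp(-1), mu_t = 10 -> s = 0.1 cm
  expect_equal(-log(exp(-1)) / 10, 0.1)
  s <- step_length(1e6, mu_t = 5, seed = 3)
  expect_true(all(s > 0))
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 0.2), 3 * se)
  # Kolmogorov distance between the empirical and closed-form survival fn
  ks <- suppressWarnings(stats::ks.test(s, stats::pexp, rate = 5))
  expect_lt(unname(ks$statistic), 0.002)
  expect_error(step_length(10, mu_t = 0), "positive")
})

test_that("Henyey-Greenstein sampler: first moment equals g", {
  for (g in c(0, 0.5, 0.9)) {
    ct <- hg_cosines(1e6, g, seed = 17 + round(100 * g))
    expect_true(all(ct >= -1 & ct <= 1))
    se <- sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se)
  }
  # g = 0 is isotropic: uniform deflection cosine
  ct0 <- hg_cosines(1e5, 0, seed = 5)
  expect_lt(suppressWarnings(
    unname(stats::ks.test(ct0, stats::punif, -1, 1)$statistic)), 0.01)
})

test_that("launch states: positions on the LED disk, inward directions", {
  geom <- finger_geometry()
  m <- launch_photons(1e5, geom, source_config(), seed = 9)
  # on (just inside) the finger surface
  r <- sqrt(m[, "x"]^2 + m[, "y"]^2)
  expect_true(all(abs(r - geom$radius_cm) < 2e-4))
  # within the LED disk: arc and axial offsets inside the radius
  phi <- atan2(m[, "x"], -m[, "y"])
  expect_true(all(sqrt((geom$radius_cm * phi)^2 + m[, "z"]^2) <=
                    geom$led_radius_cm + 1e-6))
  # mean launch position at the LED center within 3 SE
  expect_lt(abs(mean(m[, "x"])), 3 * sd(m[, "x"]) / sqrt(nrow(m)))
  expect_lt(abs(mean(m[, "z"])), 3 * sd(m[, "z"]) / sqrt(nrow(m)))
  # unit directions with positive inward component
  expect_true(all(abs(sqrt(m[, "ux"]^2 + m[, "uy"]^2 + m[, "uz"]^2) - 1)
                  < 1e-9))
  inward <- -(m[, "x"] * m[, "ux"] + m[, "y"] * m[, "uy"]) / r
  expect_true(all(inward > 0))
  # Lambertian: inward cosine has CDF u^2 -> compare against inverse-CDF law
  expect_lt(suppressWarnings(unname(
    stats::ks.test(inward^2, stats::punif)$statistic)), 0.01)
  # pencil beam: direction is exactly the inward surface normal
  p <- launch_photons(10, geom, source_config(profile = "pencil"), seed = 1)
  expect_equal(unname(p[, "ux"]), rep(0, 10))
  expect_equal(unname(p[, "uy"]), rep(1, 10))
  expect_equal(unname(p[, "uz"]), rep(0, 10))
})

test_that("weight drop and roulette arithmetic", {
  d <- drop_weight(0.8, mu_a = 2.5, mu_t = 10)
  expect_equal(d$w, 0.6)
  expect_equal(d$absorbed, 0.2)
  expect_equal(drop_weight(1, 0, 5)$w, 1)          # no absorption
  expect_equal(drop_weight(1, 5, 5)$w, 0)          # fully absorbed
  expect_error(drop_weight(1, 6, 5), "mu_a <= mu_t")
  # roulette: p = 1 never terminates; survivors rescaled by 1/p
  expect_equal(roulette(c(1e-5, 2e-5), p_survive = 1), c(1e-5, 2e-5))
  w <- rep(5e-5, 2e5)
  out <- roulette(w, p_survive = 0.1, seed = 4)
  expect_true(all(out %in% c(0, 5e-4)))
  # unbiased in expectation
  se <- sd(out) / sqrt(length(out))
  expect_lt(abs(mean(out) - 5e-5), 3 * se)
})

test_that("specular reflection negates the normal component only", {
  d <- c(0.6, -0.48, 0.64)
  nrm <- c(0, -1, 0)
  r <- reflect_direction(d, nrm)
  expect_equal(r, c(0.6, 0.48, 0.64))
  expect_equal(sum(r^2), sum(d^2))
})

test_that("Beer-Lambert: non-scattering uniform slab matches exp(-mu_a d)", {
  # pure-water finger at 940 nm, pencil beam, PD diametrically opposite
  map <- build_tissue_map(compositions = water_compositions(),
                          wavelength_nm = 940)
  mua <- unique(round(map$mua, 12))
  expect_length(mua, 1)
  d <- map$geometry$ring_diameter_cm
  n <- 2e5
  res <- run_simulation(map, source_config(940, profile = "pencil"),
                        detector_config(180), boundary_config(0),
                        n_photons = n, seed = 21)
  p <- exp(-mua * d)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(res$I - p), 3 * se)
})

test_that("energy ledger conserves launched weight across conditions", {
  map <- default_map()
  for (cfg in list(list(rho = 0, th = 25), list(rho = 1, th = 60),
                   list(rho = 0.5, th = 90))) {
    r <- run_simulation(map, detector = detector_config(cfg$th),
                        boundary = boundary_config(cfg$rho),
                        n_photons = 5e3, seed = 31)
    expect_true(all(r$ledger[c("detected", "tissue", "surround", "caps")]
                    >= 0))
    expect_lt(abs(1 - sum(r$ledger)), 1e-6)
  }
})

test_that("ideal mirror with no detector: nothing escapes the surround", {
  map <- default_map()
  r <- run_simulation(map, detector = NULL, boundary = boundary_config(1),
                      n_photons = 2e3, seed = 13)
  expect_identical(r$ledger[["surround"]], 0)
  expect_identical(r$ledger[["detected"]], 0)
  # everything is absorbed in tissue or at the end caps (roulette-corrected)
  expect_lt(abs(1 - sum(r$ledger)), 1e-6)
  expect_gt(r$ledger[["tissue"]], 0.95)
})

test_that("a vacuum finger with an all-rim detector captures everything", {
  comp <- water_compositions()
  comp$f_water <- 0   # mu_a = 0, mu_s = 0 everywhere
  map <- build_tissue_map(compositions = comp, wavelength_nm = 660)
  res <- run_simulation(
    map, source_config(660, profile = "pencil"),
    detector_config(0, aperture_cm = c(2 * pi * 0.85 + 1, 10)),
    boundary_config(0), n_photons = 1e4, seed = 2)
  expect_equal(res$I, 1, tolerance = 1e-9)
  # Lambertian launch: everything not detected on the rim reaches the
  # absorbing end caps; together they account for all launched weight
  res2 <- run_simulation(
    map, source_config(660),
    detector_config(0, aperture_cm = c(2 * pi * 0.85 + 1, 10)),
    boundary_config(0), n_photons = 1e4, seed = 2)
  expect_equal(res2$I + res2$ledger[["caps"]], 1, tolerance = 1e-9)
})

test_that("surround reflectance increases detection; runs are reproducible", {
  map <- default_map()
  r0 <- run_simulation(map, n_photons = 3e4, seed = 99)
  r0b <- run_simulation(map, n_photons = 3e4, seed = 99)
  expect_identical(r0$I, r0b$I)
  expect_identical(r0$ledger, r0b$ledger)
  r1 <- run_simulation(map, boundary = boundary_config(1),
                       n_photons = 3e4, seed = 99)
  expect_gt(r1$I, r0$I)
  # partial reflectance lands between the two ideals
  rh <- run_simulation(map, boundary = boundary_config(0.9),
                       n_photons = 3e4, seed = 99)
  expect_gt(rh$I, r0$I)
  expect_lt(rh$ledger[["surround"]], r0$ledger[["surround"]])
})
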