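# Shared fixtures built in code at test time.

default_map <- function(phase = "diastolic", wavelength_nm = 660,
                        spo2 = 0.98) {
  build_tissue_map(state = physiological_state(phase, spo2 = spo2),
                   wavelength_nm = wavelength_nm)
}

# Uniform, non-scattering "water slab" compositions: every compartment is
# pure water with mu_s = 0, so a pencil beam obeys Beer-Lambert across the
# finger diameter.
water_compositions <- function() {
  tab <- layer_compositions()
  tab$f_blood <- 0; tab$f_fat <- 0; tab$f_melanin <- 0
  tab$f_baseline <- 0; tab$f_collagen <- 0
  tab$f_water <- 1
  tab$mus_660 <- 0; tab$mus_940 <- 0
  tab$capillary <- FALSE
  tab
}

# Brute-force geometric classifier: direct ellipse/circle membership tests
# in the internal coordinate frame (y flipped so the LED side is negative).
# Independent of the kernel's classify path.
oracle_classify <- function(map, pts) {
  geom <- map$geometry
  R <- geom$radius_cm
  th <- geom$skin_thickness_cm
  bc <- c(geom$bone_center_cm[1], -geom$bone_center_cm[2])
  bs <- geom$bone_semiaxes_cm
  axy <- c(geom$artery_center_cm[1], -geom$artery_center_cm[2])
  ar <- map$state$artery_radius_cm
  apply(pts, 1, function(p) {
    x <- p[1]; y <- p[2]; z <- p[3]
    r <- sqrt(x^2 + y^2)
    if (abs(z) > geom$length_cm / 2 || r > R) return("surround")
    if ((x - axy[1])^2 + (y - axy[2])^2 <= ar^2 ||
        (x + axy[1])^2 + (y - axy[2])^2 <= ar^2) return("artery_blood")
    if (((x - bc[1]) / bs[1])^2 + ((y - bc[2]) / bs[2])^2 <= 1) return("bone")
    depth <- R - r
    bounds <- cumsum(th)
    for (i in seq_along(bounds)) {
      if (depth < bounds[i]) return(names(th)[i])
    }
    "subcutaneous_fat"
  })
}

# Synthetic sweep whose per-angle R ratios at each SpO2 level average to a
# prescribed calibration value (used to exercise the calibration pipeline
# without Monte Carlo runs).
synthetic_sweep <- function(r_by_spo2 = c(`0.7` = 1.9, `0.8` = 1.5,
                                          `0.9` = 1.25, `1` = 0.9),
                            theta_deg = seq(25, 95, by = 5),
                            jitter = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in names(r_by_spo2)) {
    r <- r_by_spo2[[s]] + if (jitter > 0)
      stats::rnorm(length(theta_deg), sd = jitter) else 0
    r <- r - mean(r) + r_by_spo2[[s]]   # keep the angle-mean exact
    pi_nir <- rep(0.2, length(theta_deg))
    pi_red <- r * pi_nir
    for (wl in c(660, 940)) {
      rows[[length(rows) + 1L]] <- data.frame(
        theta_deg = theta_deg, wavelength_nm = wl, rho = 0,
        spo2 = as.numeric(s), n_photons = 1e5, n_repeats = 1,
        dc_mean = 0.01, ac_mean = 0.01 * (if (wl == 660) pi_red else pi_nir),
        pi = if (wl == 660) pi_red else pi_nir,
        rel_std = NA_real_,
        r_ratio = r)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_summary", "data.frame")
  out
}
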