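#' Paired systolic/diastolic run: dc and ac detected intensity
#'
#' Runs the transport kernel twice on tissue maps that differ only in the
#' cardiac-phase parameters (artery radius 0.08 vs 0.092 cm; capillary
#' blood-volume multiplier 1 vs 1.5) and forms the dc and ac components of
#' the detected intensity.
#'
#' Conventions: the reference parameter table assigns the larger blood
#' volume to the diastolic column, so the literal subtraction
#' `I_diastolic - I_systolic` is negative.  The default `"magnitude"`
#' convention therefore reports `ac = |I_diastolic - I_systolic|` and
#' `dc = max(I_systolic, I_diastolic)`, recording the raw signed difference
#' as `ac_signed`; `convention = "paper"` reproduces the literal quoted
#' subtraction (`dc = I_diastolic`, `ac = I_diastolic - I_systolic`).
#'
#' Both phases use the same kernel seed (common random numbers), which
#' sharply reduces the Monte Carlo variance of the small ac difference.
#'
#' @param theta_deg PD angular separation (degrees).
#' @param wavelength_nm 660 or 940 (any tabulated wavelength accepted).
#' @param spo2 Oxygen saturation fraction.
#' @param rho Surround reflectance.
#' @param n_photons Photons per phase.
#' @param seed Kernel seed (shared by the two phases).
#' @param geometry,compositions,spectra Model inputs.
#' @param convention `"magnitude"` (default) or `"paper"`.
#' @param common_rng Use the same seed for both phases (default `TRUE`).
#' @return An object of class `paired_intensity` with fields `dc`, `ac`,
#'   `ac_signed`, `I_systolic`, `I_diastolic`, and the run metadata.
#' @export
paired_run <- function(theta_deg = 25, wavelength_nm = 660, spo2 = 0.98,
                       rho = 0, n_photons = 1e5, seed = 1,
                       geometry = finger_geometry(),
                       compositions = layer_compositions(),
                       spectra = chromophore_spectra(),
                       convention = c("magnitude", "paper"),
                       common_rng = TRUE) {
  convention <- match.arg(convention)
  src <- source_config(wavelength_nm = wavelength_nm)
  det <- detector_config(theta_deg = theta_deg)
  bnd <- boundary_config(rho = rho)
  seeds <- if (common_rng) c(seed, seed) else c(seed, seed + 1L)
  run_phase <- function(phase, sd) {
    st <- physiological_state(phase = phase, spo2 = spo2)
    map <- build_tissue_map(geometry, compositions, spectra, st,
                            wavelength_nm)
    run_simulation(map, src, det, bnd, n_photons = n_photons, seed = sd)
  }
  rs <- run_phase("systolic", seeds[1])
  rd <- run_phase("diastolic", seeds[2])
  ac_signed <- rd$I - rs$I
  if (convention == "paper") {
    dc <- rd$I; ac <- ac_signed
  } else {
    dc <- max(rs$I, rd$I); ac <- abs(ac_signed)
  }
  structure(list(
    I_systolic = rs$I, I_diastolic = rd$I,
    dc = dc, ac = ac, ac_signed = ac_signed,
    convention = convention,
    theta_deg = theta_deg, wavelength_nm = wavelength_nm,
    spo2 = spo2, rho = rho, n_photons = n_photons, seeds = seeds
  ), class = "paired_intensity")
}

#' @export
print.paired_intensity <- function(x, ...) {
  cat(sprintf(
    "Paired run at theta_PL = %g deg, %g nm, SpO2 %.0f%%, rho = %g:\n",
    x$theta_deg, x$wavelength_nm, 100 * x$spo2, x$rho))
  cat(sprintf("  I_systolic = %.4g, I_diastolic = %.4g\n",
              x$I_systolic, x$I_diastolic))
  cat(sprintf("  dc = %.4g, ac = %.4g (%s convention), PI = %.4g\n",
              x$dc, x$ac, x$convention,
              if (x$dc > 0) x$ac / x$dc else NA))
  invisible(x)
}

#' Perfusion index: ac/dc
#'
#' @param pair A `paired_intensity`, or a numeric `ac` with `dc` supplied.
#' @param dc dc intensity when `pair` is the ac value.
#' @return PI (dimensionless).
#' @export
perfusion_index <- function(pair, dc = NULL) {
  if (inherits(pair, "paired_intensity")) {
    ac <- pair$ac; dc <- pair$dc
  } else {
    ac <- pair
  }
  if (is.null(dc) || dc <= 0) stop("PI undefined: dc must be > 0")
  ac / dc
}

#' R ratio: PI(red) / PI(NIR)
#'
#' The ratio-of-ratios linking the two-wavelength perfusion indices to
#' oxygen saturation through the calibration curve.
#'
#' @param pi_red PI at 660 nm.
#' @param pi_nir PI at 940 nm.
#' @return R (dimensionless).
#' @export
r_ratio <- function(pi_red, pi_nir) {
  if (any(pi_nir <= 0)) stop("R undefined: PI at the NIR wavelength must be > 0")
  pi_red / pi_nir
}

#' Relative enhancement in percent
#'
#' `100 * (v1 - v0) / v0`: the relative increase of a boosted value over a
#' reference (e.g. mirror-coated over absorbing surround).
#'
#' @param v0 Reference value (> 0).
#' @param v1 Boosted value.
#' @return Enhancement in percent.
#' @export
enhancement <- function(v0, v1) {
  if (any(v0 <= 0)) stop("enhancement undefined for reference <= 0")
  100 * (v1 - v0) / v0
}

#' LED duty cycle in percent
#'
#' @param on_s On time per period (s), e.g. one 50 microsecond pulse.
#' @param period_s Pulse period (s), e.g. 40 ms at the 25 Hz frame rate.
#' @return Duty cycle in percent.
#' @export
duty_cycle <- function(on_s = 50e-6, period_s = 40e-3) {
  stopifnot(on_s >= 0, period_s > 0)
  100 * on_s / period_s
}

#' Angle sweep of paired dc/ac intensities
#'
#' Repeats [paired_run()] over the PD angle grid (default 25--95 degrees in
#' 5-degree steps, 15 positions) for each requested wavelength, surround
#' reflectance and SpO2 level, with optional repeats for spread statistics.
#'
#' @param theta_deg Vector of PD angles.
#' @param wavelengths_nm Wavelength set.
#' @param spo2 SpO2 levels (fractions).
#' @param rho Surround reflectance values.
#' @param n_photons Photons per phase and run.
#' @param n_repeats Independent repeats per condition (seeds
#'   `base_seed + repeat index`).
#' @param base_seed Base seed; per-condition seeds are derived
#'   deterministically from it.
#' @param resume Optional data frame of previously completed summary rows;
#'   matching conditions are reused instead of recomputed.
#' @param ... Passed to [paired_run()] (geometry, compositions, spectra,
#'   convention).
#' @return A `sweep_summary` data frame with one row per condition:
#'   theta_deg, wavelength_nm, rho, spo2, n_photons, n_repeats, dc_mean,
#'   ac_mean, pi, rel_std and (joined across wavelengths) r_ratio.
#' @export
angle_sweep <- function(theta_deg = seq(25, 95, by = 5),
                        wavelengths_nm = c(660, 940),
                        spo2 = 0.98, rho = 0,
                        n_photons = 1e5, n_repeats = 1,
                        base_seed = 1, resume = NULL, ...) {
  grid <- expand.grid(theta_deg = theta_deg, wavelength_nm = wavelengths_nm,
                      rho = rho, spo2 = spo2, KEEP.OUT.ATTRS = FALSE)
  key <- function(d) paste(d$theta_deg, d$wavelength_nm, d$rho, d$spo2)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gi <- grid[i, ]
    if (!is.null(resume)) {
      hit <- match(key(gi), key(resume))
      if (!is.na(hit)) {  # completed condition: reuse, never recompute
        rows[[i]] <- resume[hit, c("theta_deg", "wavelength_nm", "rho",
                                   "spo2", "n_photons", "n_repeats",
                                   "dc_mean", "ac_mean", "pi", "rel_std")]
        next
      }
    }
    dcs <- acs <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      # distinct, reproducible seed per condition and repeat
      sd <- (base_seed + 7919L * (i - 1L) + (r - 1L)) %% .Machine$integer.max
      pr <- paired_run(theta_deg = gi$theta_deg,
                       wavelength_nm = gi$wavelength_nm,
                       spo2 = gi$spo2, rho = gi$rho,
                       n_photons = n_photons, seed = sd, ...)
      dcs[r] <- pr$dc; acs[r] <- pr$ac
    }
    dc_mean <- mean(dcs); ac_mean <- mean(acs)
    rows[[i]] <- data.frame(
      theta_deg = gi$theta_deg, wavelength_nm = gi$wavelength_nm,
      rho = gi$rho, spo2 = gi$spo2, n_photons = n_photons,
      n_repeats = n_repeats, dc_mean = dc_mean, ac_mean = ac_mean,
      pi = if (dc_mean > 0) ac_mean / dc_mean else NA_real_,
      rel_std = if (n_repeats > 1 && dc_mean > 0)
        stats::sd(dcs) / dc_mean else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (col in c("dc_mean", "ac_mean", "pi", "rel_std")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  out$r_ratio <- NA_real_
  if (all(c(660, 940) %in% wavelengths_nm)) {
    key <- function(d) paste(d$theta_deg, d$rho, d$spo2)
    red <- out[out$wavelength_nm == 660, ]
    nir <- out[out$wavelength_nm == 940, ]
    m <- match(key(out), key(red))
    m2 <- match(key(out), key(nir))
    ok <- !is.na(m) & !is.na(m2) & !is.na(red$pi[m]) & !is.na(nir$pi[m2]) &
      nir$pi[m2] > 0
    out$r_ratio[ok] <- red$pi[m][ok] / nir$pi[m2][ok]
  }
  class(out) <- c("sweep_summary", "data.frame")
  out
}

#' Repetition statistics of the detected intensity
#'
#' Repeats a single-condition run `n_repeats` times with consecutive seeds,
#' normalizes the detected intensities to their mean, and reports the sample
#' standard deviation and the 3-sigma half-width as a percentage of the
#' mean (99.73% coverage band under normality).
#'
#' @param theta_deg,wavelength_nm,spo2,rho,n_photons Condition.
#' @param phase Cardiac phase of the single map used.
#' @param n_repeats Number of repeats (>= 2); seeds `base_seed + 0:(n-1)`.
#' @param base_seed Base seed.
#' @param geometry,compositions,spectra Model inputs.
#' @return An object of class `repetition_stats`: normalized intensities,
#'   their mean intensity, `std` of the normalized values, and
#'   `three_sigma_pct`.
#' @export
repetition_statistics <- function(theta_deg = 25, wavelength_nm = 660,
                                  spo2 = 0.98, rho = 0, n_photons = 1e5,
                                  phase = "diastolic", n_repeats = 100,
                                  base_seed = 1,
                                  geometry = finger_geometry(),
                                  compositions = layer_compositions(),
                                  spectra = chromophore_spectra()) {
  stopifnot(n_repeats >= 2)
  st <- physiological_state(phase = phase, spo2 = spo2)
  map <- build_tissue_map(geometry, compositions, spectra, st, wavelength_nm)
  src <- source_config(wavelength_nm = wavelength_nm)
  det <- detector_config(theta_deg = theta_deg)
  bnd <- boundary_config(rho = rho)
  I <- vapply(seq_len(n_repeats) - 1L, function(k) {
    run_simulation(map, src, det, bnd, n_photons = n_photons,
                   seed = base_seed + k)$I
  }, numeric(1))
  if (any(I == 0)) {
    warning("repeat(s) with zero detection retained as 0")
  }
  m <- mean(I)
  norm <- if (m > 0) I / m else I
  s <- stats::sd(norm)
  structure(list(intensities = I, normalized = norm, mean = m, std = s,
                 three_sigma_pct = 300 * s, n_photons = n_photons,
                 seeds = base_seed + seq_len(n_repeats) - 1L),
            class = "repetition_stats")
}

#' @export
print.repetition_stats <- function(x, ...) {
  cat(sprintf(
    "Repetition statistics: %d repeats x %g photons\n  mean I = %.4g, std of normalized intensity = %.4g\n  3-sigma band: +/-%.2f%% of the mean\n",
    length(x$intensities), x$n_photons, x$mean, x$std, x$three_sigma_pct))
  invisible(x)
}
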