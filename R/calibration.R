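#' Reference calibration curve from the published simulation
#'
#' The 1e8-photon absorbing-surround reference calibration values
#' (R = 0.9, 1.25, 1.5, 1.9 at SpO2 = 100, 90, 80, 70%), shipped as a
#' constant for downstream reliability analysis and tests.
#'
#' @return A `calibration_curve` object.
#' @export
reference_calibration_curve <- function() {
  new_calibration_curve(spo2_pct = c(100, 90, 80, 70),
                        r = c(0.9, 1.25, 1.5, 1.9),
                        reference = "published")
}

#' @keywords internal
new_calibration_curve <- function(spo2_pct, r, reference = "simulated",
                                  n_photons = NA, rho = NA) {
  o <- order(spo2_pct, decreasing = TRUE)
  spo2_pct <- spo2_pct[o]; r <- r[o]
  if (any(diff(r) <= 0)) {
    stop("calibration curve must be strictly decreasing in SpO2 ",
         "(R strictly increasing as SpO2 decreases)")
  }
  structure(list(spo2_pct = spo2_pct, r = r, reference = reference,
                 n_photons = n_photons, rho = rho),
            class = "calibration_curve")
}

#' Calibration curve from sweep results
#'
#' Averages the 15 per-angle R ratios at each SpO2 level of a sweep run
#' under the reference condition (absorbing surround, largest affordable
#' photon count), yielding the SpO2-to-R calibration curve.  Monotonicity
#' (R strictly decreasing with SpO2) is enforced as a validation check.
#'
#' @param sweep A [angle_sweep()] result containing all 15 angles for every
#'   requested SpO2 level, with `r_ratio` filled (both wavelengths present).
#' @param spo2_pct SpO2 levels (percent) expected in the sweep.
#' @param theta_deg The full angle grid that must be present per level.
#' @return A `calibration_curve` object.
#' @export
calibration_curve <- function(sweep, spo2_pct = c(70, 80, 90, 100),
                              theta_deg = seq(25, 95, by = 5)) {
  red <- sweep[sweep$wavelength_nm == 660, ]
  rvals <- vapply(spo2_pct, function(s) {
    rows <- red[abs(red$spo2 * 100 - s) < 1e-6, ]
    missing <- setdiff(theta_deg, rows$theta_deg)
    if (length(missing)) {
      stop(sprintf("incomplete sweep: SpO2 %g%% missing angles %s",
                   s, paste(missing, collapse = ", ")))
    }
    rr <- rows$r_ratio[match(theta_deg, rows$theta_deg)]
    if (any(is.na(rr))) {
      stop(sprintf("incomplete sweep: undefined R ratio at SpO2 %g%%", s))
    }
    mean(rr)
  }, numeric(1))
  new_calibration_curve(spo2_pct = spo2_pct, r = rvals,
                        n_photons = sweep$n_photons[1], rho = sweep$rho[1])
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("SpO2 calibration curve (", x$reference, "):\n", sep = "")
  print(data.frame(spo2_pct = x$spo2_pct, R = x$r), row.names = FALSE)
  invisible(x)
}

#' Reliability limits from a calibration curve
#'
#' Each limit is the midpoint of the calibration R values of two adjacent
#' SpO2 levels: `L_R1 = (R_100 + R_90)/2`, `L_R2 = (R_90 + R_80)/2`,
#' `L_R3 = (R_80 + R_70)/2`.  For the published reference curve this gives
#' (1.075, 1.375, 1.7).
#'
#' @param curve A `calibration_curve` (strictly monotone).
#' @return An object of class `reliability_limits` with fields `L_R1`,
#'   `L_R2`, `L_R3`.
#' @export
reliability_limits <- function(curve = reference_calibration_curve()) {
  if (!inherits(curve, "calibration_curve")) {
    curve <- new_calibration_curve(c(100, 90, 80, 70), curve)
  }
  r <- curve$r
  if (length(r) != 4) stop("expected exactly four SpO2 levels")
  lims <- (r[-4] + r[-1]) / 2
  structure(list(L_R1 = lims[1], L_R2 = lims[2], L_R3 = lims[3]),
            class = "reliability_limits")
}

#' @export
print.reliability_limits <- function(x, ...) {
  cat(sprintf("Reliability limits: L_R1 = %g, L_R2 = %g, L_R3 = %g\n",
              x$L_R1, x$L_R2, x$L_R3))
  invisible(x)
}

#' Classify an R ratio as reliable for a known SpO2 level
#'
#' Bin rule with strict inequalities (a value exactly on a limit is
#' unreliable): SpO2 100% requires `R < L_R1`; 90% requires
#' `L_R1 < R < L_R2`; 80% requires `L_R2 < R < L_R3`; 70% requires
#' `R > L_R3`.
#'
#' @param r R ratio value(s).
#' @param true_spo2_pct The known SpO2 level: 70, 80, 90 or 100.
#' @param limits A [reliability_limits()] object.
#' @return Logical: `TRUE` where R falls in the bin of `true_spo2_pct`.
#' @export
classify_reliable <- function(r, true_spo2_pct,
                              limits = reliability_limits()) {
  if (!true_spo2_pct %in% c(70, 80, 90, 100)) {
    stop("true SpO2 must be one of 70, 80, 90, 100 (%)")
  }
  switch(as.character(true_spo2_pct),
         "100" = r < limits$L_R1,
         "90"  = r > limits$L_R1 & r < limits$L_R2,
         "80"  = r > limits$L_R2 & r < limits$L_R3,
         "70"  = r > limits$L_R3)
}

#' Maximum reliable PD angle
#'
#' The largest angle on the grid such that every angle up to it has all
#' four SpO2 levels classified reliable.  Because the perfusion index
#' increases with the PD angle inside the reliable range, this angle is
#' also the optimal PD position.  If no angle qualifies the condition is
#' not measurable and `NA` is returned.
#'
#' @param reliable Logical matrix: rows = angles (ascending), columns =
#'   SpO2 levels; or a data frame with columns `theta_deg` and `reliable`.
#' @param theta_deg Angle grid matching the rows.
#' @return The angle in degrees, or `NA_real_` ("not measurable").
#' @export
theta_max <- function(reliable, theta_deg = seq(25, 95, by = 5)) {
  if (is.data.frame(reliable)) {
    ok <- tapply(reliable$reliable, reliable$theta_deg, all)
    theta_deg <- as.numeric(names(ok))
    ok <- as.logical(ok)
  } else {
    reliable <- as.matrix(reliable)
    stopifnot(nrow(reliable) == length(theta_deg))
    ok <- apply(reliable, 1, all)
  }
  o <- order(theta_deg)
  ok <- ok[o]; theta_deg <- theta_deg[o]
  run <- cumprod(ok) > 0   # prefix of angles that are all reliable
  if (!any(run)) return(NA_real_)
  max(theta_deg[run])
}

#' Per-angle reliability matrix from a sweep
#'
#' Evaluates [classify_reliable()] for every angle and SpO2 level of a
#' sweep (one surround reflectance at a time).
#'
#' @param sweep An [angle_sweep()] result with `r_ratio` filled.
#' @param limits A [reliability_limits()] object.
#' @return Data frame with columns `theta_deg`, `spo2_pct`, `r_ratio`,
#'   `reliable`.
#' @export
reliability_table <- function(sweep, limits = reliability_limits()) {
  red <- sweep[sweep$wavelength_nm == 660 & !is.na(sweep$r_ratio), ]
  if (length(unique(red$rho)) > 1) {
    stop("reliability_table expects a single surround reflectance")
  }
  data.frame(
    theta_deg = red$theta_deg,
    spo2_pct = 100 * red$spo2,
    r_ratio = red$r_ratio,
    reliable = mapply(function(r, s) classify_reliable(r, s, limits),
                      red$r_ratio, 100 * red$spo2))
}
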