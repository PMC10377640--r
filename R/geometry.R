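#' Finger geometry for the ring-type oximeter model
#'
#' Circular-cylinder finger coincident with the ring inner surface (zero
#' gap), elliptical bone cross-section, two mirrored digital arteries, and
#' the LED/PD footprint dimensions.  Defaults reproduce the reference
#' geometry: ring diameter 1.7 cm, bone centered 0.3 cm from the axis with
#' full widths 0.5 x 0.3 cm, arteries at (+/-0.4, 0.45) cm with radius
#' 0.08 cm, PD aperture 0.3 x 0.3 cm^2, LED radius 0.15 cm.
#'
#' Internal coordinates: the cylinder axis is z; the LED sits at the bottom
#' of the cross-section (rim angle 0 deg, surface point (0, -R)); the bone
#' and artery center heights are measured positive toward the LED (palmar)
#' side, so internally the bone sits at (0, -0.3) and the arteries at
#' (+/-0.4, -0.45) -- beneath the bone, on the LED side.
#'
#' @param ring_diameter_cm Finger/ring diameter.
#' @param bone_center_cm (x, y) bone center; y positive toward the LED side.
#' @param bone_size_cm Full widths (x, y) of the bone ellipse.
#' @param artery_center_cm (x, y) of the right artery; the left is mirrored
#'   at -x.  y positive toward the LED side.
#' @param artery_radius_cm Baseline (systolic) artery radius.
#' @param skin_thickness_cm Named vector of shell thicknesses (cm), outermost
#'   first; subcutaneous fat fills the remainder.
#' @param length_cm Cylinder length (absorbing end caps).
#' @param pd_size_cm PD aperture (arc width, axial height).
#' @param led_radius_cm LED disk radius on the surface.
#' @return An object of class `finger_geometry`.
#' @export
finger_geometry <- function(ring_diameter_cm = 1.7,
                            bone_center_cm = c(0, 0.3),
                            bone_size_cm = c(0.5, 0.3),
                            artery_center_cm = c(0.4, 0.45),
                            artery_radius_cm = 0.08,
                            skin_thickness_cm = c(
                              epidermis = 0.010,
                              papillary_dermis = 0.020,
                              upper_blood_net_dermis = 0.008,
                              reticular_dermis = 0.080,
                              deep_blood_net_dermis = 0.030),
                            length_cm = 4.0,
                            pd_size_cm = c(0.3, 0.3),
                            led_radius_cm = 0.15) {
  g <- structure(list(
    ring_diameter_cm = ring_diameter_cm,
    radius_cm = ring_diameter_cm / 2,
    bone_center_cm = bone_center_cm,
    bone_semiaxes_cm = bone_size_cm / 2,
    artery_center_cm = artery_center_cm,
    artery_radius_cm = artery_radius_cm,
    skin_thickness_cm = skin_thickness_cm,
    length_cm = length_cm,
    pd_size_cm = pd_size_cm,
    led_radius_cm = led_radius_cm
  ), class = "finger_geometry")
  validate_geometry(g)
  g
}

#' @keywords internal
validate_geometry <- function(g, artery_radius_cm = g$artery_radius_cm) {
  R <- g$radius_cm
  if (R <= 0) stop("ring diameter must be positive")
  if (sum(g$skin_thickness_cm) >= R) {
    stop("skin layer thicknesses must sum to less than the finger radius")
  }
  # bone strictly inside the finger
  bc <- g$bone_center_cm; bs <- g$bone_semiaxes_cm
  if (sqrt(bc[1]^2 + bc[2]^2) + max(bs) >= R) {
    stop("bone extends outside the finger boundary")
  }
  # arteries strictly inside the finger (at the widest cardiac radius given)
  ac <- g$artery_center_cm
  if (sqrt(ac[1]^2 + ac[2]^2) + artery_radius_cm >= R) {
    stop("artery extends outside the finger boundary")
  }
  # artery should not intersect the bone ellipse (coarse bounding check)
  dx <- max(0, abs(ac[1]) - bs[1]); dy <- max(0, abs(ac[2] - bc[2]) - bs[2])
  if (sqrt(dx^2 + dy^2) < artery_radius_cm) {
    stop("artery overlaps the bone")
  }
  invisible(g)
}

#' @export
print.finger_geometry <- function(x, ...) {
  cat("Finger geometry: cylinder radius", x$radius_cm, "cm, length",
      x$length_cm, "cm\n")
  cat("  bone ellipse center (0,", -x$bone_center_cm[2], ") semi-axes",
      paste(x$bone_semiaxes_cm, collapse = " x "), "cm\n")
  cat("  arteries at (+/-", x$artery_center_cm[1], ",",
      -x$artery_center_cm[2], ") cm, radius", x$artery_radius_cm, "cm\n")
  cat("  skin shells (cm):",
      paste(names(x$skin_thickness_cm), x$skin_thickness_cm,
            collapse = ", "), "\n")
  cat("  PD", paste(x$pd_size_cm, collapse = " x "),
      "cm^2, LED radius", x$led_radius_cm, "cm\n")
  invisible(x)
}

#' Physiological state of the finger model
#'
#' The two cardiac phases carry the reference parameter set: artery radius
#' 0.08 cm with capillary blood multiplier 1 in the systolic state, and
#' 0.092 cm with multiplier 1.5 in the diastolic state (the multiplier is
#' normalized to the systolic state).  Any SpO2 in \[0, 1\] is accepted; the
#' calibration sweeps use 0.70-1.00 in steps of 0.10.
#'
#' @param phase `"systolic"` or `"diastolic"`.
#' @param spo2 Oxygen saturation fraction.
#' @param artery_radius_cm Override of the phase default.
#' @param capillary_multiplier Override of the phase default.
#' @return An object of class `physiological_state`.
#' @export
physiological_state <- function(phase = c("diastolic", "systolic"),
                                spo2 = 0.98,
                                artery_radius_cm = NULL,
                                capillary_multiplier = NULL) {
  phase <- match.arg(phase)
  stopifnot(spo2 >= 0, spo2 <= 1)
  defaults <- list(systolic = list(r = 0.080, m = 1.0),
                   diastolic = list(r = 0.092, m = 1.5))[[phase]]
  structure(list(
    phase = phase,
    spo2 = spo2,
    artery_radius_cm = artery_radius_cm %||% defaults$r,
    capillary_multiplier = capillary_multiplier %||% defaults$m
  ), class = "physiological_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
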